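# Synthetic scalp EEG: a linear mixture of a fronto-central low-frequency
# inhibition source, posterior alpha, broadband 1/f noise, and a lateralized
# motor source, with per-channel sensor noise. The ground-truth mixing matrix
# and per-trial source amplitudes travel with the recording so closed-loop
# tests can inject the true unmixing and score recovery.

eeg_channel_sets <- function(n_channels) {
  base <- c("FCz", "Cz", "C1", "C2", "FC1", "FC2")
  extra <- c("F3", "F4", "C3", "C4", "P3", "P4", "Pz", "POz", "O1", "O2",
             "F1", "F2", "CP1", "CP2", "P1", "P2")
  if (n_channels < length(base)) {
    abort("need at least the six fronto-central channels")
  }
  c(base, extra)[seq_len(n_channels)]
}

# Raised-cosine attack (attack_ms) followed by a Hann-shaped decay; a fast
# attack keeps the planted onset recoverable by sample-wise testing.
burst_waveform <- function(nsamp, srate, freq = 4, dur_ms = 400,
                           attack_ms = 10) {
  t_ms <- (seq_len(nsamp) - 1) * 1000 / srate
  env <- numeric(nsamp)
  a <- t_ms <= attack_ms
  env[a] <- 0.5 - 0.5 * cos(pi * t_ms[a] / attack_ms)
  d <- t_ms > attack_ms & t_ms <= dur_ms
  env[d] <- 0.5 + 0.5 * cos(pi * (t_ms[d] - attack_ms) / (dur_ms - attack_ms))
  env * cos(2 * pi * freq * t_ms / 1000)
}

# Broadband 1/f ("pink") noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  N <- stats::nextn(n, c(2, 3, 5))
  X <- fft(rnorm(N))
  f <- c(1, seq_len(N - 1))
  f <- pmin(f, N - f + 1)
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE) / N)[seq_len(n)]
  as.numeric(scale(x))
}

#' Simulate a scalp EEG session as a linear source mixture
#'
#' Builds a continuous multichannel recording for a behavior table from
#' [gen_simon_behavior()] or [gen_stop_signal_session()]. Four sources are
#' mixed: (1) a fronto-central source emitting a 2-8 Hz-band burst (4 Hz
#' carrier under a fast-attack/Hann-decay envelope) after stop-signals
#' (onset earlier on successful than failed stops) or after incongruent Simon
#' stimuli, with single-trial amplitude `burst_amp + rt_effect_gain * z(RT)`
#' on incongruent trials; (2) posterior alpha; (3) broadband 1/f noise;
#' (4) a lateralized central motor source. White sensor noise (`noise_sd`) is
#' added per channel.
#'
#' @param behavior A behavior tibble; stop-signal sessions are recognized by
#'   non-missing `ssd` values.
#' @param n_channels Number of channels (>= 6; the first six are the
#'   fronto-central set FCz, Cz, C1, C2, FC1, FC2).
#' @param params A [simon_params()] block (its `rt_effect_gain` drives the
#'   amplitude-RT coupling); ignored for stop sessions.
#' @param seed Integer seed.
#' @param srate Sampling rate (Hz).
#' @param burst_amp Baseline burst amplitude of the inhibition source.
#' @param noise_sd Per-channel white sensor-noise SD.
#' @param onset_success,onset_fail Burst onset (ms after the stop-signal) on
#'   successful and failed stop trials.
#' @param onset_simon Burst onset (ms after stimulus) on incongruent trials.
#' @param burst_freq,burst_dur_ms,attack_ms Carrier frequency and envelope
#'   shape of the burst.
#' @param mixing Optional channels x 4 mixing matrix to reuse (e.g. to give
#'   two sessions of one subject a common forward model); default: drawn.
#' @return A [new_recording()] with `events` (columns `trial`, `sample`,
#'   `stop_sample`) and an attribute `truth` holding the mixing matrix, the
#'   planted source index, per-trial burst amplitudes and onsets.
#' @export
gen_scalp_eeg <- function(behavior, n_channels = 16, params = simon_params(),
                          seed = 1, srate = 500, burst_amp = 2, noise_sd = 1,
                          onset_success = 250, onset_fail = 290,
                          onset_simon = 200, burst_freq = 4,
                          burst_dur_ms = 400, attack_ms = 10, mixing = NULL) {
  assert_columns(behavior, c("trial", "condition", "rt", "correct", "ssd"))
  chans <- eeg_channel_sets(n_channels)
  n_trials <- nrow(behavior)
  is_sst <- any(!is.na(behavior$ssd))
  with_seed(child_seed(seed, "eeg"), {
    iti_s <- 1.6
    lead_s <- 1.0
    nsamp <- as.integer((lead_s + iti_s * n_trials + lead_s) * srate)
    stim <- as.integer(lead_s * srate + (seq_len(n_trials) - 1L) * iti_s * srate) + 1L

    # source 1: inhibition bursts
    s1 <- numeric(nsamp)
    nb <- ms_to_samples(burst_dur_ms + 50, srate)
    wave <- burst_waveform(nb, srate, burst_freq, burst_dur_ms, attack_ms)
    amp <- rep(NA_real_, n_trials)
    onset_ms <- rep(NA_real_, n_trials)
    stop_sample <- rep(NA_integer_, n_trials)
    if (is_sst) {
      for (i in seq_len(n_trials)) {
        if (behavior$condition[i] != "stop") next
        stop_sample[i] <- stim[i] + ms_to_samples(behavior$ssd[i], srate)
        onset_ms[i] <- if (behavior$stop_outcome[i] == "success")
          onset_success else onset_fail
        amp[i] <- burst_amp
        at <- stop_sample[i] + ms_to_samples(onset_ms[i], srate)
        s1[at:(at + nb - 1L)] <- s1[at:(at + nb - 1L)] + amp[i] * wave
      }
    } else {
      sel <- which(behavior$condition == "incongruent" & behavior$correct &
                     !is.na(behavior$rt))
      z <- as.numeric(scale(behavior$rt[sel]))
      amp[sel] <- pmax(burst_amp + params$rt_effect_gain * z, 0.1)
      onset_ms[sel] <- onset_simon
      for (k in seq_along(sel)) {
        i <- sel[k]
        at <- stim[i] + ms_to_samples(onset_simon, srate)
        s1[at:(at + nb - 1L)] <- s1[at:(at + nb - 1L)] + amp[i] * wave
      }
    }

    # sources 2-4: posterior alpha, 1/f background, lateralized motor beta
    tt <- (seq_len(nsamp) - 1) / srate
    s2 <- sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) *
      (0.8 + 0.4 * sin(2 * pi * 0.1 * tt + runif(1, 0, 2 * pi)))
    s3 <- pink_noise(nsamp)
    s4 <- sin(2 * pi * 20 * tt + runif(1, 0, 2 * pi)) *
      (0.6 + 0.3 * sin(2 * pi * 0.07 * tt + runif(1, 0, 2 * pi)))
    S <- rbind(s1, s2, s3, s4)

    if (is.null(mixing)) {
      mixing <- matrix(runif(n_channels * 4, 0.05, 0.3), n_channels, 4)
      rownames(mixing) <- chans
      mixing[match(c("FCz", "Cz", "FC1", "FC2", "C1", "C2"), chans), 1] <-
        c(1.0, 0.9, 0.75, 0.75, 0.7, 0.7)
      post <- intersect(c("Pz", "POz", "O1", "O2", "P3", "P4", "P1", "P2"), chans)
      if (length(post) > 0) mixing[match(post, chans), 2] <- runif(length(post), 0.7, 1)
      mixing[, 3] <- runif(n_channels, 0.4, 0.8)
      lat <- intersect(c("C3", "C4"), chans)
      if (length(lat) > 0) mixing[match(lat, chans), 4] <- c(0.9, 0.9)[seq_along(lat)]
    } else {
      stopifnot(nrow(mixing) == n_channels, ncol(mixing) == 4L)
    }

    X <- mixing %*% S + matrix(rnorm(n_channels * nsamp, sd = noise_sd),
                               n_channels, nsamp)
    events <- tibble(trial = behavior$trial, sample = stim,
                     stop_sample = stop_sample)
    rec <- new_recording(X, srate, chans, events)
    attr(rec, "truth") <- list(
      mixing = mixing, source_index = 1L, amp = amp, onset_ms = onset_ms,
      burst_freq = burst_freq, burst_dur_ms = burst_dur_ms,
      attack_ms = attack_ms, noise_sd = noise_sd)
    rec
  })
}
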