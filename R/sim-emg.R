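# Synthetic TMS-evoked EMG sweeps: Gaussian background EMG plus a biphasic
# MEP template, with controllable pre-pulse contamination and interleaved
# null-trial baseline sweeps.

#' @rdname simon_params
#' @param baseline_amp Peak-to-peak MEP amplitude (mV) on congruent/baseline
#'   sweeps.
#' @param suppression_factor Multiplier on incongruent-trial amplitudes, in
#'   (0, 1].
#' @param emg_noise_rms RMS of the background EMG noise (mV).
#' @param contaminated_fraction Fraction of sweeps given pre-pulse EMG
#'   activity exceeding the 0.01 mV rejection threshold.
#' @param pulse_time TMS pulse latency in ms post-stimulus (the CSE probe
#'   timepoint).
#' @export
mep_params <- function(baseline_amp = 1, suppression_factor = 0.8,
                       emg_noise_rms = 0.003, contaminated_fraction = 0,
                       pulse_time = 250) {
  assert_scalar_number(baseline_amp, "baseline_amp", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(suppression_factor, "suppression_factor", 0, 1,
                       strict_lower = TRUE)
  assert_scalar_number(contaminated_fraction, "contaminated_fraction", 0, 1)
  list(baseline_amp = baseline_amp, suppression_factor = suppression_factor,
       emg_noise_rms = emg_noise_rms,
       contaminated_fraction = contaminated_fraction, pulse_time = pulse_time)
}

# Biphasic difference-of-Gaussians MEP, unit peak-to-peak, peaks 20-30 ms
# post-pulse on the `t_ms` axis (ms relative to the pulse).
mep_template <- function(t_ms) {
  w <- exp(-(t_ms - 22)^2 / (2 * 2^2)) - 0.9 * exp(-(t_ms - 28)^2 / (2 * 2.5^2))
  w / (max(w) - min(w))
}

#' Simulate TMS-evoked EMG sweeps
#'
#' One sweep per correct Simon trial plus `n_baseline` null-trial baseline
#' sweeps. Sweeps start 150 ms before the TMS pulse and run 100 ms past it at
#' 1000 Hz. The MEP peak-to-peak amplitude is `baseline_amp` on congruent and
#' baseline sweeps and `baseline_amp * suppression_factor` on incongruent
#' sweeps (log-normal trial-to-trial jitter `amp_jitter`); a
#' `contaminated_fraction` of sweeps receives pre-pulse EMG activity with
#' RMS above the 0.01 mV screening threshold.
#'
#' @param behavior A Simon behavior tibble (only correct trials yield sweeps).
#' @param params A [mep_params()] block.
#' @param seed Integer seed.
#' @param n_baseline Number of null-trial baseline sweeps.
#' @param amp_jitter SD of the log-normal amplitude jitter (0 = noiseless
#'   template amplitudes).
#' @return A tibble of EMG trials: `trial`, `condition`, `side`, `rt`,
#'   `timepoint` (ms post-stimulus of the pulse), `pulse_time` (ms from sweep
#'   start), `srate`, list-column `sweep` (mV), and ground-truth columns
#'   `true_amp`, `contaminated`.
#' @export
gen_emg_sweeps <- function(behavior, params = mep_params(), seed = 1,
                           n_baseline = 40, amp_jitter = 0.1) {
  assert_columns(behavior, c("trial", "condition", "correct"))
  keep <- behavior[behavior$correct &
                     behavior$condition %in% c("congruent", "incongruent"), ]
  with_seed(child_seed(seed, "emg"), {
    srate <- 1000
    pulse_ms <- 150
    sweep_len <- ms_to_samples(pulse_ms + 100, srate)
    t_post <- (seq_len(sweep_len) - 1) * 1000 / srate - pulse_ms
    template <- mep_template(t_post)
    n_task <- nrow(keep)
    n <- n_task + n_baseline
    cond <- c(keep$condition, rep("baseline", n_baseline))
    amp <- ifelse(cond == "incongruent",
                  params$baseline_amp * params$suppression_factor,
                  params$baseline_amp)
    if (amp_jitter > 0) amp <- amp * exp(rnorm(n, 0, amp_jitter))
    contaminated <- rbinom(n, 1L, params$contaminated_fraction) == 1L
    sweeps <- purrr::map(seq_len(n), function(i) {
      sw <- rnorm(sweep_len, 0, params$emg_noise_rms) + amp[i] * template
      if (contaminated[i]) {
        pre <- t_post < 0
        sw[pre] <- sw[pre] + rnorm(sum(pre), 0, runif(1, 0.015, 0.04))
      }
      sw
    })
    tibble(
      trial = c(keep$trial, max(behavior$trial) + seq_len(n_baseline)),
      condition = cond,
      side = c(keep$side, rep(NA_character_, n_baseline)),
      rt = c(keep$rt, rep(NA_real_, n_baseline)),
      timepoint = params$pulse_time,
      pulse_time = pulse_ms, srate = srate,
      sweep = sweeps, true_amp = amp, contaminated = contaminated)
  })
}
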