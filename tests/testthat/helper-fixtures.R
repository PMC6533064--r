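# Shared fixtures and independent oracles, all built in code at test time.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

# Independent brute-force Benjamini-Hochberg step-up, coded directly from the
# step-up definition (kept separate from the implementation path).
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  mask <- logical(m)
  if (length(below) > 0) mask[o[seq_len(max(below))]] <- TRUE
  mask
}

# A tfr object with prescribed phase angles (trials x freqs x times).
tfr_from_phase <- function(theta, freqs = NULL, times = NULL, srate = 1000) {
  d <- dim(theta)
  conflictr:::new_tfr(exp(1i * theta),
                      freqs %||% seq_len(d[2]),
                      times %||% seq_len(d[3]) * 1000 / srate,
                      srate)
}

# A tfr object carrying prescribed nonnegative power values.
tfr_from_power <- function(pw, freqs = NULL, times = NULL, srate = 500,
                           metadata = NULL) {
  d <- dim(pw)
  conflictr:::new_tfr(sqrt(pw) + 0i,
                      freqs %||% seq_len(d[2]),
                      times %||% seq_len(d[3]) * 1000 / srate,
                      srate, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full closed-loop stop-signal EEG session: generated behavior + broadband-
# filtered EEG + ground-truth unmixing, component selection, and the stop /
# matched-go amplitude matrices.
sst_closed_loop <- function(seed, n_go = 200, n_stop = 100, n_channels = 8,
                            ...) {
  sst <- gen_stop_signal_session(race_params(), n_go, n_stop, seed = seed)
  eeg <- broadband_filter(gen_scalp_eeg(sst, n_channels = n_channels,
                                        seed = seed, ...))
  truth <- attr(eeg, "truth")
  unmix <- conflictr:::pinv(truth$mixing)
  ev <- eeg$events
  stop_idx <- which(!is.na(ev$stop_sample))
  ep <- epoch(eeg, ev$stop_sample[stop_idx], c(-100, 600), sst[stop_idx, ])
  cs <- component_set(unmix, ep)
  sel <- quietly(select_inhibition_component(cs))
  bp <- backproject(cs, sel$selected[1])
  go_idx <- which(sst$condition == "go")
  go_lock <- ev$sample[go_idx] +
    conflictr:::ms_to_samples(sst$staircase_ssd[go_idx], eeg$srate)
  bpg <- backproject(component_set(unmix, epoch(eeg, go_lock, c(-100, 600))),
                     sel$selected[1])
  list(sst = sst, eeg = eeg, truth = truth, unmixing = unmix,
       selection = sel, times = ep$times,
       stop = bp, stop_meta = sst[stop_idx, ], go = bpg)
}

# Planted onsets recovered for one seed; returns c(success, fail) in ms.
recover_onsets <- function(loop) {
  succ <- loop$stop_meta$stop_outcome == "success"
  c(detect_p3_onset(loop$stop[succ, , drop = FALSE], loop$go,
                    loop$times)$onset,
    detect_p3_onset(loop$stop[!succ, , drop = FALSE], loop$go,
                    loop$times)$onset)
}

# Band/window-aggregated percent change for one direction of a
# granger_timecourse fit (aggregate raw estimates before baselining, which
# is the stable summary for band-level comparisons).
granger_band_pct <- function(g, direction, band, window) {
  fi <- g$freqs >= band[1] & g$freqs <= band[2]
  wi <- g$window_centers >= window[1] & g$window_centers <= window[2] &
    !g$excluded
  bi <- g$window_centers - g$window_len / 2 >= g$baseline[1] &
    g$window_centers + g$window_len / 2 <= g$baseline[2] & !g$excluded
  m <- mean(g$raw[[direction]][fi, wi])
  b <- mean(g$raw[[direction]][fi, bi])
  (m - b) / b * 100
}
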