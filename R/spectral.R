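#' Filter-Hilbert time-frequency decomposition
#'
#' Band-pass filters a signal at a grid of center frequencies (default the
#' 1-30 Hz integer grid with a +/- 0.5 Hz window) using symmetric two-way
#' least-squares FIR filters, then extracts the complex analytic signal with
#' the Hilbert transform. Power is the squared magnitude of the analytic
#' signal, phase its argument.
#'
#' Filtering is applied to the continuous trace before epoching when the
#' input is a [new_recording()] (preferred: no epoch-edge artifacts); for
#' already-epoched input each trial is zero-padded by `pad_ms` on both sides
#' before filtering and trimmed afterwards.
#'
#' @param x A `recording`, `epochs` object, or a trials x samples numeric
#'   matrix (a vector is one trial).
#' @param freqs Center frequencies in Hz (default `1:30`).
#' @param bw Half-bandwidth in Hz around each center frequency (default 0.5).
#' @param channel Channel label or index to decompose (single channel).
#' @param events,window,metadata For `recording` input: lock-event samples and
#'   epoch window (ms) passed to [epoch()] after filtering.
#' @param pad_ms Zero-padding per side for epoched input, in ms.
#' @param srate Sampling rate for matrix input.
#' @param times Optional time axis (ms) for matrix input.
#' @param ... Passed between methods.
#'
#' @return A `tfr` object: complex `analytic` array (trials x freqs x times),
#'   plus `freqs`, `times`, `srate` and trial `metadata`.
#' @export
filter_hilbert <- function(x, ...) UseMethod("filter_hilbert")

check_freqs <- function(freqs, bw, srate) {
  if (any(freqs + bw >= srate / 2)) {
    abort("requested frequency at or above Nyquist")
  }
  if (any(freqs - bw < 0)) abort("band edge below 0 Hz")
}

new_tfr <- function(analytic, freqs, times, srate, metadata = NULL) {
  structure(list(analytic = analytic, freqs = freqs, times = times,
                 srate = srate, metadata = metadata),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$analytic)
  cat(sprintf("<tfr> %d trial(s) x %d freq(s) x %d timepoints @ %g Hz\n",
              d[1], d[2], d[3], x$srate))
  cat(sprintf("freqs %g..%g Hz, times %g..%g ms\n",
              min(x$freqs), max(x$freqs), min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname filter_hilbert
#' @export
filter_hilbert.recording <- function(x, freqs = 1:30, bw = 0.5,
                                     channel = 1L, events = NULL,
                                     window = NULL, metadata = NULL, ...) {
  check_freqs(freqs, bw, x$srate)
  sig <- if (is.character(channel)) recording_channel(x, channel) else
    x$data[channel, , drop = FALSE]
  bands <- cbind(freqs - bw, freqs + bw)
  an <- band_analytic(sig, bands, x$srate)     # list over freqs, 1 x samples
  if (is.null(events)) {
    A <- array(NA_complex_, dim = c(1L, length(freqs), ncol(sig)))
    for (i in seq_along(an)) A[1L, i, ] <- an[[i]][1L, ]
    return(new_tfr(A, freqs, seq_len(ncol(sig)) * 1000 / x$srate, x$srate,
                   metadata))
  }
  stopifnot(length(window) == 2L)
  lo <- ms_to_samples(window[1], x$srate)
  hi <- ms_to_samples(window[2], x$srate) - 1L
  first <- as.integer(events) + lo
  last <- as.integer(events) + hi
  bad <- which(first < 1L | last > ncol(sig))
  if (length(bad) > 0L) {
    abort(sprintf("event window out of bounds for trial(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")))
  }
  nt <- hi - lo + 1L
  A <- array(NA_complex_, dim = c(length(events), length(freqs), nt))
  for (i in seq_along(an)) {
    for (r in seq_along(events)) A[r, i, ] <- an[[i]][1L, first[r]:last[r]]
  }
  new_tfr(A, freqs, (lo:hi) * 1000 / x$srate, x$srate, metadata)
}

#' @rdname filter_hilbert
#' @export
filter_hilbert.epochs <- function(x, freqs = 1:30, bw = 0.5, channel = 1L,
                                  pad_ms = 500, ...) {
  mat <- epochs_channel(x, channel)
  out <- filter_hilbert.default(mat, freqs = freqs, bw = bw, srate = x$srate,
                                times = x$times, pad_ms = pad_ms)
  out$metadata <- x$metadata
  out
}

#' @rdname filter_hilbert
#' @export
filter_hilbert.default <- function(x, freqs = 1:30, bw = 0.5, srate,
                                   times = NULL, pad_ms = 500, ...) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  check_freqs(freqs, bw, srate)
  npad <- ms_to_samples(pad_ms, srate)
  n <- ncol(x)
  xp <- cbind(matrix(0, nrow(x), npad), x, matrix(0, nrow(x), npad))
  bands <- cbind(freqs - bw, freqs + bw)
  an <- band_analytic(xp, bands, srate)
  keep <- npad + seq_len(n)
  A <- array(NA_complex_, dim = c(nrow(x), length(freqs), n))
  for (i in seq_along(an)) A[, i, ] <- an[[i]][, keep, drop = FALSE]
  if (is.null(times)) times <- seq_len(n) * 1000 / srate
  new_tfr(A, freqs, times, srate)
}

#' Power and phase of a decomposition
#'
#' @param tf A `tfr` object.
#' @return Numeric array (trials x freqs x times): squared magnitude
#'   (`tf_power`) or phase angle in radians (`tf_phase`).
#' @export
tf_power <- function(tf) {
  stopifnot(inherits(tf, "tfr"))
  Mod(tf$analytic)^2
}

#' @rdname tf_power
#' @export
tf_phase <- function(tf) {
  stopifnot(inherits(tf, "tfr"))
  Arg(tf$analytic)
}

# Column indices of a ms window (closed) on a time axis.
time_index <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0L) abort("window outside the epoch's time axis")
  idx
}

#' Event-related spectral perturbation (dB-baselined power)
#'
#' Trial-averaged power expressed in decibels relative to the trial-averaged
#' power in a pre-stimulus baseline window:
#' `10 * log10(mean_power(f, t) / mean_baseline_power(f))`.
#'
#' @param tf A `tfr` object.
#' @param baseline Length-2 ms window, default `c(-300, 0)`.
#' @param trials Optional integer/logical trial selector.
#' @return An `ersp` object: dB matrix `values` (freqs x times) with `freqs`,
#'   `times`, `baseline`, `n_trials`. Use [tidy()] for a long tibble.
#' @export
ersp <- function(tf, baseline = c(-300, 0), trials = NULL) {
  stopifnot(inherits(tf, "tfr"))
  pw <- tf_power(tf)
  if (!is.null(trials)) pw <- pw[trials, , , drop = FALSE]
  if (baseline[1] < min(tf$times) || baseline[2] > max(tf$times)) {
    abort("baseline window outside the epoch")
  }
  mp <- apply(pw, c(2, 3), mean)                      # freqs x times
  bidx <- time_index(tf$times, baseline)
  bl <- rowMeans(mp[, bidx, drop = FALSE])
  if (any(bl <= 0)) abort("zero baseline power at one or more frequencies")
  vals <- 10 * log10(mp / bl)
  structure(list(values = vals, freqs = tf$freqs, times = tf$times,
                 baseline = baseline, n_trials = dim(pw)[1]),
            class = "ersp")
}

#' @export
print.ersp <- function(x, ...) {
  cat(sprintf("<ersp> %d freqs x %d timepoints, baseline %g..%g ms, %d trial(s)\n",
              length(x$freqs), length(x$times), x$baseline[1], x$baseline[2],
              x$n_trials))
  cat(sprintf("range %.2f..%.2f dB\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
tidy.ersp <- function(x, ...) {
  tibble(freq = rep(x$freqs, times = length(x$times)),
         time = rep(x$times, each = length(x$freqs)),
         db = as.vector(x$values))
}
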