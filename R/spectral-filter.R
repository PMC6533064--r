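# Filtering primitives for the filter-Hilbert stack.
#
# Band-pass design: the unweighted least-squares optimum for a linear-phase
# FIR approximating a brick-wall band-pass is the truncated ideal impulse
# response; that is what fir_ls_bandpass() returns. Zero-phase ("two-way")
# filtering is applied in the frequency domain by multiplying with the
# squared magnitude response |B(w)|^2, which is exactly the response of a
# forward-backward pass of the symmetric filter, and is fused with the
# analytic-signal (Hilbert) step so each band costs one inverse FFT.

#' Least-squares linear-phase FIR band-pass coefficients
#'
#' @param f_lo,f_hi Band edges in Hz.
#' @param srate Sampling rate in Hz.
#' @param ntaps Odd number of taps; default [fir_ntaps()] of the band center.
#' @return Numeric vector of symmetric filter coefficients (unit passband gain).
#' @export
fir_ls_bandpass <- function(f_lo, f_hi, srate, ntaps = NULL) {
  assert_scalar_number(f_lo, "f_lo", lower = 0)
  assert_scalar_number(f_hi, "f_hi", lower = f_lo, strict_lower = TRUE)
  if (f_hi >= srate / 2) abort("band edge at or above Nyquist frequency")
  if (is.null(ntaps)) ntaps <- fir_ntaps((f_lo + f_hi) / 2, srate)
  ntaps <- as.integer(ntaps)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  half <- (ntaps - 1L) %/% 2L
  k <- seq(-half, half)
  w2 <- 2 * pi * f_hi / srate
  w1 <- 2 * pi * f_lo / srate
  b <- ifelse(k == 0L, (w2 - w1) / pi, (sin(w2 * k) - sin(w1 * k)) / (pi * k))
  b
}

#' Default FIR length: three cycles of the center frequency
#'
#' @param f Center frequency in Hz.
#' @param srate Sampling rate in Hz.
#' @return Odd tap count spanning `3 / f` seconds.
#' @export
fir_ntaps <- function(f, srate) {
  n <- as.integer(round(3 * srate / f))
  if (n %% 2L == 0L) n <- n + 1L
  n
}

# Squared-magnitude response of `b` on the length-N DFT grid.
fir_mag2 <- function(b, N) {
  Bf <- fft(c(b, rep(0, N - length(b))))
  Mod(Bf)^2
}

# Analytic-signal multiplier on the length-N DFT grid (MATLAB hilbert()
# convention: double positive frequencies, keep DC and Nyquist).
hilbert_mask <- function(N) {
  h <- numeric(N)
  h[1] <- 1
  if (N %% 2L == 0L) {
    h[N / 2 + 1] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[2:((N + 1) / 2)] <- 2
  }
  h
}

# Zero-phase band-pass + analytic signal for a set of series.
# x: matrix with one series per row. Returns list of complex matrices,
# one per band (rows = series), same width as x.
band_analytic <- function(x, bands, srate, ntaps = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  maxtaps <- max(vapply(seq_len(nrow(bands)), function(i) {
    if (is.null(ntaps)) fir_ntaps(mean(unlist(bands[i, ])), srate) else ntaps
  }, numeric(1)))
  N <- stats::nextn(n + 2L * maxtaps, c(2, 3, 5))
  xp <- cbind(x, matrix(0, nrow(x), N - n))
  Fx <- stats::mvfft(t(xp))                      # N x nseries
  h <- hilbert_mask(N)
  out <- vector("list", nrow(bands))
  for (i in seq_len(nrow(bands))) {
    f_lo <- bands[i, 1]; f_hi <- bands[i, 2]
    fc <- (f_lo + f_hi) / 2
    nt <- if (is.null(ntaps)) fir_ntaps(fc, srate) else ntaps
    b <- fir_ls_bandpass(f_lo, f_hi, srate, nt)
    # unity passband gain: normalize the two-pass response at the center
    # frequency (short kernels cannot reach full gain in a narrow band)
    gc <- Mod(sum(b * exp(-2i * pi * fc / srate * (seq_along(b) - 1))))^2
    g <- fir_mag2(b, N) * h / gc
    Y <- stats::mvfft(Fx * g, inverse = TRUE) / N
    out[[i]] <- t(Y)[, seq_len(n), drop = FALSE]
  }
  out
}

#' Welch power spectral density
#'
#' Averaged Hann-windowed periodograms over overlapping segments; used by the
#' resting-state contact-selection step.
#'
#' @param x Numeric vector.
#' @param srate Sampling rate in Hz.
#' @param seg_len Segment length in samples (default `srate`, i.e. 1 s).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A tibble with columns `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, srate, seg_len = srate, overlap = 0.5) {
  seg_len <- as.integer(seg_len)
  if (length(x) < seg_len) abort("signal shorter than one Welch segment")
  step <- max(1L, as.integer(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  scale <- sum(w^2) * srate
  nf <- seg_len %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / scale
    acc <- acc + 2 * P[2:(nf + 1L)]
  }
  tibble(freq = (1:nf) * srate / seg_len, power = acc / length(starts))
}

#' Broadband zero-phase pre-filter for continuous recordings
#'
#' Two-way FIR band-pass (default 0.5-50 Hz) applied to every channel of a
#' continuous recording — the standard broadband conditioning step before
#' component decomposition of scalp EEG.
#'
#' @param recording A [new_recording()].
#' @param hp,lp High-pass and low-pass cutoffs in Hz.
#' @return The filtered `recording`.
#' @export
broadband_filter <- function(recording, hp = 0.5, lp = 50) {
  stopifnot(inherits(recording, "recording"))
  ntaps <- fir_ntaps(max(hp, 0.5), recording$srate)
  an <- band_analytic(recording$data, rbind(c(hp, lp)), recording$srate,
                      ntaps = ntaps)[[1]]
  out <- recording
  out$data <- Re(an)
  attr(out, "truth") <- attr(recording, "truth")
  out
}
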