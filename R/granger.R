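# Spectral Granger prediction from bivariate autoregressive models:
# windowed OLS VAR fits, the Geweke frequency-domain decomposition from the
# fitted transfer function and residual covariance, and percent-change
# baselining over a sliding time course.

#' Fit bivariate and univariate autoregressive models to windowed data
#'
#' Ordinary least squares on the lagged design, with window-wise (per-trial)
#' demeaning; multiple trials' windows are stacked into one design (lags
#' never cross trial boundaries). Univariate models for both series are
#' fitted alongside for time-domain Granger ratios.
#'
#' @param x,y Numeric vectors or trials x samples matrices (same shape).
#' @param order AR model order (lags).
#' @param srate Sampling rate (Hz), carried for the spectral step.
#' @return A `bivar_ar` fit: `A` (2 x 2 x order coefficient array, equation x
#'   variable x lag), `Sigma` (2 x 2 residual covariance), `uni_var`
#'   (univariate residual variances), `order`, `nobs`, `srate`, `stable`.
#' @export
fit_bivariate_ar <- function(x, y, order, srate = 1000) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  stopifnot(identical(dim(x), dim(y)))
  order <- as.integer(order)
  n <- ncol(x)
  if (n <= 2L * order) abort("window length must exceed twice the model order")
  x <- x - rowMeans(x)
  y <- y - rowMeans(y)
  ntr <- nrow(x)
  nobs_tr <- n - order
  X <- matrix(NA_real_, ntr * nobs_tr, 2L * order)
  Y <- matrix(NA_real_, ntr * nobs_tr, 2L)
  for (r in seq_len(ntr)) {
    rows <- (r - 1L) * nobs_tr + seq_len(nobs_tr)
    tix <- (order + 1L):n
    Y[rows, 1] <- x[r, tix]
    Y[rows, 2] <- y[r, tix]
    for (k in seq_len(order)) {
      X[rows, k] <- x[r, tix - k]
      X[rows, order + k] <- y[r, tix - k]
    }
  }
  # normal-equation solve; the Gram matrix also provides both univariate fits
  G <- crossprod(X)
  XtY <- crossprod(X, Y)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < sqrt(.Machine$double.eps) * max(diag(R))) {
    abort("singular AR design (collinear or duplicated series)")
  }
  B <- backsolve(R, forwardsolve(t(R), XtY))  # (2*order) x 2
  E <- Y - X %*% B
  dof <- nrow(X) - ncol(X)
  Sigma <- crossprod(E) / dof
  A <- array(NA_real_, dim = c(2, 2, order))
  for (k in seq_len(order)) {
    A[1, 1, k] <- B[k, 1];          A[1, 2, k] <- B[order + k, 1]
    A[2, 1, k] <- B[k, 2];          A[2, 2, k] <- B[order + k, 2]
  }
  ix <- seq_len(order); iy <- order + ix
  uni_var <- c(
    x = uni_var_from_gram(G[ix, ix], XtY[ix, 1], sum(Y[, 1]^2), nrow(X), order),
    y = uni_var_from_gram(G[iy, iy], XtY[iy, 2], sum(Y[, 2]^2), nrow(X), order))
  structure(
    list(A = A, Sigma = Sigma, uni_var = uni_var, order = order,
         nobs = nrow(X), srate = srate, stable = var_is_stable(A)),
    class = "bivar_ar")
}

uni_var_from_gram <- function(G, Xty, yty, nobs, order) {
  b <- solve(G, Xty)
  rss <- yty - sum(b * Xty)
  max(rss, 0) / (nobs - order)
}

# VAR stability: all companion-matrix eigenvalues strictly inside the unit
# circle.
var_is_stable <- function(A) {
  p <- dim(A)[3]
  comp <- matrix(0, 2 * p, 2 * p)
  for (k in seq_len(p)) comp[1:2, (2 * k - 1):(2 * k)] <- A[, , k]
  if (p > 1) comp[3:(2 * p), 1:(2 * (p - 1))] <- diag(2 * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
}

#' @export
print.bivar_ar <- function(x, ...) {
  cat(sprintf("<bivar_ar> order %d, %d observations, %s\n", x$order, x$nobs,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Frequency-domain Granger prediction from a fitted bivariate AR model
#'
#' Geweke's spectral decomposition: from the fitted transfer function
#' `H(f) = (I - sum_k A_k e^(-i 2 pi f k / fs))^-1` and residual covariance,
#' the directed influence at frequency f is the log-ratio of the full
#' spectral density of the target to its intrinsic part. Nonnegative at
#' every frequency.
#'
#' @param fit A [fit_bivariate_ar()] result.
#' @param freqs Frequencies (Hz) to evaluate.
#' @return A tibble with columns `freq`, `yx` (influence of `y` on `x`) and
#'   `xy` (influence of `x` on `y`).
#' @export
spectral_granger <- function(fit, freqs) {
  stopifnot(inherits(fit, "bivar_ar"))
  S <- fit$Sigma
  p <- fit$order
  k <- seq_len(p)
  res <- purrr::map_dfr(freqs, function(f) {
    ek <- exp(-2i * pi * f * k / fit$srate)
    Af <- diag(2) + 0i
    for (j in k) Af <- Af - fit$A[, , j] * ek[j]
    H <- solve(Af)
    Sf <- H %*% S %*% Conj(t(H))
    sxx <- Re(Sf[1, 1]); syy <- Re(Sf[2, 2])
    s2_y_x <- S[2, 2] - S[1, 2]^2 / S[1, 1]   # y-noise not explained by x-noise
    s2_x_y <- S[1, 1] - S[1, 2]^2 / S[2, 2]
    gyx <- log(sxx / (sxx - s2_y_x * Mod(H[1, 2])^2))
    gxy <- log(syy / (syy - s2_x_y * Mod(H[2, 1])^2))
    tibble(freq = f, yx = max(gyx, 0), xy = max(gxy, 0))
  })
  res
}

#' Time-domain Granger log-variance ratios
#'
#' `ln(univariate residual variance / bivariate residual variance)` for each
#' series; the band-integrated spectral measure is consistent with this
#' (Geweke).
#'
#' @param fit A [fit_bivariate_ar()] result.
#' @return Named vector: `yx` (y improves prediction of x), `xy`.
#' @export
granger_time_domain <- function(fit) {
  stopifnot(inherits(fit, "bivar_ar"))
  c(yx = log(fit$uni_var[["x"]] / fit$Sigma[1, 1]),
    xy = log(fit$uni_var[["y"]] / fit$Sigma[2, 2]))
}

#' Time/frequency-resolved Granger prediction between two sites
#'
#' Slides a window across the epoch; in every window a bivariate AR model of
#' the given order is fitted on the trial-stacked data and the spectral
#' Granger estimate evaluated at the requested frequencies for both
#' directions. Each direction is then expressed as percent change from the
#' mean over the baseline windows (windows fully inside `baseline`):
#' `(estimate - baseline_mean) / baseline_mean * 100`, per frequency.
#' Windows with an unstable AR fit are flagged and excluded.
#'
#' @param epochs_x,epochs_y Single-channel [epoch()] objects on a common time
#'   axis (e.g. STN as `x`, M1 as `y`).
#' @param order AR order, default 50.
#' @param window_len Window length in ms, default 200.
#' @param step Window step in ms, default 10; window timestamps are centers.
#' @param freqs Frequency grid, default 21 values spanning 10-30 Hz.
#' @param baseline Baseline interval in ms, default `c(-300, 0)`.
#' @param trials Optional trial selector applied to both sites.
#' @return A `granger_estimate`: `pct` and `raw` lists of freqs x windows
#'   matrices for directions `xy` and `yx`, `window_centers` (ms), `freqs`,
#'   `excluded` window flags, plus fit metadata.
#' @export
granger_timecourse <- function(epochs_x, epochs_y, order = 50,
                               window_len = 200, step = 10,
                               freqs = seq(10, 30, length.out = 21),
                               baseline = c(-300, 0), trials = NULL) {
  stopifnot(inherits(epochs_x, "epochs"), inherits(epochs_y, "epochs"))
  if (!isTRUE(all.equal(epochs_x$times, epochs_y$times))) {
    abort("epochs must share a time axis")
  }
  x <- epochs_channel(epochs_x, 1L)
  y <- epochs_channel(epochs_y, 1L)
  if (!is.null(trials)) {
    x <- x[trials, , drop = FALSE]
    y <- y[trials, , drop = FALSE]
  }
  srate <- epochs_x$srate
  times <- epochs_x$times
  half <- window_len / 2
  centers <- seq(min(times) + half, max(times) - half + 1e-9, by = step)
  wsamp <- ms_to_samples(window_len, srate)
  if (wsamp <= 2 * order) abort("window holds too few samples for the order")
  nw <- length(centers)
  nf <- length(freqs)
  raw_xy <- raw_yx <- matrix(NA_real_, nf, nw)
  excluded <- logical(nw)
  for (w in seq_len(nw)) {
    i0 <- which.min(abs(times - (centers[w] - half)))
    idx <- i0:(i0 + wsamp - 1L)
    fit <- fit_bivariate_ar(x[, idx, drop = FALSE], y[, idx, drop = FALSE],
                            order, srate)
    if (!fit$stable) {
      excluded[w] <- TRUE
      inform(sprintf("unstable AR fit in window centered at %g ms; excluded",
                     centers[w]))
      next
    }
    sg <- spectral_granger(fit, freqs)
    raw_xy[, w] <- sg$xy
    raw_yx[, w] <- sg$yx
  }
  in_base <- centers - half >= baseline[1] & centers + half <= baseline[2] &
    !excluded
  if (!any(in_base)) abort("no usable baseline windows")
  pct <- function(M) {
    b <- rowMeans(M[, in_base, drop = FALSE])
    sweep(sweep(M, 1, b, "-"), 1, b, "/") * 100
  }
  structure(
    list(pct = list(xy = pct(raw_xy), yx = pct(raw_yx)),
         raw = list(xy = raw_xy, yx = raw_yx),
         window_centers = centers, freqs = freqs, order = order,
         window_len = window_len, baseline = baseline,
         excluded = excluded, n_trials = nrow(x)),
    class = "granger_estimate")
}

#' @export
print.granger_estimate <- function(x, ...) {
  cat(sprintf("<granger_estimate> order %d, %d windows (%d excluded), %d freqs, %d trials\n",
              x$order, length(x$window_centers), sum(x$excluded),
              length(x$freqs), x$n_trials))
  invisible(x)
}

#' @export
tidy.granger_estimate <- function(x, ...) {
  tibble(direction = rep(c("xy", "yx"),
                         each = length(x$freqs) * length(x$window_centers)),
         freq = rep(rep(x$freqs, times = length(x$window_centers)), 2),
         time = rep(rep(x$window_centers, each = length(x$freqs)), 2),
         pct_change = c(as.vector(x$pct$xy), as.vector(x$pct$yx)),
         raw = c(as.vector(x$raw$xy), as.vector(x$raw$yx)))
}

# Mean percent change of a direction within a band/time window.
granger_window_mean <- function(g, direction, band, window) {
  fi <- g$freqs >= band[1] & g$freqs <= band[2]
  wi <- g$window_centers >= window[1] & g$window_centers <= window[2] &
    !g$excluded
  mean(g$pct[[direction]][fi, wi], na.rm = TRUE)
}
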