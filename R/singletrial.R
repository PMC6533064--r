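# Single-trial time-frequency regression on RT and mass-univariate group
# statistics with FDR control.

new_tf_map <- function(values, freqs, times, class, ...) {
  structure(c(list(values = values, freqs = freqs, times = times), list(...)),
            class = class)
}

map_values <- function(m) {
  if (is.matrix(m)) m else m$values
}

#' Single-trial regression of time-frequency power on reaction time
#'
#' For every time-frequency pixel, the ordinary-least-squares slope of
#' single-trial power on z-scored RT (intercept included; z-scoring over the
#' selected trials only). Power enters in raw units by default; `db = TRUE`
#' converts single trials to dB against their own baseline first.
#'
#' @param tf A `tfr` decomposition.
#' @param rts Per-trial RTs in ms (defaults to `metadata$rt`).
#' @param trials Trial selector (integer or logical); typically the correct
#'   incongruent trials. Default: all trials.
#' @param db Regress dB-scaled power (single-trial baseline) instead of raw.
#' @param baseline Baseline window for `db = TRUE`.
#' @return A `beta_map`: slope matrix (freqs x times, power units per z(RT)),
#'   with `freqs`, `times`, `n_trials`.
#' @export
tf_power_rt_regression <- function(tf, rts = NULL, trials = NULL, db = FALSE,
                                   baseline = c(-300, 0)) {
  stopifnot(inherits(tf, "tfr"))
  if (is.null(rts)) {
    if (is.null(tf$metadata) || is.null(tf$metadata$rt)) {
      abort("no `rts` given and no metadata RT available")
    }
    rts <- tf$metadata$rt
  }
  pw <- tf_power(tf)
  if (!is.null(trials)) {
    pw <- pw[trials, , , drop = FALSE]
    rts <- rts[trials]
  }
  n <- dim(pw)[1]
  if (n < 10L) abort("need at least 10 selected trials")
  if (sd(rts) == 0) abort("RT variance is zero; z-score undefined")
  if (db) {
    bidx <- time_index(tf$times, baseline)
    for (r in seq_len(n)) {
      bl <- rowMeans(pw[r, , bidx, drop = FALSE][, , , drop = TRUE])
      pw[r, , ] <- 10 * log10(sweep(pw[r, , , drop = FALSE][1, , ], 1, bl, "/"))
    }
  }
  z <- as.numeric(scale(rts))
  X <- matrix(pw, nrow = n)               # trials x (freq*time)
  beta <- as.numeric(crossprod(z, X)) / (n - 1)
  new_tf_map(matrix(beta, length(tf$freqs), length(tf$times)),
             tf$freqs, tf$times, class = "beta_map", n_trials = n)
}

#' @export
print.beta_map <- function(x, ...) {
  cat(sprintf("<beta_map> %d freqs x %d timepoints, %d trials, range %.3g..%.3g\n",
              length(x$freqs), length(x$times), x$n_trials,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
tidy.beta_map <- function(x, ...) {
  tibble(freq = rep(x$freqs, times = length(x$times)),
         time = rep(x$times, each = length(x$freqs)),
         beta = as.vector(x$values))
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false-discovery-rate control over the flattened input at level
#' `q` (default 0.01). Classic BH (independence) variant; set
#' `method = "BY"` for the dependency-robust variant.
#'
#' @param pvals Numeric vector, matrix or array of p-values in (0, 1].
#' @param q FDR level.
#' @param method `"BH"` (default) or `"BY"`.
#' @return Logical mask of rejected hypotheses, same shape as `pvals`.
#' @export
fdr_correct <- function(pvals, q = 0.01, method = c("BH", "BY")) {
  method <- match.arg(method)
  p <- as.vector(pvals)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  mask <- p.adjust(p, method = method) <= q
  if (!is.null(dim(pvals))) dim(mask) <- dim(pvals)
  mask
}

# Shared engine for the group-level pixelwise maps.
group_map_engine <- function(maps, maps2 = NULL, alpha = 0.01,
                             correction = c("fdr", "none"),
                             alternative = "two.sided") {
  correction <- match.arg(correction)
  vals <- purrr::map(maps, map_values)
  dims <- purrr::map(vals, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) != 1L) {
    abort("per-subject maps must share an identical grid")
  }
  if (length(vals) < 3L) abort("need at least 3 subjects")
  A <- do.call(rbind, purrr::map(vals, as.vector))
  if (!is.null(maps2)) {
    vals2 <- purrr::map(maps2, map_values)
    if (length(vals2) != length(vals)) abort("paired map sets differ in length")
    if (!identical(dim(vals2[[1]]), dim(vals[[1]]))) {
      abort("paired map sets must share an identical grid")
    }
    A <- A - do.call(rbind, purrr::map(vals2, as.vector))
  }
  bad <- !is.finite(A)
  if (any(bad)) {
    # subjects missing a pixel (e.g. excluded AR windows) drop out of that
    # pixel's test; pixels with fewer than 3 remaining subjects yield p = 1
    A0 <- ifelse(bad, 0, A)
    n_ok <- nrow(A) - colSums(bad)
    m <- colSums(A0) / pmax(n_ok, 1)
    ss <- colSums(A0^2) - n_ok * m^2
    s2 <- ss / pmax(n_ok - 1, 1)
    se <- sqrt(s2 / pmax(n_ok, 1))
    t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
    df <- pmax(n_ok - 1, 1)
    p <- switch(alternative,
                two.sided = 2 * pt(-abs(t), df),
                greater = pt(t, df, lower.tail = FALSE),
                less = pt(t, df))
    p <- zero_se_p(p, m, se == 0)
    p[n_ok < 3] <- 1
    t[n_ok < 3] <- 0
    res <- list(estimate = m, t = t, df = df, p = p)
  } else {
    res <- col_onesample_t(A, 0, alternative)
  }
  mask <- if (correction == "fdr") fdr_correct(res$p, alpha) else res$p < alpha
  shape <- dim(vals[[1]])
  list(estimate = matrix(colMeans(A), shape[1], shape[2]),
       t = matrix(res$t, shape[1], shape[2]),
       p = matrix(res$p, shape[1], shape[2]),
       mask = matrix(mask, shape[1], shape[2]),
       alpha = alpha, correction = correction, n_subjects = length(vals))
}

#' Group-level pixelwise statistics over subject maps
#'
#' One-sample (vs 0) or paired pixelwise t-tests across subjects' maps
#' (beta maps, ERSPs, PLV matrices, or plain matrices on a shared grid), with
#' multiple-comparison correction over all pixels jointly.
#'
#' @param maps List of per-subject maps.
#' @param mode `"one-sample"` (test `maps` against zero) or `"paired"` (test
#'   `maps` minus `maps2`).
#' @param maps2 Second map set for `mode = "paired"`.
#' @param alpha Significance/FDR level, default 0.01.
#' @param correction `"fdr"` (Benjamini-Hochberg, default) or `"none"`.
#' @return A `stat_map`: `estimate`, `t`, `p`, `mask` matrices plus grid and
#'   metadata. [tidy()] gives one row per pixel.
#' @export
group_stat_map <- function(maps, mode = c("one-sample", "paired"),
                           maps2 = NULL, alpha = 0.01,
                           correction = c("fdr", "none")) {
  mode <- match.arg(mode)
  if (mode == "paired" && is.null(maps2)) abort("`maps2` required for paired mode")
  if (mode == "one-sample") maps2 <- NULL
  eng <- group_map_engine(maps, maps2, alpha, correction, "two.sided")
  first <- maps[[1]]
  freqs <- if (is.matrix(first)) seq_len(nrow(map_values(first))) else first$freqs
  times <- if (is.matrix(first)) seq_len(ncol(map_values(first))) else first$times
  new_tf_map(eng$estimate, freqs, times, class = "stat_map",
             t = eng$t, p = eng$p, mask = eng$mask, alpha = eng$alpha,
             correction = eng$correction, n_subjects = eng$n_subjects,
             alternative = "two.sided")
}

#' One-sided group tests for Granger percent-change maps
#'
#' Pixelwise one-sample t-tests against zero with a one-sided
#' (greater-than) alternative — raw spectral Granger estimates cannot be
#' negative, so baseline increases are tested one-sided.
#'
#' @param estimates List of per-subject percent-change matrices (or
#'   `granger_estimate` objects).
#' @inheritParams group_stat_map
#' @return A `stat_map` (one-sided p-values).
#' @export
granger_onesided_tests <- function(estimates, alpha = 0.01,
                                   correction = c("fdr", "none")) {
  eng <- group_map_engine(estimates, NULL, alpha, correction, "greater")
  first <- estimates[[1]]
  freqs <- if (is.matrix(first)) seq_len(nrow(map_values(first))) else first$freqs
  times <- if (is.matrix(first)) seq_len(ncol(map_values(first))) else first$times
  new_tf_map(eng$estimate, freqs, times, class = "stat_map",
             t = eng$t, p = eng$p, mask = eng$mask, alpha = eng$alpha,
             correction = eng$correction, n_subjects = eng$n_subjects,
             alternative = "greater")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d freqs x %d timepoints, %d subjects, %s %s at %g\n",
              length(x$freqs), length(x$times), x$n_subjects,
              if (x$alternative == "greater") "one-sided" else "two-sided",
              x$correction, x$alpha))
  cat(sprintf("significant pixels: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
tidy.stat_map <- function(x, ...) {
  tibble(freq = rep(x$freqs, times = length(x$times)),
         time = rep(x$times, each = length(x$freqs)),
         estimate = as.vector(x$values), t = as.vector(x$t),
         p = as.vector(x$p), significant = as.vector(x$mask))
}

#' @export
glance.stat_map <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, alpha = x$alpha,
         correction = x$correction, alternative = x$alternative,
         n_significant = sum(x$mask), n_pixels = length(x$mask),
         min_p = min(x$p))
}
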