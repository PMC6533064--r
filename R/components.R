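# Functional-localizer logic: select the stop-signal "motor inhibition"
# independent component, back-project it, and detect single-condition P3
# onsets by the backwards-from-peak rule.

FRONTOCENTRAL <- c("FCz", "Cz", "C1", "C2", "FC1", "FC2")

#' Bundle an ICA decomposition with epoched data
#'
#' The decomposition itself is pluggable (any unmixing matrix — an external
#' infomax/FastICA fit, or the inverse of a known mixing matrix in
#' simulation); this container derives the back-projection maps
#' (pseudo-inverse of the unmixing) and the per-trial component activations.
#'
#' @param unmixing Components x channels unmixing matrix.
#' @param epochs An [epoch()]ed dataset the activations are computed from.
#' @return A `component_set`: `unmixing`, `maps` (channels x components),
#'   `activations` (trials x components x samples), `times`,
#'   `channel_names`, `metadata`.
#' @export
component_set <- function(unmixing, epochs) {
  stopifnot(inherits(epochs, "epochs"), is.matrix(unmixing))
  nchan <- dim(epochs$data)[2]
  if (ncol(unmixing) != nchan) {
    abort("`unmixing` must have one column per channel")
  }
  ncomp <- nrow(unmixing)
  d <- dim(epochs$data)
  act <- array(NA_real_, dim = c(d[1], ncomp, d[3]))
  for (r in seq_len(d[1])) {
    act[r, , ] <- unmixing %*% epochs$data[r, , ]
  }
  structure(
    list(unmixing = unmixing, maps = pinv(unmixing), activations = act,
         times = epochs$times, srate = epochs$srate,
         channel_names = epochs$channel_names, metadata = epochs$metadata),
    class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  d <- dim(x$activations)
  cat(sprintf("<component_set> %d components, %d trials x %d samples, %d channels\n",
              d[2], d[1], d[3], length(x$channel_names)))
  invisible(x)
}

#' Back-project a component into channel space
#'
#' Selective matrix multiplication of one map column with the component's
#' activation, averaged over the requested channels.
#'
#' @param components A [component_set()].
#' @param index Component index; `NULL` back-projects all components (their
#'   sum reconstructs the data).
#' @param channels Channel labels to average over (default FCz and Cz).
#' @return A trials x samples matrix of channel-averaged activity.
#' @export
backproject <- function(components, index = NULL,
                        channels = c("FCz", "Cz")) {
  stopifnot(inherits(components, "component_set"))
  ci <- match(channels, components$channel_names)
  if (anyNA(ci)) {
    abort(sprintf("unknown channel label(s): %s",
                  paste(channels[is.na(ci)], collapse = ", ")))
  }
  d <- dim(components$activations)
  if (is.null(index)) index <- seq_len(d[2])
  if (any(index < 1 | index > d[2])) abort("component index out of range")
  out <- matrix(0, d[1], d[3])
  for (k in index) {
    w <- mean(components$maps[ci, k])
    out <- out + w * components$activations[, k, ]
  }
  out
}

#' Select the motor-inhibition component
#'
#' Candidates are the components whose absolute map weight is maximal at one
#' of the six fronto-central channels (FCz, Cz, C1, C2, FC1, FC2). Each
#' candidate is back-projected to those channels, trial-averaged over the
#' 0-500 ms post-stop-signal window, and correlated with the all-components
#' ERP over the same channels and window; the candidate with the highest
#' correlation wins. Ties break to the lowest index (logged). Optionally all
#' candidates correlating above `corr_threshold` are returned (`multi =
#' TRUE`), mirroring datasets where two components split the P3.
#'
#' @param components A [component_set()] from stop-signal-locked epochs
#'   covering 0-500 ms.
#' @param window Correlation window in ms, default `c(0, 500)`.
#' @param multi Return all candidates above `corr_threshold` instead of just
#'   the best one.
#' @param corr_threshold Minimum ERP correlation for `multi` selection.
#' @return A `component_selection`: `selected` (index or indices),
#'   `candidates` tibble (`component`, `peak_channel`, `erp_correlation`).
#' @export
select_inhibition_component <- function(components, window = c(0, 500),
                                        multi = FALSE, corr_threshold = 0.5) {
  stopifnot(inherits(components, "component_set"))
  fc <- FRONTOCENTRAL
  if (!all(fc %in% components$channel_names)) {
    abort("channel set must contain the six fronto-central labels")
  }
  peak_chan <- components$channel_names[apply(abs(components$maps), 2, which.max)]
  cand <- which(peak_chan %in% fc)
  if (length(cand) == 0L) {
    abort("no fronto-central component: no component's maximal weight lies at FCz/Cz/C1/C2/FC1/FC2")
  }
  widx <- time_index(components$times, window)
  overall <- colMeans(backproject(components, NULL, fc))[widx]
  corr <- vapply(cand, function(k) {
    erp <- colMeans(backproject(components, k, fc))[widx]
    if (sd(erp) == 0 || sd(overall) == 0) return(-Inf)
    stats::cor(erp, overall)
  }, numeric(1))
  best <- cand[which.max(corr)]   # which.max: ties -> lowest index
  if (sum(corr == max(corr)) > 1L) {
    inform("correlation tie between candidate components; lowest index selected")
  }
  selected <- if (multi) cand[corr >= corr_threshold] else best
  if (multi && length(selected) == 0L) selected <- best
  structure(
    list(selected = selected,
         candidates = tibble(component = cand, peak_channel = peak_chan[cand],
                             erp_correlation = corr)),
    class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat("<component_selection> selected:", paste(x$selected, collapse = ", "), "\n")
  print(x$candidates)
  invisible(x)
}

#' @export
tidy.component_selection <- function(x, ...) {
  mutate(x$candidates, selected = .data$component %in% x$selected)
}

#' Detect a P3 onset by the backwards-from-peak rule
#'
#' Sample-by-sample comparison of stop-trial amplitudes against matched
#' go-trial amplitudes over 0-500 ms (Welch two-sample t by default, since
#' the matched go set is usually larger; `paired = TRUE` for 1:1 matchings).
#' The peak of the positive difference wave is located; if the test at the
#' peak is significant at `alpha`, the onset is the first sample of the
#' contiguous run of significant, positive samples containing the peak.
#'
#' @param stop_trials,matched_go_trials Trials x time amplitude matrices on a
#'   common time axis, go trials aligned to the would-be stop-signal time.
#' @param times Time axis in ms.
#' @param alpha Two-sided significance level per sample, default 0.01.
#' @param window Search window in ms, default `c(0, 500)`.
#' @param paired Use a paired test (requires equal trial counts).
#' @return An `onset_result`: `onset` (ms; `NA` with `reason` when the peak
#'   is not significant), `peak_latency`, `peak_significant`, `sig_mask`,
#'   `diff`, `times`.
#' @export
detect_p3_onset <- function(stop_trials, matched_go_trials, times,
                            alpha = 0.01, window = c(0, 500),
                            paired = FALSE) {
  stopifnot(is.matrix(stop_trials), is.matrix(matched_go_trials),
            ncol(stop_trials) == length(times),
            ncol(matched_go_trials) == length(times))
  widx <- time_index(times, window)
  A <- stop_trials[, widx, drop = FALSE]
  B <- matched_go_trials[, widx, drop = FALSE]
  res <- if (paired) col_paired_t(A, B) else col_welch_t(A, B)
  tw <- times[widx]
  dif <- res$estimate
  sig <- res$p < alpha & dif > 0
  peak <- which.max(dif)
  peak_sig <- isTRUE(sig[peak])
  onset <- NA_real_
  reason <- NA_character_
  if (!peak_sig) {
    reason <- "difference wave not significant at its peak"
  } else {
    i <- peak
    while (i > 1L && sig[i - 1L]) i <- i - 1L
    onset <- tw[i]
  }
  structure(
    list(onset = onset, peak_latency = tw[peak], peak_significant = peak_sig,
         sig_mask = sig, diff = dif, p = res$p, times = tw, alpha = alpha,
         reason = reason),
    class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$peak_significant) {
    cat(sprintf("<onset_result> onset %g ms (peak %g ms)\n",
                x$onset, x$peak_latency))
  } else {
    cat(sprintf("<onset_result> no onset: %s (peak %g ms)\n",
                x$reason, x$peak_latency))
  }
  invisible(x)
}

#' @export
tidy.onset_result <- function(x, ...) {
  tibble(time = x$times, diff = x$diff, p = x$p, significant = x$sig_mask)
}

#' @export
glance.onset_result <- function(x, ...) {
  tibble(onset = x$onset, peak_latency = x$peak_latency,
         peak_significant = x$peak_significant, alpha = x$alpha)
}

#' Group-level onset comparisons
#'
#' Paired t-test of per-subject P3 onsets between successful and failed
#' stop trials, and the across-subject Pearson correlation of
#' successful-stop onsets with SSRT.
#'
#' @param onsets_success,onsets_fail Per-subject onsets (ms), equal length.
#' @param ssrt Optional per-subject SSRT (ms) for the onset-SSRT correlation.
#' @return A tibble with the paired contrast (`mean_diff`, `t`, `df`, `p`)
#'   and, when `ssrt` is given, `r_onset_ssrt` and `p_cor`.
#' @export
onset_group_tests <- function(onsets_success, onsets_fail, ssrt = NULL) {
  if (length(onsets_success) != length(onsets_fail)) {
    abort("onset vectors must have the same length")
  }
  if (length(onsets_success) < 3L) abort("need at least 3 subjects")
  d <- onsets_fail - onsets_success
  out <- if (sd(d) == 0) {
    # constant difference: noise-free limit
    tibble(mean_diff = mean(d),
           t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
           df = length(d) - 1,
           p = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- t.test(d)
    tibble(mean_diff = mean(d), t = unname(tt$statistic),
           df = unname(tt$parameter), p = tt$p.value)
  }
  if (!is.null(ssrt)) {
    if (length(ssrt) != length(onsets_success)) {
      abort("`ssrt` must have one value per subject")
    }
    ct <- cor.test(onsets_success, ssrt)
    out$r_onset_ssrt <- unname(ct$estimate)
    out$p_cor <- ct$p.value
  }
  out
}
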