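# MEP screening, peak-to-peak quantification, baseline normalization, and
# condition contrasts.

#' Peak-to-peak MEP amplitude
#'
#' Difference between the maximum and minimum of the sweep within the window
#' `(pulse_time + 10, pulse_time + 50]` ms.
#'
#' @param sweep Numeric EMG sweep (mV).
#' @param pulse_time Pulse latency in ms from sweep start.
#' @param srate Sampling rate (Hz).
#' @return Peak-to-peak amplitude in mV.
#' @export
mep_amplitude <- function(sweep, pulse_time = 150, srate = 1000) {
  t_ms <- (seq_along(sweep) - 1) * 1000 / srate - pulse_time
  idx <- which(t_ms > 10 & t_ms <= 50)
  if (length(idx) == 0L || max(t_ms) < 50) {
    abort("MEP search window (10-50 ms post-pulse) outside the sweep")
  }
  max(sweep[idx]) - min(sweep[idx])
}

#' Screen EMG sweeps and quantify MEPs
#'
#' Applies the two screening rules: a sweep is rejected with reason
#' `"pre-pulse RMS"` when the RMS of the 100 ms preceding the pulse exceeds
#' `rms_limit` (strictly greater), and with reason `"amplitude floor"` when
#' its peak-to-peak MEP amplitude does not exceed `amp_floor`. Accepted
#' sweeps carry their amplitude; rejected sweeps carry `NA`.
#'
#' @param trials A sweep tibble from [gen_emg_sweeps()] (columns `sweep`,
#'   `pulse_time`, `srate`).
#' @param rms_limit Pre-pulse RMS threshold (mV), default 0.01.
#' @param amp_floor Minimum MEP amplitude (mV), default 0.01.
#' @return The input with `rejected`, `reason`, `amplitude` columns added.
#' @export
reject_emg_trials <- function(trials, rms_limit = 0.01, amp_floor = 0.01) {
  assert_columns(trials, c("sweep", "pulse_time", "srate"), "sweep table")
  res <- purrr::pmap_dfr(
    list(trials$sweep, trials$pulse_time, trials$srate),
    function(sw, pt, sr) {
      t_ms <- (seq_along(sw) - 1) * 1000 / sr - pt
      pre <- which(t_ms >= -100 & t_ms < 0)
      if (length(pre) < ms_to_samples(100, sr)) {
        abort("sweep does not cover the 100 ms pre-pulse window")
      }
      rms <- sqrt(mean(sw[pre]^2))
      amp <- mep_amplitude(sw, pt, sr)
      if (rms > rms_limit) {
        tibble(rejected = TRUE, reason = "pre-pulse RMS", amplitude = NA_real_)
      } else if (amp <= amp_floor) {
        tibble(rejected = TRUE, reason = "amplitude floor", amplitude = NA_real_)
      } else {
        tibble(rejected = FALSE, reason = NA_character_, amplitude = amp)
      }
    })
  dplyr::bind_cols(trials, res)
}

#' Baseline-normalized condition summaries of MEP amplitudes
#'
#' Per-condition location statistic (median by default, mean optional — both
#' conventions appear in the field) of accepted amplitudes, divided by the
#' same statistic over accepted baseline sweeps.
#'
#' @param trials A flagged sweep tibble from [reject_emg_trials()].
#' @param stat `"median"` (default) or `"mean"`.
#' @return A tibble with one row per condition: `condition`, `n_used`,
#'   `amplitude` (raw) and `normalized` (baseline-relative; baseline = 1 by
#'   construction).
#' @export
summarize_meps <- function(trials, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  assert_columns(trials, c("condition", "rejected", "amplitude"), "sweep table")
  fn <- if (stat == "median") median else mean
  acc <- trials[!trials$rejected, ]
  conds <- unique(trials$condition)
  for (cc in conds) {
    if (sum(acc$condition == cc) == 0L) {
      abort(sprintf("no accepted sweeps in condition '%s'", cc))
    }
  }
  if (!"baseline" %in% conds) abort("no accepted sweeps in condition 'baseline'")
  base <- fn(acc$amplitude[acc$condition == "baseline"])
  acc %>%
    group_by(condition = .data$condition) %>%
    summarise(n_used = dplyr::n(), amplitude = fn(.data$amplitude),
              .groups = "drop") %>%
    mutate(normalized = .data$amplitude / base)
}

#' Group-level MEP condition contrasts
#'
#' Paired t-test of incongruent vs congruent normalized amplitudes, one-sample
#' t-tests of each condition against the baseline value 1, and (when per-
#' subject RT slowing is supplied) the across-subject Pearson correlation of
#' MEP suppression with RT slowing.
#'
#' @param summaries A tibble of per-subject normalized summaries: columns
#'   `subject`, `condition`, `normalized` (long format, as from stacking
#'   [summarize_meps()] outputs).
#' @param slowing Optional named/per-subject vector of RT slowing
#'   (incongruent - congruent, ms), aligned with the subject order.
#' @return A `mep_contrast` list: `$paired` (incongruent vs congruent),
#'   `$vs_baseline` (per condition), `$slowing_cor` (or `NULL`).
#' @export
compare_conditions <- function(summaries, slowing = NULL) {
  assert_columns(summaries, c("subject", "condition", "normalized"),
                 "summary table")
  wide <- summaries %>%
    filter(.data$condition %in% c("congruent", "incongruent")) %>%
    tidyr::pivot_wider(id_cols = "subject", names_from = "condition",
                       values_from = "normalized")
  if (anyNA(wide$congruent) || anyNA(wide$incongruent)) {
    abort("every subject needs both congruent and incongruent summaries")
  }
  if (nrow(wide) < 3L) abort("need at least 3 subjects")
  safe_t <- function(v, mu = 0) {
    if (sd(v) == 0) {
      delta <- mean(v) - mu
      return(list(t = if (delta == 0) 0 else sign(delta) * Inf,
                  df = length(v) - 1, p = if (delta == 0) 1 else 0))
    }
    tt <- t.test(v, mu = mu)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  d <- wide$incongruent - wide$congruent
  tt <- safe_t(d)
  paired <- tibble(mean_diff = mean(d), t = tt$t, df = tt$df, p = tt$p,
                   cohens_d = if (sd(d) == 0) NA_real_ else cohens_d_paired(d))
  vs_baseline <- purrr::map_dfr(c("congruent", "incongruent"), function(cc) {
    v <- wide[[cc]]
    bt <- safe_t(v, mu = 1)
    tibble(condition = cc, mean = mean(v), t = bt$t, df = bt$df, p = bt$p)
  })
  slowing_cor <- NULL
  if (!is.null(slowing)) {
    if (length(slowing) != nrow(wide)) {
      abort("`slowing` must have one value per subject")
    }
    suppression <- wide$congruent - wide$incongruent
    ct <- cor.test(suppression, slowing)
    slowing_cor <- tibble(r = unname(ct$estimate), p = ct$p.value,
                          n = nrow(wide))
  }
  structure(list(paired = paired, vs_baseline = vs_baseline,
                 slowing_cor = slowing_cor),
            class = "mep_contrast")
}

#' @export
print.mep_contrast <- function(x, ...) {
  cat("<mep_contrast> incongruent vs congruent:\n")
  print(x$paired)
  cat("vs baseline (=1):\n")
  print(x$vs_baseline)
  if (!is.null(x$slowing_cor)) {
    cat("suppression ~ RT slowing:\n")
    print(x$slowing_cor)
  }
  invisible(x)
}

#' @export
tidy.mep_contrast <- function(x, ...) {
  bind_rows(
    mutate(x$paired, term = "incongruent - congruent", .before = 1),
    mutate(select(x$vs_baseline, mean_diff = "mean", "t", "df", "p"),
           term = paste(x$vs_baseline$condition, "vs baseline"), .before = 1))
}
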