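# Behavioral summaries and estimators: condition contrasts, race-model
# ordering, integration-method SSRT, and staircase-matched go trials.

#' Condition-level Simon summary
#'
#' Correct-trial RT mean and SEM per condition, error rates, and the
#' congruency contrast. Given a list of per-subject tables, the contrast is a
#' group-level paired t-test across subjects with Cohen's d.
#'
#' @param table A behavior tibble (as from [gen_simon_behavior()]) or a list
#'   of such tibbles, one per subject.
#' @return A `simon_summary`: `$conditions` tibble (per condition: `n`,
#'   `mean_rt`, `sem_rt`, `err_rate`) and `$contrast` one-row tibble
#'   (`rt_diff`, `err_diff`, and for multi-subject input `t`, `df`, `p`,
#'   `cohens_d`).
#' @export
simon_summary <- function(table) {
  if (is.data.frame(table)) {
    conds <- simon_condition_stats(table)
    contrast <- tibble(
      rt_diff = conds$mean_rt[conds$condition == "incongruent"] -
        conds$mean_rt[conds$condition == "congruent"],
      err_diff = conds$err_rate[conds$condition == "incongruent"] -
        conds$err_rate[conds$condition == "congruent"])
  } else {
    per <- purrr::map(table, simon_condition_stats)
    conds <- bind_rows(per, .id = "subject") %>%
      group_by(.data$condition) %>%
      summarise(n = sum(.data$n),
                sem_rt = sd(.data$mean_rt) / sqrt(dplyr::n()),
                mean_rt = mean(.data$mean_rt),
                err_rate = mean(.data$err_rate), .groups = "drop") %>%
      select("condition", "n", "mean_rt", "sem_rt", "err_rate")
    diffs <- purrr::map_dbl(per, function(s) {
      s$mean_rt[s$condition == "incongruent"] -
        s$mean_rt[s$condition == "congruent"]
    })
    tt <- t.test(diffs)
    contrast <- tibble(
      rt_diff = mean(diffs),
      err_diff = conds$err_rate[conds$condition == "incongruent"] -
        conds$err_rate[conds$condition == "congruent"],
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, cohens_d = cohens_d_paired(diffs))
  }
  structure(list(conditions = conds, contrast = contrast),
            class = "simon_summary")
}

simon_condition_stats <- function(table) {
  assert_columns(table, c("condition", "rt", "correct"))
  out <- purrr::map_dfr(c("congruent", "incongruent"), function(cc) {
    sub <- table[table$condition == cc & !is.na(table$condition), ]
    ok <- sub[sub$correct & !is.na(sub$rt), ]
    if (nrow(ok) < 2L) {
      abort(sprintf("fewer than 2 correct trials in condition '%s'", cc))
    }
    tibble(condition = cc, n = nrow(sub),
           mean_rt = mean(ok$rt), sem_rt = sd(ok$rt) / sqrt(nrow(ok)),
           err_rate = mean(!sub$correct))
  })
  out
}

#' @export
print.simon_summary <- function(x, ...) {
  cat("<simon_summary>\n")
  print(x$conditions)
  cat("contrast (incongruent - congruent):\n")
  print(x$contrast)
  invisible(x)
}

#' @export
tidy.simon_summary <- function(x, ...) x$conditions

#' @export
glance.simon_summary <- function(x, ...) x$contrast

#' Race-model ordering check
#'
#' The independent-race account requires the mean RT of failed stop trials to
#' be faster than the mean correct go RT.
#'
#' @param table A stop-signal behavior tibble.
#' @return One-row tibble: `mean_go_rt`, `mean_failed_stop_rt`, `race_ok`
#'   (logical, `NA` with a `reason` when there are no failed stops).
#' @export
race_model_check <- function(table) {
  assert_columns(table, c("condition", "rt", "correct", "stop_outcome"))
  go_rt <- table$rt[table$condition == "go" & table$correct & !is.na(table$rt)]
  fs_rt <- table$rt[!is.na(table$stop_outcome) &
                      table$stop_outcome == "fail" & !is.na(table$rt)]
  if (length(go_rt) < 1L) abort("no correct go trials with RT")
  if (length(fs_rt) < 1L) {
    return(tibble(mean_go_rt = mean(go_rt), mean_failed_stop_rt = NA_real_,
                  race_ok = NA, reason = "no failed stop trials"))
  }
  tibble(mean_go_rt = mean(go_rt), mean_failed_stop_rt = mean(fs_rt),
         race_ok = mean(fs_rt) < mean(go_rt), reason = NA_character_)
}

#' Integration-method SSRT
#'
#' The stop-signal reaction time is estimated by the integration method: the
#' go-RT distribution is integrated up to the observed probability of
#' responding on stop trials, and the mean SSD is subtracted from that
#' quantile. The quantile convention is the `ceiling(p * n_go)`-th order
#' statistic of the correct go RTs (no interpolation); set
#' `quantile_type = "interp"` for interpolated (type-7) quantiles.
#'
#' @param table A stop-signal behavior tibble.
#' @param quantile_type `"order"` (default) or `"interp"`.
#' @param by_side If `TRUE`, estimate per go direction and average; the
#'   default pools both directions' SSDs and go RTs.
#' @return An `ssrt_estimate` tibble row: `ssrt`, `p_respond_given_stop`,
#'   `mean_ssd`, `go_quantile_rt`, `n_go`, `n_stop`.
#' @export
ssrt_integration <- function(table, quantile_type = c("order", "interp"),
                             by_side = FALSE) {
  quantile_type <- match.arg(quantile_type)
  assert_columns(table, c("condition", "side", "rt", "correct",
                          "ssd", "stop_outcome"))
  if (by_side) {
    est <- purrr::map_dfr(c("left", "right"), function(s) {
      ssrt_integration(table[table$side == s, ], quantile_type, by_side = FALSE)
    })
    out <- tibble(ssrt = mean(est$ssrt),
                  p_respond_given_stop = mean(est$p_respond_given_stop),
                  mean_ssd = mean(est$mean_ssd),
                  go_quantile_rt = mean(est$go_quantile_rt),
                  n_go = sum(est$n_go), n_stop = sum(est$n_stop))
    class(out) <- c("ssrt_estimate", class(out))
    return(out)
  }
  stop_rows <- table[table$condition == "stop" & !is.na(table$stop_outcome), ]
  go_rt <- table$rt[table$condition == "go" & table$correct & !is.na(table$rt)]
  if (nrow(stop_rows) < 1L) abort("no stop trials")
  if (length(go_rt) < 10L) abort("need at least 10 correct go RTs")
  p_resp <- mean(stop_rows$stop_outcome == "fail")
  if (p_resp <= 0 || p_resp >= 1) {
    abort("p(respond | stop) must lie strictly in (0, 1); estimator undefined")
  }
  mean_ssd <- mean(stop_rows$ssd)
  go_sorted <- sort(go_rt)
  go_q <- if (quantile_type == "order") {
    go_sorted[ceiling(p_resp * length(go_sorted))]
  } else {
    unname(quantile(go_sorted, p_resp, type = 7))
  }
  out <- tibble(ssrt = go_q - mean_ssd, p_respond_given_stop = p_resp,
                mean_ssd = mean_ssd, go_quantile_rt = go_q,
                n_go = length(go_rt), n_stop = nrow(stop_rows))
  class(out) <- c("ssrt_estimate", class(out))
  out
}

#' Match go trials to stop trials by staircase position
#'
#' For each stop trial, the matched go set consists of the go trials in the
#' same direction whose recorded staircase SSD equals that stop trial's SSD
#' (SSDs live on the staircase's step grid, so matching is exact equality).
#'
#' @param table A stop-signal behavior tibble carrying `staircase_ssd` on go
#'   trials.
#' @return A tibble with one row per stop trial: `stop_trial`, `side`, `ssd`,
#'   `n_matched`, and list-column `go_trials` of matched go trial ids. Empty
#'   match sets produce a warning, not an error.
#' @export
match_go_trials <- function(table) {
  assert_columns(table, c("trial", "condition", "side", "ssd", "staircase_ssd"))
  stops <- table[table$condition == "stop", ]
  gos <- table[table$condition == "go", ]
  out <- purrr::map_dfr(seq_len(nrow(stops)), function(i) {
    hit <- gos$trial[gos$side == stops$side[i] &
                       !is.na(gos$staircase_ssd) &
                       gos$staircase_ssd == stops$ssd[i]]
    tibble(stop_trial = stops$trial[i], side = stops$side[i],
           ssd = stops$ssd[i], n_matched = length(hit),
           go_trials = list(hit))
  })
  if (any(out$n_matched == 0L)) {
    warn(sprintf("%d stop trial(s) have no staircase-matched go trials",
                 sum(out$n_matched == 0L)))
  }
  out
}
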