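# End-to-end experiment recipes over synthetic cohorts.

#' Pipeline configuration
#'
#' Bundles cohort size, module parameter blocks and the root seed for the
#' three experiment recipes. Analysis defaults resolve to the study
#' conventions: FDR q = 0.01, Granger order 50 with 200 ms windows on a
#' 21-point 10-30 Hz grid, dB/PLV baselines of -300 to 0 ms.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param n_subjects Cohort size.
#' @param seed Root seed; every per-subject generator derives a substream
#'   from it.
#' @param simon,race,coupling,mep Parameter blocks ([simon_params()],
#'   [race_params()], [coupling_params()], [mep_params()]).
#' @param n_trials_simon,n_go,n_stop Per-subject trial counts. The simulated
#'   session sizes default to a compact demonstration scale
#'   (`n_trials_simon = 192`, 120 go / 60 stop trials); full-study sizes
#'   (768, 200/100) are a configuration away.
#' @param n_channels EEG channel count for exp1.
#' @param alpha Significance/FDR level.
#' @param granger_step Granger window step (ms) for exp2.
#' @param timepoints CSE probe timepoints (ms) for exp3.
#' @param suppress_at Timepoint at which MEP suppression is planted.
#' @return A `run_config` list.
#' @export
run_config <- function(experiment = c("exp1", "exp2", "exp3"),
                       n_subjects = 6, seed = 1,
                       simon = simon_params(), race = race_params(),
                       coupling = coupling_params(), mep = mep_params(),
                       n_trials_simon = 192, n_go = 120, n_stop = 60,
                       n_channels = 8, alpha = 0.01, granger_step = 20,
                       timepoints = 250, suppress_at = 250) {
  experiment <- match.arg(experiment)
  cfg <- list(experiment = experiment, n_subjects = n_subjects, seed = seed,
              simon = simon, race = race, coupling = coupling, mep = mep,
              n_trials_simon = n_trials_simon, n_go = n_go, n_stop = n_stop,
              n_channels = n_channels, alpha = alpha,
              granger_step = granger_step, timepoints = timepoints,
              suppress_at = suppress_at)
  class(cfg) <- "run_config"
  cfg
}

subject_seed <- function(config, s, what) {
  child_seed(child_seed(config$seed, what), paste0("s", s))
}

provenance <- function(config) {
  list(seed = config$seed, experiment = config$experiment,
       config_hash = rlang::hash(unclass(config)),
       package_version = as.character(utils::packageVersion("conflictr")))
}

# Stop-locked and matched-go amplitude matrices for one session.
stop_go_amplitudes <- function(eeg, behavior, unmixing, window = c(0, 500)) {
  ev <- eeg$events
  stop_idx <- which(!is.na(ev$stop_sample))
  ep_stop <- epoch(eeg, ev$stop_sample[stop_idx], c(-100, 600),
                   behavior[stop_idx, ])
  cs <- component_set(unmixing, ep_stop)
  sel <- select_inhibition_component(cs)
  bp_stop <- backproject(cs, sel$selected[1])
  go_idx <- which(behavior$condition == "go")
  go_lock <- ev$sample[go_idx] +
    ms_to_samples(behavior$staircase_ssd[go_idx], eeg$srate)
  ep_go <- epoch(eeg, go_lock, c(-100, 600), behavior[go_idx, ])
  cs_go <- component_set(unmixing, ep_go)
  bp_go <- backproject(cs_go, sel$selected[1])
  list(selection = sel, times = ep_stop$times,
       stop = bp_stop, stop_meta = behavior[stop_idx, ],
       go = bp_go, go_meta = behavior[go_idx, ])
}

onset_for_outcome <- function(amps, matches, outcome, alpha = 0.01) {
  keep <- amps$stop_meta$stop_outcome == outcome
  matched_ids <- unique(unlist(matches$go_trials[
    matches$stop_trial %in% amps$stop_meta$trial[keep]]))
  go_keep <- amps$go_meta$trial %in% matched_ids
  if (sum(go_keep) < 2L || sum(keep) < 2L) {
    abort(sprintf("too few trials to detect the %s-stop onset", outcome))
  }
  detect_p3_onset(amps$stop[keep, , drop = FALSE],
                  amps$go[go_keep, , drop = FALSE],
                  amps$times, alpha = alpha)
}

#' Run the scalp-EEG experiment recipe on a synthetic cohort
#'
#' Per subject: simulate a stop-signal session and a Simon session sharing
#' one EEG forward model, select the fronto-central inhibition component
#' (ground-truth unmixing injected by default; pass `ica` for an external
#' decomposition), detect P3 onsets for successful and failed stops, and run
#' the single-trial time-frequency RT regression on correct incongruent
#' Simon trials. Group level: onset comparison, SSRT correlation, ERSP
#' condition contrast, and the FDR-masked group regression map.
#'
#' @param config A [run_config()].
#' @param ica Optional function `(epochs) -> unmixing matrix`; default
#'   injects the pseudo-inverse of the true mixing.
#' @return An `exp_report` list with per-subject and group-level results.
#' @export
run_exp1 <- function(config = run_config("exp1"), ica = NULL) {
  subjects <- seq_len(config$n_subjects)
  per <- purrr::map(subjects, function(s) {
    sst <- gen_stop_signal_session(config$race, config$n_go, config$n_stop,
                                   seed = subject_seed(config, s, "sst"))
    eeg <- gen_scalp_eeg(sst, n_channels = config$n_channels,
                         seed = subject_seed(config, s, "eeg_sst"))
    mixing <- attr(eeg, "truth")$mixing
    unmixing <- if (is.null(ica)) pinv(mixing) else NULL
    amps <- if (is.null(unmixing)) {
      ep <- epoch(eeg, eeg$events$sample, c(-100, 600), sst)
      stop_go_amplitudes(eeg, sst, ica(ep))
    } else stop_go_amplitudes(eeg, sst, unmixing)
    matches <- match_go_trials(sst)
    on_s <- onset_for_outcome(amps, matches, "success", config$alpha)
    on_f <- onset_for_outcome(amps, matches, "fail", config$alpha)
    ssrt <- ssrt_integration(sst)

    simon <- gen_simon_behavior(config$simon, config$n_trials_simon,
                                seed = subject_seed(config, s, "simon"))
    eeg2 <- gen_scalp_eeg(simon, n_channels = config$n_channels,
                          params = config$simon, mixing = mixing,
                          seed = subject_seed(config, s, "eeg_simon"))
    ep2 <- epoch(eeg2, eeg2$events$sample, c(-500, 900), simon)
    cs2 <- component_set(if (is.null(unmixing)) ica(ep2) else unmixing, ep2)
    comp_ts <- backproject(cs2, amps$selection$selected[1])
    tf <- filter_hilbert(comp_ts, srate = eeg2$srate, times = ep2$times)
    tf$metadata <- simon
    keep_t <- tf$times >= -300 & tf$times < 700
    tf$analytic <- tf$analytic[, , keep_t, drop = FALSE]
    tf$times <- tf$times[keep_t]
    inc <- simon$condition == "incongruent" & simon$correct
    con <- simon$condition == "congruent" & simon$correct
    list(selection = amps$selection,
         onset_success = on_s$onset, onset_fail = on_f$onset,
         ssrt = ssrt$ssrt,
         ersp_incongruent = ersp(tf, trials = inc),
         ersp_congruent = ersp(tf, trials = con),
         beta_map = tf_power_rt_regression(tf, simon$rt, trials = inc),
         behavior = simon_summary(simon))
  })
  onsets_s <- purrr::map_dbl(per, "onset_success")
  onsets_f <- purrr::map_dbl(per, "onset_fail")
  ssrts <- purrr::map_dbl(per, "ssrt")
  group <- list(
    onset_tests = onset_group_tests(onsets_s, onsets_f, ssrts),
    ersp_contrast = group_stat_map(
      purrr::map(per, "ersp_incongruent"), "paired",
      purrr::map(per, "ersp_congruent"), alpha = config$alpha),
    regression = group_stat_map(purrr::map(per, "beta_map"),
                                alpha = config$alpha))
  lowfreq <- group$regression$freqs >= 2 & group$regression$freqs <= 8
  structure(
    list(config = config, provenance = provenance(config), subjects = per,
         group = group,
         flags = list(
           onset_order_recovered = mean(onsets_f - onsets_s) > 0 &&
             group$onset_tests$p < 0.05,
           regression_cluster_recovered =
             sum(group$regression$mask[lowfreq, ]) > 0)),
    class = "exp_report")
}

#' Run the intracranial connectivity recipe on a synthetic cohort
#'
#' Per subject: simulate Simon behavior and the STN/M1 LFP pair, embed both
#' signals into synthetic 4-contact arrays, rebuild them through bipolar
#' montage construction and contact selection, then compute the
#' incongruent-congruent PLV contrast and the incongruent-trial Granger
#' time course. Group level: paired PLV test and one-sided Granger tests.
#'
#' @param config A [run_config()].
#' @param n_trials Simon trials per subject (default 96).
#' @return An `exp_report`.
#' @export
run_exp2 <- function(config = run_config("exp2"), n_trials = 96) {
  subjects <- seq_len(config$n_subjects)
  band <- c(config$coupling$band_lo, config$coupling$band_hi)
  per <- purrr::map(subjects, function(s) {
    beh <- gen_simon_behavior(config$simon, n_trials,
                              seed = subject_seed(config, s, "simon"))
    pair <- gen_lfp_pair(beh, config$coupling,
                         seed = subject_seed(config, s, "lfp"))
    # montage construction + resting beta selection on a synthetic array
    arr <- gen_contact_array(pair$stn, target = 2,
                             seed = subject_seed(config, s, "arr"))
    bip <- make_bipolar(arr)
    rest_lead <- new_recording(
      bip$data[, seq_len(6 * bip$srate), drop = FALSE] +
        rbind(0, sin(2 * pi * 20 * seq_len(6 * bip$srate) / bip$srate) * 0.3, 0),
      bip$srate, bip$channel_names)
    stn_sel <- select_stn_contact(rest_lead)
    stn <- new_recording(bip$data[stn_sel$selected, , drop = FALSE],
                         bip$srate, "STN", bip$events)
    ev <- pair$stn$events$sample
    tf_x <- filter_hilbert(stn, freqs = 1:30, events = ev,
                           window = c(-400, 600), metadata = beh)
    tf_y <- filter_hilbert(pair$m1, freqs = 1:30, events = ev,
                           window = c(-400, 600), metadata = beh)
    inc <- beh$condition == "incongruent" & beh$correct
    con <- beh$condition == "congruent" & beh$correct
    sub_tf <- function(tf, keep) {
      tf$analytic <- tf$analytic[keep, , , drop = FALSE]
      tf
    }
    plv_inc <- plv(sub_tf(tf_x, inc), sub_tf(tf_y, inc), baseline = c(-300, 0))
    plv_con <- plv(sub_tf(tf_x, con), sub_tf(tf_y, con), baseline = c(-300, 0))
    ep_x <- epoch(stn, ev, c(-400, 600), beh)
    ep_y <- epoch(pair$m1, ev, c(-400, 600), beh)
    g <- granger_timecourse(ep_x, ep_y, step = config$granger_step,
                            trials = inc)
    list(stn_selection = stn_sel, plv_incongruent = plv_inc,
         plv_congruent = plv_con, granger = g)
  })
  group <- list(
    plv_contrast = group_stat_map(
      purrr::map(per, "plv_incongruent"), "paired",
      purrr::map(per, "plv_congruent"), alpha = config$alpha),
    granger_xy = granger_onesided_tests(
      purrr::map(per, ~.x$granger$pct$xy), alpha = config$alpha),
    granger_yx = granger_onesided_tests(
      purrr::map(per, ~.x$granger$pct$yx), alpha = config$alpha))
  win <- c(config$coupling$window_lo, config$coupling$window_hi)
  dir_means <- purrr::map_dfr(per, function(p) {
    tibble(xy = granger_window_mean(p$granger, "xy", band, win),
           yx = granger_window_mean(p$granger, "yx", band, win))
  })
  structure(
    list(config = config, provenance = provenance(config), subjects = per,
         group = group,
         flags = list(
           directionality_recovered = mean(dir_means$xy > dir_means$yx) > 0.5,
           stn_montage_hit_rate =
             mean(purrr::map_int(per, ~.x$stn_selection$selected) == 2L))),
    class = "exp_report")
}

#' Run the TMS/MEP recipe on a synthetic cohort
#'
#' Per subject and probe timepoint: simulate Simon behavior and EMG sweeps
#' (suppression planted only at `suppress_at`), screen sweeps, quantify and
#' normalize MEPs. Group level: per-timepoint condition contrasts and the
#' across-subject correlation of MEP suppression with RT slowing.
#'
#' @param config A [run_config()].
#' @param n_trials Simon trials per subject per timepoint (default 96).
#' @return An `exp_report`.
#' @export
run_exp3 <- function(config = run_config("exp3"), n_trials = 96) {
  subjects <- seq_len(config$n_subjects)
  per <- purrr::map(subjects, function(s) {
    beh <- gen_simon_behavior(config$simon, n_trials,
                              seed = subject_seed(config, s, "simon"))
    sums <- purrr::map_dfr(config$timepoints, function(tp) {
      p <- config$mep
      p$pulse_time <- tp
      if (tp != config$suppress_at) p$suppression_factor <- 1
      sweeps <- gen_emg_sweeps(beh, p,
                               seed = subject_seed(config, s,
                                                   paste0("emg", tp)))
      mutate(summarize_meps(reject_emg_trials(sweeps)), timepoint = tp)
    })
    sm <- simon_summary(beh)
    list(summaries = sums, slowing = sm$contrast$rt_diff)
  })
  long <- purrr::imap_dfr(per, function(p, s) {
    mutate(p$summaries, subject = as.character(s))
  })
  slowing <- purrr::map_dbl(per, "slowing")
  contrasts <- purrr::map(config$timepoints, function(tp) {
    compare_conditions(filter(long, .data$timepoint == tp),
                       slowing = if (tp == config$suppress_at) slowing)
  })
  names(contrasts) <- paste0("t", config$timepoints)
  sig_at <- purrr::map_lgl(contrasts, ~.x$paired$p < 0.05)
  structure(
    list(config = config, provenance = provenance(config), subjects = per,
         group = list(contrasts = contrasts),
         flags = list(
           suppression_recovered =
             sig_at[[paste0("t", config$suppress_at)]] &&
             sum(sig_at) == sum(config$timepoints == config$suppress_at))),
    class = "exp_report")
}

#' @export
print.exp_report <- function(x, ...) {
  cat(sprintf("<exp_report> %s, %d subjects, seed %d\n",
              x$config$experiment, x$config$n_subjects, x$config$seed))
  for (f in names(x$flags)) cat(sprintf("  %s: %s\n", f, x$flags[[f]]))
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' Writes flags, provenance and compact group-level summaries (not the raw
#' per-subject arrays) so runs can be compared and archived.
#'
#' @param report An `exp_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "exp_report"))
  summ <- list(provenance = report$provenance, flags = report$flags)
  g <- report$group
  if (!is.null(g$onset_tests)) summ$onset_tests <- as.list(g$onset_tests)
  for (nm in intersect(names(g), c("ersp_contrast", "regression",
                                   "plv_contrast", "granger_xy",
                                   "granger_yx"))) {
    summ[[nm]] <- as.list(glance(g[[nm]]))
  }
  if (!is.null(g$contrasts)) {
    summ$contrasts <- purrr::map(g$contrasts, ~as.list(.x$paired))
  }
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
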