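# Synthetic task behavior: Simon-task congruency effects and stop-signal
# sessions governed by an independent race with a staircased SSD.

#' Parameter blocks for the synthetic generators
#'
#' Constructors that validate and default the ground-truth parameters of the
#' behavioral, EEG, LFP and EMG simulators. Defaults are the study's operating
#' point: congruent RT 326 ms with a 35 ms congruency cost and error rates of
#' 10.38% / 22.67%; an ex-Gaussian go process averaging ~470 ms with a true
#' stop latency of 238 ms and a 50 ms staircase starting at 200 ms; a
#' transient 18-22 Hz STN->M1 coupling at 180-240 ms post-stimulus; and MEPs
#' suppressed to 0.8 of baseline on incongruent trials.
#'
#' @param mean_rt_congruent,congruency_delta,rt_sd Congruent-trial mean RT,
#'   incongruent slowing, and trial-to-trial RT standard deviation (ms).
#' @param err_rate_congruent,err_rate_incongruent Per-condition error rates.
#' @param rt_effect_gain Planted coupling (power units per z(RT)) between
#'   incongruent-trial slowing and the inhibition source's burst amplitude.
#' @return A named list of validated parameters.
#' @export
simon_params <- function(mean_rt_congruent = 326, congruency_delta = 35,
                         rt_sd = 80, err_rate_congruent = 0.1038,
                         err_rate_incongruent = 0.2267, rt_effect_gain = 0.5) {
  assert_scalar_number(mean_rt_congruent, "mean_rt_congruent", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(rt_sd, "rt_sd", lower = 0, strict_lower = TRUE)
  assert_scalar_number(err_rate_congruent, "err_rate_congruent", 0, 1)
  assert_scalar_number(err_rate_incongruent, "err_rate_incongruent", 0, 1)
  if (mean_rt_congruent + congruency_delta <= 0) {
    abort("incongruent mean RT must be positive")
  }
  list(mean_rt_congruent = mean_rt_congruent,
       congruency_delta = congruency_delta, rt_sd = rt_sd,
       err_rate_congruent = err_rate_congruent,
       err_rate_incongruent = err_rate_incongruent,
       rt_effect_gain = rt_effect_gain)
}

#' @rdname simon_params
#' @param go_mu,go_sigma,go_tau Ex-Gaussian go finish-time parameters (ms).
#' @param ssrt_true,ssrt_sd True stop-process latency mean and SD (ms).
#' @param ssd_start,ssd_step Staircase start value and step (ms).
#' @param p_stop_target Stopping-success rate the staircase aims for.
#' @export
race_params <- function(go_mu = 400, go_sigma = 60, go_tau = 70,
                        ssrt_true = 238, ssrt_sd = 20,
                        ssd_start = 200, ssd_step = 50, p_stop_target = 0.5) {
  assert_scalar_number(ssd_start, "ssd_start", lower = 0)
  assert_scalar_number(ssd_step, "ssd_step", lower = 0, strict_lower = TRUE)
  assert_scalar_number(ssrt_true, "ssrt_true", lower = 0, strict_lower = TRUE)
  assert_scalar_number(p_stop_target, "p_stop_target", 0, 1)
  list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
       ssrt_true = ssrt_true, ssrt_sd = ssrt_sd,
       ssd_start = ssd_start, ssd_step = ssd_step,
       p_stop_target = p_stop_target)
}

rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

empty_behavior <- function(n) {
  tibble(trial = seq_len(n),
         condition = NA_character_, side = NA_character_,
         rt = NA_real_, correct = NA,
         ssd = NA_real_, stop_outcome = NA_character_,
         staircase_ssd = NA_real_)
}

#' Simulate Simon-task behavior
#'
#' One row per trial with condition (congruent/incongruent, half each),
#' balanced stimulus side, Gaussian RTs slowed by `congruency_delta` on
#' incongruent trials, and per-condition error rates.
#'
#' @param params A [simon_params()] block.
#' @param n_trials Even trial count (default 768: eight blocks of 96).
#' @param seed Integer seed; the generator is a pure function of
#'   `(params, n_trials, seed)`.
#' @return A behavior tibble (columns `trial`, `condition`, `side`, `rt`,
#'   `correct`, plus stop-task columns as `NA`).
#' @export
gen_simon_behavior <- function(params = simon_params(), n_trials = 768,
                               seed = 1) {
  if (n_trials < 2) abort("`n_trials` must be at least 2")
  if (n_trials %% 2L != 0L) abort("`n_trials` must be even")
  with_seed(child_seed(seed, "simon"), {
    half <- n_trials %/% 2L
    cond <- sample(rep(c("congruent", "incongruent"), each = half))
    side <- character(n_trials)
    for (cc in c("congruent", "incongruent")) {
      idx <- which(cond == cc)
      side[idx] <- sample(rep(c("left", "right"), length.out = length(idx)))
    }
    mu <- ifelse(cond == "incongruent",
                 params$mean_rt_congruent + params$congruency_delta,
                 params$mean_rt_congruent)
    rt <- pmax(rnorm(n_trials, mu, params$rt_sd), 50)
    perr <- ifelse(cond == "incongruent", params$err_rate_incongruent,
                   params$err_rate_congruent)
    correct <- rbinom(n_trials, 1L, 1 - perr) == 1L
    out <- empty_behavior(n_trials)
    out$condition <- cond
    out$side <- side
    out$rt <- rt
    out$correct <- correct
    out
  })
}

#' Simulate a stop-signal session (independent race, staircased SSD)
#'
#' Go and stop finish times race independently; a stop trial fails (a response
#' is emitted) iff the go process finishes before `SSD + stop latency`. The
#' SSD staircase is maintained independently per go direction: shortened by
#' `ssd_step` after a failed stop (floor 0), lengthened after a successful
#' stop. Every go trial records the staircase position current for its
#' direction, for later stop/go matching.
#'
#' @param params A [race_params()] block.
#' @param n_go,n_stop Trial counts (defaults 200/100: six blocks of 50).
#' @param seed Integer seed.
#' @return A behavior tibble; stop trials carry `ssd` and
#'   `stop_outcome` in `{"success","fail"}` (successful stops have no RT), go
#'   trials carry `staircase_ssd`.
#' @export
gen_stop_signal_session <- function(params = race_params(), n_go = 200,
                                    n_stop = 100, seed = 1) {
  if (n_go < 1 || n_stop < 1) abort("need at least one go and one stop trial")
  with_seed(child_seed(seed, "sst"), {
    n <- n_go + n_stop
    is_stop <- sample(rep(c(FALSE, TRUE), times = c(n_go, n_stop)))
    side <- character(n)
    for (ss in c(FALSE, TRUE)) {
      idx <- which(is_stop == ss)
      side[idx] <- sample(rep(c("left", "right"), length.out = length(idx)))
    }
    ssd_now <- c(left = params$ssd_start, right = params$ssd_start)
    out <- empty_behavior(n)
    out$side <- side
    out$condition <- ifelse(is_stop, "stop", "go")
    go_finish <- rexgauss(n, params$go_mu, params$go_sigma, params$go_tau)
    stop_lat <- pmax(rnorm(n, params$ssrt_true, params$ssrt_sd), 1)
    for (i in seq_len(n)) {
      d <- side[i]
      if (!is_stop[i]) {
        out$rt[i] <- go_finish[i]
        out$correct[i] <- TRUE
        out$staircase_ssd[i] <- ssd_now[[d]]
      } else {
        ssd <- ssd_now[[d]]
        out$ssd[i] <- ssd
        failed <- go_finish[i] < ssd + stop_lat[i]
        if (failed) {
          out$stop_outcome[i] <- "fail"
          out$rt[i] <- go_finish[i]
          out$correct[i] <- FALSE
          ssd_now[[d]] <- max(0, ssd - params$ssd_step)
        } else {
          out$stop_outcome[i] <- "success"
          out$correct[i] <- TRUE
          ssd_now[[d]] <- ssd + params$ssd_step
        }
      }
    }
    out
  })
}
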