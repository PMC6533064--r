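test_that("mep_amplitude is peak-to-peak inside (10, 50] ms post-pulse", {
  srate <- 1000
  sweep <- numeric(250)
  t_ms <- (seq_along(sweep) - 1) - 150
  sweep[t_ms == 25] <- 0.5
  sweep[t_ms == 30] <- -0.7
  expect_equal(mep_amplitude(sweep), 1.2)
  expect_equal(mep_amplitude(numeric(250)), 0)

  # offset invariance
  expect_equal(mep_amplitude(sweep + 3.3), 1.2)

  # a deflection outside the window does not contribute
  late <- numeric(250)
  late[t_ms == 60] <- 5
  expect_equal(mep_amplitude(late), 0)

  expect_error(mep_amplitude(numeric(120)), "window")
})

test_that("screening applies both stated thresholds strictly", {
  base <- gen_emg_sweeps(gen_simon_behavior(n_trials = 8, seed = 1),
                         mep_params(emg_noise_rms = 0.001), seed = 1,
                         n_baseline = 2, amp_jitter = 0)
  # contaminate one sweep to RMS 0.02 pre-pulse
  hot <- base
  hot$sweep[[1]][1:150] <- 0.02
  flagged <- reject_emg_trials(hot)
  expect_true(flagged$rejected[1])
  expect_equal(flagged$reason[1], "pre-pulse RMS")

  # tiny MEP -> amplitude floor
  tiny <- base
  tiny$sweep[[2]] <- tiny$sweep[[2]] * 0.004
  flagged2 <- reject_emg_trials(tiny)
  expect_true(flagged2$rejected[2])
  expect_equal(flagged2$reason[2], "amplitude floor")

  # thresholds are strict: RMS exactly at the limit passes
  flat <- base[1, ]
  flat$sweep[[1]] <- rep(0, 250)
  flat$sweep[[1]][150 + 22] <- 0.5   # clean MEP
  flat$sweep[[1]][1:150] <- 0.01 * c(1, -1)
  out <- reject_emg_trials(flat)
  expect_false(out$rejected[1])
})

test_that("rejection counts match the construction", {
  beh <- gen_simon_behavior(n_trials = 500, seed = 3)
  sweeps <- gen_emg_sweeps(beh, mep_params(contaminated_fraction = 0.2),
                           seed = 3, n_baseline = 0)
  flagged <- reject_emg_trials(sweeps)
  n_pre <- sum(flagged$reason == "pre-pulse RMS", na.rm = TRUE)
  expect_equal(n_pre, sum(sweeps$contaminated))
  # and the realized count sits inside the binomial 99% CI of 0.2 * n
  n <- nrow(sweeps)
  ci <- qbinom(c(0.005, 0.995), n, 0.2)
  expect_gte(n_pre, ci[1])
  expect_lte(n_pre, ci[2])
})

test_that("screening and amplitude are blind to condition labels", {
  beh <- gen_simon_behavior(n_trials = 40, seed = 5)
  sw <- gen_emg_sweeps(beh, seed = 5)
  a <- reject_emg_trials(sw)
  shuffled <- sw
  shuffled$condition <- sample(shuffled$condition)
  b <- reject_emg_trials(shuffled)
  expect_equal(a$rejected, b$rejected)
  expect_equal(a$amplitude, b$amplitude)
})

test_that("summaries normalize to baseline and are gain-invariant", {
  beh <- gen_simon_behavior(n_trials = 60, seed = 6)
  sw <- gen_emg_sweeps(beh, mep_params(suppression_factor = 0.8,
                                       emg_noise_rms = 0.001), seed = 6)
  s1 <- summarize_meps(reject_emg_trials(sw))
  expect_equal(s1$normalized[s1$condition == "baseline"], 1)

  # gain small enough that the scaled noise floor stays below the
  # screening threshold (screening is deliberately gain-sensitive)
  gained <- sw
  gained$sweep <- purrr::map(gained$sweep, ~.x * 1.5)
  s2 <- summarize_meps(reject_emg_trials(gained))
  expect_equal(s2$normalized, s1$normalized)

  # noiseless template amplitudes are exact
  exact <- gen_emg_sweeps(beh, mep_params(baseline_amp = 1.2,
                                          emg_noise_rms = 0),
                          seed = 1, amp_jitter = 0)
  flagged <- reject_emg_trials(exact)
  expect_equal(flagged$amplitude[flagged$condition == "congruent"][1], 1.2)

  # identical amplitudes in all conditions -> all normalized values 1
  s3 <- summarize_meps(reject_emg_trials(
    gen_emg_sweeps(beh, mep_params(suppression_factor = 1,
                                   emg_noise_rms = 0), seed = 2,
                   amp_jitter = 0)))
  expect_equal(s3$normalized, rep(1, nrow(s3)))
})

test_that("the planted suppression factor is recovered", {
  vals <- vapply(1:10, function(s) {
    beh <- gen_simon_behavior(n_trials = 240, seed = s)
    sw <- gen_emg_sweeps(beh, mep_params(suppression_factor = 0.8,
                                         emg_noise_rms = 0.001),
                         seed = s, amp_jitter = 0.05)
    s1 <- summarize_meps(reject_emg_trials(sw))
    s1$normalized[s1$condition == "incongruent"]
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.8), 0.05)
})

test_that("compare_conditions reports exact contrasts and the slowing link", {
  summaries <- purrr::map_dfr(1:30, function(s) {
    cong <- 1 + s / 100
    tibble::tibble(subject = as.character(s),
                   condition = c("congruent", "incongruent"),
                   normalized = c(cong, cong * 0.9))
  })
  cc <- compare_conditions(summaries)
  expect_lt(cc$paired$p, 1e-6)
  expect_equal(cc$paired$mean_diff,
               mean(-0.1 * (1 + (1:30) / 100)))

  # cross-subject suppression/slowing correlation: plant a positive link
  set.seed(2)
  slow <- rnorm(30, 30, 8)
  summaries2 <- purrr::map_dfr(1:30, function(s) {
    tibble::tibble(subject = as.character(s),
                   condition = c("congruent", "incongruent"),
                   normalized = c(1, 1 - 0.004 * slow[s] - rnorm(1, 0, 0.02)))
  })
  cc2 <- compare_conditions(summaries2, slowing = slow)
  expect_gt(cc2$slowing_cor$r, 0)

  expect_error(compare_conditions(summaries[1:3, ]), "both")
})
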