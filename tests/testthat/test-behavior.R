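toy_simon <- function(n_per = 4, delta = 35) {
  tibble::tibble(
    trial = seq_len(2 * n_per),
    condition = rep(c("congruent", "incongruent"), each = n_per),
    side = rep(c("left", "right"), n_per),
    rt = c(300 + seq_len(n_per) * 10, 300 + seq_len(n_per) * 10 + delta),
    correct = TRUE,
    ssd = NA_real_, stop_outcome = NA_character_, staircase_ssd = NA_real_)
}

toy_sst <- function(go_rts, n_fail, n_success, ssd_val = 200) {
  n_go <- length(go_rts)
  n_stop <- n_fail + n_success
  df <- data.frame(
    trial = seq_len(n_go + n_stop),
    condition = c(rep("go", n_go), rep("stop", n_stop)),
    side = rep(c("left", "right"), length.out = n_go + n_stop),
    rt = c(go_rts, rep(450, n_fail), rep(NA_real_, n_success)),
    correct = c(rep(TRUE, n_go), rep(FALSE, n_fail), rep(TRUE, n_success)),
    ssd = c(rep(NA_real_, n_go), rep(ssd_val, n_stop)),
    stop_outcome = c(rep(NA_character_, n_go), rep("fail", n_fail),
                     rep("success", n_success)),
    staircase_ssd = c(rep(ssd_val, n_go), rep(NA_real_, n_stop)))
  tibble::as_tibble(df)
}

test_that("simon_summary reports exact contrasts on constructed tables", {
  s <- simon_summary(toy_simon(delta = 35))
  expect_equal(s$contrast$rt_diff, 35)
  expect_equal(s$conditions$err_rate, c(0, 0))

  bad <- toy_simon()
  bad$correct[bad$condition == "incongruent"] <- FALSE
  expect_error(simon_summary(bad), "incongruent")
})

test_that("simon_summary recovers the planted delta from simulation", {
  est <- simon_summary(gen_simon_behavior(n_trials = 768, seed = 42))
  expect_lt(abs(est$contrast$rt_diff - 35), 17)
  grp <- simon_summary(purrr::map(1:5, ~gen_simon_behavior(n_trials = 384,
                                                           seed = .x)))
  expect_lt(abs(grp$contrast$rt_diff - 35), 15)
  expect_true(all(c("t", "p", "cohens_d") %in% names(grp$contrast)))
})

test_that("race_model_check orders means and handles missing failed stops", {
  tab <- toy_sst(go_rts = c(500, 600), n_fail = 1, n_success = 1)
  chk <- race_model_check(tab)
  expect_equal(chk$mean_go_rt, 550)
  expect_equal(chk$mean_failed_stop_rt, 450)
  expect_true(chk$race_ok)

  none <- toy_sst(go_rts = c(500, 600), n_fail = 0, n_success = 2)
  chk2 <- race_model_check(none)
  expect_true(is.na(chk2$race_ok))
  expect_match(chk2$reason, "no failed stop")
})

test_that("ssrt_integration reproduces the hand-computed toy exactly", {
  # 5 go RTs 400..800; p(respond|stop) = 0.4 -> 2nd order statistic = 500;
  # mean SSD 200 -> SSRT = 300
  tab <- toy_sst(go_rts = c(400, 500, 600, 700, 800) ,
                 n_fail = 4, n_success = 6, ssd_val = 200)
  tab <- dplyr::bind_rows(tab, dplyr::mutate(tab[tab$condition == "go", ],
                                             trial = trial + 100))
  est <- ssrt_integration(tab)
  expect_equal(est$p_respond_given_stop, 0.4)
  expect_equal(est$go_quantile_rt, 500)
  expect_equal(est$ssrt, 300)
})

test_that("ssrt_integration rejects degenerate stopping rates", {
  allfail <- toy_sst(go_rts = seq(400, 800, length.out = 12), n_fail = 5,
                     n_success = 0)
  expect_error(ssrt_integration(allfail), "strictly in")
  allstop <- toy_sst(go_rts = seq(400, 800, length.out = 12), n_fail = 0,
                     n_success = 5)
  expect_error(ssrt_integration(allstop), "strictly in")
})

test_that("ssrt_integration is invariant to trial order and successful stops", {
  tab <- gen_stop_signal_session(seed = 9)
  base <- ssrt_integration(tab)
  perm <- ssrt_integration(tab[sample(nrow(tab)), ])
  expect_equal(perm$ssrt, base$ssrt)
  extra <- tab[tab$condition == "stop" & tab$stop_outcome == "success", ][1, ]
  # adding successful stops changes p(respond|stop) but adding *go omissions
  # without RT* must not; here we check successful stops carry no RT at all
  expect_true(all(is.na(tab$rt[tab$stop_outcome == "success"])))
  # quantile is monotone nondecreasing in p(respond|stop)
  go_sorted <- sort(tab$rt[tab$condition == "go" & tab$correct])
  qs <- go_sorted[ceiling(seq(0.1, 0.9, by = 0.1) * length(go_sorted))]
  expect_true(all(diff(qs) >= 0))
})

test_that("ssrt_integration recovers the true stop latency from race sessions", {
  est <- vapply(1:25, function(s) {
    ssrt_integration(gen_stop_signal_session(seed = s))$ssrt
  }, numeric(1))
  expect_lt(abs(mean(est) - 238), 15)
})

test_that("match_go_trials matches on exact SSD within direction", {
  tab <- tibble::tibble(
    trial = 1:4,
    condition = c("stop", "go", "go", "go"),
    side = c("left", "left", "left", "left"),
    rt = c(NA, 400, 410, 420), correct = c(TRUE, TRUE, TRUE, TRUE),
    ssd = c(200, NA, NA, NA), stop_outcome = c("success", NA, NA, NA),
    staircase_ssd = c(NA, 200, 200, 250))
  m <- match_go_trials(tab)
  expect_equal(m$n_matched, 2L)
  expect_setequal(m$go_trials[[1]], c(2L, 3L))

  tab$side[2:4] <- "right"   # direction mismatch -> empty set, warning
  expect_warning(m2 <- match_go_trials(tab), "no staircase-matched")
  expect_equal(m2$n_matched, 0L)
})

test_that("staircase simulations leave few stop trials unmatched", {
  frac <- vapply(1:10, function(s) {
    tab <- gen_stop_signal_session(seed = s)
    m <- quietly(match_go_trials(tab))
    mean(m$n_matched >= 1)
  }, numeric(1))
  expect_true(all(frac >= 0.9))
})
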