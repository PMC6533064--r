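test_that("bipolar montages are literal adjacent differences", {
  X <- rbind(c1 = rnorm(100), c2 = rnorm(100), c3 = rnorm(100),
             c4 = rnorm(100))
  rec <- new_recording(X, 1000, paste0("c", 1:4))
  bip <- make_bipolar(rec)
  expect_equal(nrow(bip$data), 3)
  expect_equal(bip$channel_names, c("c1-c2", "c2-c3", "c3-c4"))
  expect_equal(bip$data[2, ], X[2, ] - X[3, ])

  # common-mode rejection
  same <- new_recording(rbind(X[1, ], X[1, ]), 1000, c("a", "b"))
  expect_equal(max(abs(make_bipolar(same)$data)), 0)

  # a source on contact 2 only appears with opposite signs in pairs 1-2, 2-3
  solo <- matrix(0, 4, 100)
  solo[2, ] <- sin(seq_len(100) / 5)
  bs <- make_bipolar(new_recording(solo, 1000, paste0("c", 1:4)))
  expect_equal(bs$data[1, ], -bs$data[2, ])

  expect_error(make_bipolar(rec, layout = c("c1", "zz")), "unknown channel")
})

test_that("resting beta peaks drive STN montage selection", {
  srate <- 1000
  n <- 8 * srate
  set.seed(4)
  mont <- do.call(rbind, purrr::map(1:3, ~conflictr:::pink_noise(n)))
  mont[2, ] <- mont[2, ] + 0.8 * sin(2 * pi * 20 * seq_len(n) / srate)
  rec <- new_recording(mont, srate, paste0("m", 1:3))
  sel <- select_stn_contact(rec)
  expect_equal(sel$selected, 2L)

  # doubling the oscillation raises the winning score
  mont2 <- mont
  mont2[2, ] <- mont2[2, ] + 0.8 * sin(2 * pi * 20 * seq_len(n) / srate)
  sel2 <- select_stn_contact(new_recording(mont2, srate, paste0("m", 1:3)))
  expect_gt(sel2$scores$score[2], sel$scores$score[2])

  # pure 1/f everywhere: warning and lowest-index default
  flat <- new_recording(do.call(rbind,
                                purrr::map(4:6, ~conflictr:::pink_noise(n))),
                        srate, paste0("m", 1:3))
  expect_warning(self <- select_stn_contact(flat), "no montage")
  expect_equal(self$selected, 1L)

  short <- new_recording(mont[, 1:2000], srate)
  expect_error(select_stn_contact(short), "5 s")
})

test_that("motor montage selection rewards beta desynchronization only", {
  srate <- 500
  times_n <- 500                       # 1 s epochs, response at 500 ms
  make_ep <- function(drop = FALSE, rebound = FALSE, seed = 1) {
    set.seed(seed)
    n_tr <- 14
    beta_amp <- rep(1, times_n)
    mid <- 150:350
    if (drop) beta_amp[mid] <- 0.4
    if (rebound) beta_amp[mid] <- 1.8
    X <- array(NA_real_, dim = c(n_tr, 1, times_n))
    tt <- seq_len(times_n) / srate
    for (r in seq_len(n_tr)) {
      X[r, 1, ] <- beta_amp * sin(2 * pi * 20 * tt + runif(1, 0, 2 * pi)) +
        rnorm(times_n, 0, 0.3)
    }
    structure(list(data = X, times = seq(-500, 498, by = 2), srate = srate,
                   channel_names = "m", metadata = NULL), class = "epochs")
  }
  eps <- list(make_ep(seed = 1), make_ep(drop = TRUE, seed = 2),
              make_ep(seed = 3))
  sel <- select_motor_contact(eps, window = c(-200, 200))
  expect_equal(sel$selected, 2L)

  # a beta rebound (power increase) is never selected over flat montages
  eps2 <- list(make_ep(seed = 4), make_ep(rebound = TRUE, seed = 5))
  sel2 <- quietly(select_motor_contact(eps2, window = c(-200, 200)))
  expect_false(sel2$selected == 2L)

  few <- make_ep(seed = 6)
  few$data <- few$data[1:5, , , drop = FALSE]
  expect_error(select_motor_contact(list(few)), "10")
})

test_that("PLV is exact for locked phases and matches the Rayleigh null", {
  set.seed(31)
  theta <- array(runif(40 * 3 * 20, -pi, pi), dim = c(40, 3, 20))
  x <- tfr_from_phase(theta)
  y <- tfr_from_phase(theta)
  expect_lt(max(abs(plv(x, y)$values - 1)), 1e-9)

  # constant phase offset: phase-difference consistency, not equality
  y2 <- tfr_from_phase(theta + pi / 4)
  expect_lt(max(abs(plv(x, y2)$values - 1)), 1e-9)

  # independent phases at n = 200: E[PLV] ~ sqrt(pi / (4 n))
  n <- 200
  a <- tfr_from_phase(array(runif(n * 5 * 40, -pi, pi), dim = c(n, 5, 40)))
  b <- tfr_from_phase(array(runif(n * 5 * 40, -pi, pi), dim = c(n, 5, 40)))
  null_mean <- mean(plv(a, b)$values)
  expect_lt(abs(null_mean / sqrt(pi / (4 * n)) - 1), 0.2)

  expect_error(plv(x, tfr_from_phase(theta[1:10, , ])), "trials")
})

test_that("PLV is invariant to common rotations and trial permutation,
           and baselining zeroes the baseline window", {
  set.seed(32)
  theta_x <- array(runif(30 * 2 * 50, -pi, pi), dim = c(30, 2, 50))
  theta_y <- theta_x + array(rnorm(30 * 2 * 50, 0, 0.7), dim = dim(theta_x))
  base <- plv(tfr_from_phase(theta_x), tfr_from_phase(theta_y))
  rot <- plv(tfr_from_phase(theta_x + 1.1), tfr_from_phase(theta_y + 1.1))
  expect_equal(rot$values, base$values)
  perm <- sample(30)
  pp <- plv(tfr_from_phase(theta_x[perm, , ]),
            tfr_from_phase(theta_y[perm, , ]))
  expect_equal(pp$values, base$values)

  # monotone nonincreasing in added independent phase noise
  lv <- vapply(c(0, 0.5, 1, 2), function(s) {
    noisy <- theta_y + array(rnorm(length(theta_y), 0, s), dim = dim(theta_y))
    mean(plv(tfr_from_phase(theta_x), tfr_from_phase(noisy))$values)
  }, numeric(1))
  expect_true(all(diff(lv) < 0))

  x <- tfr_from_phase(theta_x, times = seq(-300, 190, by = 10))
  y <- tfr_from_phase(theta_y, times = seq(-300, 190, by = 10))
  bl <- plv(x, y, baseline = c(-300, 0))
  bidx <- x$times >= -300 & x$times <= 0
  expect_lt(max(abs(rowMeans(bl$values[, bidx]))), 1e-12)
})

test_that("gen_lfp_pair plants perfect locking when noise-free", {
  beh <- gen_simon_behavior(n_trials = 16, seed = 2)
  pair <- gen_lfp_pair(beh, coupling_params(plv_target = 1, granger_gain = 0,
                                            noise_sd = 0), seed = 2)
  ev <- pair$stn$events$sample
  inc <- beh$condition == "incongruent" & beh$correct
  tf_x <- filter_hilbert(pair$stn, freqs = 18:22, events = ev,
                         window = c(-300, 500))
  tf_y <- filter_hilbert(pair$m1, freqs = 18:22, events = ev,
                         window = c(-300, 500))
  keep <- function(tf) {
    tf$analytic <- tf$analytic[inc, , , drop = FALSE]
    tf
  }
  pm <- plv(keep(tf_x), keep(tf_y))
  widx <- pm$times >= 180 & pm$times <= 240
  expect_lt(max(abs(pm$values[, widx] - 1)), 1e-6)
})
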