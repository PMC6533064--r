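# Build a small component set from a known mixing model.
mixture_components <- function(seed = 1, peak = "Cz", n_trials = 12,
                               nsamp = 300, srate = 500) {
  set.seed(seed)
  chans <- c("FCz", "Cz", "C1", "C2", "FC1", "FC2", "Pz", "Oz")
  times <- seq(0, by = 1000 / srate, length.out = nsamp)
  S <- array(rnorm(n_trials * 3 * nsamp), dim = c(n_trials, 3, nsamp))
  # source 1: evoked deflection 100-300 ms, consistent across trials
  wave <- 3 * exp(-(times - 200)^2 / (2 * 50^2))
  S[, 1, ] <- S[, 1, ] * 0.2 + rep(wave, each = n_trials)
  mix <- matrix(runif(8 * 3, 0.05, 0.3), 8, 3)
  rownames(mix) <- chans
  mix[match(peak, chans), 1] <- 1
  mix[7:8, 2] <- c(1, 0.9)                 # posterior source
  mix[, 3] <- runif(8, 0.3, 0.5)
  mix[4, 3] <- 0.9                         # another central source, no ERP
  X <- array(NA_real_, dim = c(n_trials, 8, nsamp))
  for (r in seq_len(n_trials)) X[r, , ] <- mix %*% S[r, , ]
  ep <- structure(list(data = X, times = times, srate = srate,
                       channel_names = chans, metadata = NULL),
                  class = "epochs")
  list(cs = component_set(conflictr:::pinv(mix), ep), ep = ep, mix = mix)
}

test_that("back-projection reconstructs the data and is linear", {
  fx <- mixture_components()
  cs <- fx$cs
  # summing all components over one channel reproduces that channel
  recon <- backproject(cs, NULL, channels = "FCz")
  expect_lt(max(abs(recon - fx$ep$data[, 1, ])),
            1e-6 * max(abs(fx$ep$data)))

  # scaling a map column scales the back-projection
  cs2 <- cs
  cs2$maps[, 2] <- cs2$maps[, 2] * 3
  expect_equal(backproject(cs2, 2), 3 * backproject(cs, 2))

  # zero-activation component back-projects to zero
  cs3 <- cs
  cs3$activations[, 2, ] <- 0
  expect_equal(max(abs(backproject(cs3, 2))), 0)

  expect_error(backproject(cs, 1, channels = "Fp9"), "unknown channel")
})

test_that("selection finds the fronto-central ERP-dominant component", {
  fx <- mixture_components(seed = 2, peak = "Cz")
  sel <- select_inhibition_component(fx$cs)
  expect_equal(sel$selected, 1L)

  # invariant to component sign flips and order permutations
  perm <- c(3, 1, 2)
  unmix_p <- (diag(c(-1, 1, -1)) %*% fx$cs$unmixing)[perm, ]
  cs_p <- component_set(unmix_p, fx$ep)
  sel_p <- select_inhibition_component(cs_p)
  expect_equal(sel_p$selected, which(perm == 1L))
})

test_that("selection errors without any fronto-central component", {
  set.seed(3)
  chans <- c("FCz", "Cz", "C1", "C2", "FC1", "FC2", "Pz", "Oz")
  mix <- matrix(runif(8 * 2, 0.05, 0.3), 8, 2)
  mix[7, 1] <- 1                       # both sources peak posterior
  mix[8, 2] <- 1
  X <- array(NA_real_, dim = c(6, 8, 100))
  for (r in 1:6) X[r, , ] <- mix %*% matrix(rnorm(200), 2)
  ep <- structure(list(data = X, times = seq(0, 495, by = 5), srate = 200,
                       channel_names = chans, metadata = NULL),
                  class = "epochs")
  cs <- component_set(conflictr:::pinv(mix), ep)
  expect_error(select_inhibition_component(cs), "no fronto-central")
})

test_that("duplicated candidates tie-break to the lowest index", {
  fx <- mixture_components(seed = 4, peak = "FCz")
  cs <- fx$cs
  d <- dim(cs$activations)
  cs$unmixing <- rbind(cs$unmixing, cs$unmixing[1, ])
  cs$maps <- cbind(cs$maps, cs$maps[, 1])
  act <- array(NA_real_, dim = d + c(0, 1, 0))
  act[, seq_len(d[2]), ] <- cs$activations
  act[, d[2] + 1L, ] <- cs$activations[, 1, ]
  cs$activations <- act
  expect_message(sel <- select_inhibition_component(cs), "tie")
  expect_equal(sel$selected, 1L)
})

test_that("the planted source is selected across synthetic mixtures", {
  hits <- vapply(1:10, function(s) {
    loop <- sst_closed_loop(s, n_go = 80, n_stop = 40)
    loop$selection$selected[1] == attr(loop$eeg, "truth")$source_index
  }, logical(1))
  expect_true(all(hits))
})

test_that("onset detection is exact on a noise-free step difference", {
  times <- seq(0, 498, by = 2)
  stopm <- matrix(0, 20, length(times))
  stopm[, times >= 250] <- 1
  gom <- matrix(0, 30, length(times))
  o <- detect_p3_onset(stopm, gom, times)
  expect_true(o$peak_significant)
  expect_equal(o$onset, 250)
})

test_that("onset detection is translation-equivariant", {
  set.seed(6)
  times <- seq(0, 498, by = 2)
  shape <- pmax(0, 1 - abs(times - 300) / 80)
  stopm <- matrix(rep(shape, each = 40), 40) + matrix(rnorm(40 * 250, 0, 0.2), 40)
  gom <- matrix(rnorm(60 * 250, 0, 0.2), 60)
  o1 <- detect_p3_onset(stopm, gom, times)
  k <- 15
  roll <- function(m) cbind(m[, -(1:k)], m[, 1:k])
  o2 <- detect_p3_onset(roll(stopm), roll(gom), times)
  expect_equal(o2$onset, o1$onset - k * 2)
})

test_that("tightening alpha never moves the onset earlier", {
  set.seed(8)
  times <- seq(0, 498, by = 2)
  shape <- pmax(0, 1 - abs(times - 300) / 120)
  stopm <- matrix(rep(shape, each = 30), 30) + matrix(rnorm(30 * 250, 0, 0.35), 30)
  gom <- matrix(rnorm(60 * 250, 0, 0.35), 60)
  onsets <- vapply(c(0.05, 0.01, 0.001), function(a) {
    detect_p3_onset(stopm, gom, times, alpha = a)$onset
  }, numeric(1))
  expect_true(all(diff(onsets) >= 0))
})

test_that("per-sample null rejection rate tracks alpha", {
  set.seed(12)
  rates <- vapply(1:40, function(i) {
    A <- matrix(rnorm(30 * 200), 30)
    B <- matrix(rnorm(50 * 200), 50)
    o <- detect_p3_onset(A, B, seq(0, 398, by = 2), alpha = 0.05)
    mean(o$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})

test_that("planted stop onsets are recovered with the correct ordering", {
  res <- vapply(1:6, function(s) recover_onsets(sst_closed_loop(s)),
                numeric(2))
  expect_true(all(abs(res[1, ] - 250) <= 10))
  expect_true(all(abs(res[2, ] - 290) <= 10))
  expect_true(all(res[2, ] > res[1, ]))
})

test_that("group onset tests report exact differences and correlations", {
  on_s <- c(240, 250, 255, 260, 270)
  g <- onset_group_tests(on_s, on_s + 40, ssrt = on_s + 10)
  expect_equal(g$mean_diff, 40)
  expect_equal(g$r_onset_ssrt, 1)

  expect_error(onset_group_tests(on_s, on_s[1:3]), "same length")
  set.seed(14)
  rs <- vapply(1:200, function(i) {
    onset_group_tests(rnorm(8, 250, 20), rnorm(8, 290, 20),
                      ssrt = rnorm(8, 238, 15))$r_onset_ssrt
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.08)   # independent onsets/SSRT: centered on 0
})
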