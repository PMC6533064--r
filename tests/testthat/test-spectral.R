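test_that("epoching cuts half-open windows around events", {
  rec <- new_recording(matrix(1, 2, 1000), srate = 500,
                       channel_names = c("a", "b"))
  ep <- epoch(rec, events = c(300, 500), window = c(-100, 200))
  expect_equal(dim(ep$data), c(2, 2, 150))
  expect_true(all(ep$data == 1))
  expect_equal(ep$times[1], -100)
  expect_equal(ep$times[length(ep$times)], 198)

  expect_error(epoch(rec, events = 10, window = c(-300, 0)),
               "out of bounds")

  # a sub-window equals slicing the wider epoch
  rec2 <- new_recording(matrix(rnorm(2000), 2, 1000), 500)
  wide <- epoch(rec2, 500, c(-300, 300))
  narrow <- epoch(rec2, 500, c(-100, 100))
  keep <- wide$times >= -100 & wide$times < 100
  expect_equal(narrow$data[1, , ], wide$data[1, , keep])
  expect_equal(narrow$times, wide$times[keep])
})

test_that("filter-Hilbert recovers envelope power and suppresses leakage", {
  srate <- 500
  t <- seq(1 / srate, 10, by = 1 / srate)
  rec <- new_recording(2 * sin(2 * pi * 10 * t), srate)
  tf <- filter_hilbert(rec, freqs = c(10, 25))
  pw <- tf_power(tf)
  mid <- seq(2 * srate, 8 * srate)   # away from edges
  expect_lt(max(abs(pw[1, 1, mid] - 4)) / 4, 0.05)
  expect_lt(mean(pw[1, 2, mid]) / mean(pw[1, 1, mid]), 0.01)

  tf0 <- filter_hilbert(new_recording(numeric(2000), srate), freqs = c(5, 10))
  expect_equal(max(tf_power(tf0)), 0)

  expect_error(filter_hilbert(rec, freqs = c(10, 250)), "Nyquist")
})

test_that("two-pass filtering is zero-phase", {
  srate <- 500
  t <- seq(1 / srate, 4, by = 1 / srate)
  env <- exp(-(t - 2.1)^2 / (2 * 0.05^2))   # envelope peak at 2100 ms
  rec <- new_recording(env * sin(2 * pi * 10 * t), srate)
  tf <- filter_hilbert(rec, freqs = 10)
  peak <- which.max(tf_power(tf)[1, 1, ])
  expect_lte(abs(peak - 2.1 * srate), 1)
})

test_that("band power sums track broadband variance for white noise", {
  srate <- 500
  set.seed(5)
  x <- rnorm(20000)
  tf <- filter_hilbert(new_recording(x, srate), freqs = 1:30)
  band_sum <- sum(apply(tf_power(tf)[1, , ], 1, mean)) / 2
  # FFT oracle: expected power of each band = variance x the filter's
  # two-pass noise bandwidth as a share of the sampling bandwidth
  enbw <- vapply(1:30, function(f) {
    b <- fir_ls_bandpass(f - 0.5, f + 0.5, srate)
    N <- 2^15
    g <- conflictr:::fir_mag2(b, N)
    gc <- Mod(sum(b * exp(-2i * pi * f / srate * (seq_along(b) - 1))))^2
    mean((g / gc)^2)
  }, numeric(1))
  expected <- var(x) * sum(enbw)
  expect_lt(abs(band_sum / expected - 1), 0.1)
  # and the bank's total stays within a small constant factor of the
  # nominal 30 Hz / Nyquist share
  expect_lt(band_sum / (var(x) * 30 / 250), 6)
  expect_gt(band_sum / (var(x) * 30 / 250), 1)
})

test_that("decomposing trial subsets equals decomposing once", {
  set.seed(8)
  X <- matrix(rnorm(6 * 500), 6, 500)
  whole <- filter_hilbert(X, freqs = c(4, 9), srate = 500)
  parts <- filter_hilbert(X[1:3, ], freqs = c(4, 9), srate = 500)
  expect_equal(whole$analytic[1:3, , ], parts$analytic)
})

test_that("ERSP is calibrated in dB against the pre-stimulus baseline", {
  # continuous-trace decomposition (the preferred path: no epoch edges)
  srate <- 500
  nsec <- 50
  tt <- seq(1 / srate, nsec, by = 1 / srate)
  events <- as.integer(seq(3, nsec - 2, by = 2) * srate)

  # stationary tone -> flat 0 dB at every frequency
  rec <- new_recording(sin(2 * pi * 10 * tt), srate)
  tf <- filter_hilbert(rec, freqs = c(5, 10), events = events,
                       window = c(-300, 700))
  e <- ersp(tf, c(-300, 0))
  expect_lt(max(abs(e$values)), 0.1)

  # power doubles 200-1200 ms after each event -> +3.0103 dB once the
  # filter settles (measured mid-plateau, clear of the kernel's support)
  amp <- rep(1, length(tt))
  for (ev in events) amp[(ev + 0.2 * srate):(ev + 1.2 * srate)] <- sqrt(2)
  rec2 <- new_recording(amp * sin(2 * pi * 10 * tt), srate)
  tf2 <- filter_hilbert(rec2, freqs = 10, events = events,
                        window = c(-300, 1400))
  e2 <- ersp(tf2, c(-300, 0))
  post <- e2$times > 700 & e2$times < 900
  expect_lt(max(abs(e2$values[, post] - 10 * log10(2))), 0.15)

  expect_error(ersp(tf, c(-800, -400)), "baseline")
  tfz <- filter_hilbert(matrix(0, 5, 500), freqs = 10, srate = srate,
                        times = seq(-300, 698, by = 2))
  expect_error(ersp(tfz, c(-300, 0)), "baseline power")
})

test_that("recordings decimate with rescaled events", {
  srate <- 2000
  x <- sin(2 * pi * 7 * seq(1 / srate, 4, by = 1 / srate))
  rec <- new_recording(x, srate,
                       events = tibble::tibble(sample = c(2000L, 4000L)))
  dec <- decimate_recording(rec, 500)
  expect_equal(dec$srate, 500)
  expect_equal(ncol(dec$data), length(x) / 4)
  expect_equal(dec$events$sample, c(500L, 1000L))
  expect_error(decimate_recording(rec, 300), "evenly divide")
})
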