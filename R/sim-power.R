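# Direct single-trial power-map generator: plants an RT-coupled
# time-frequency cluster at the power level, skipping the raw-EEG stage, so
# the regression + group-statistics path can be exercised closed-loop at
# full grid size cheaply.

#' Simulate single-trial time-frequency power with an RT-coupled cluster
#'
#' Generates a `tfr`-compatible decomposition on the standard 30 x 350 grid
#' (1-30 Hz, 0-698 ms at 500 Hz) where power in a planted low-frequency
#' cluster follows `base + gain * z(RT)` plus Gaussian noise, and power
#' elsewhere is pure noise around `base`. RTs come from the incongruent arm
#' of a [simon_params()] model.
#'
#' @param n_trials Number of (incongruent, correct) trials.
#' @param gain Planted slope in power units per z(RT).
#' @param noise_sd Pixel noise SD.
#' @param base Baseline power level.
#' @param cluster_freqs,cluster_times Planted cluster extent (Hz, ms).
#' @param freqs,times Grid (defaults: 1-30 Hz, 0-698 ms in 2 ms steps).
#' @param params A [simon_params()] block for the RT distribution.
#' @param seed Integer seed.
#' @return A list: `tf` (a `tfr` whose power carries the planted structure),
#'   `rts`, and `truth` (logical freqs x times mask of planted pixels).
#' @export
gen_singletrial_power <- function(n_trials = 384, gain = 0.5, noise_sd = 1,
                                  base = 2, cluster_freqs = c(2, 8),
                                  cluster_times = c(200, 600),
                                  freqs = 1:30, times = seq(0, 698, by = 2),
                                  params = simon_params(), seed = 1) {
  with_seed(child_seed(seed, "power"), {
    rts <- rnorm(n_trials, params$mean_rt_congruent + params$congruency_delta,
                 params$rt_sd)
    z <- as.numeric(scale(rts))
    mask <- outer(freqs >= cluster_freqs[1] & freqs <= cluster_freqs[2],
                  times >= cluster_times[1] & times <= cluster_times[2], "&")
    npix <- length(freqs) * length(times)
    pw <- matrix(rnorm(n_trials * npix, 0, noise_sd), n_trials, npix) + base
    pw <- pw + z %*% t(as.numeric(mask) * gain)
    pw <- pmax(pw, 1e-3)
    A <- array(sqrt(pw), dim = c(n_trials, length(freqs), length(times)))
    tf <- new_tfr(A + 0i, freqs, times, srate = 500,
                  metadata = tibble(rt = rts))
    list(tf = tf, rts = rts, truth = mask)
  })
}
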