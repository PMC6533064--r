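# Synthetic STN/M1 LFP pair with transient beta-band phase coupling and a
# lagged directed influence on incongruent trials.
#
# Coupling model: inside the coupling window each site's band-limited
# component is a mixture (s + a*n_i)/sqrt(1+a^2) of a shared narrowband
# process s and a private one n_i; the mixing ratio `a` is calibrated to the
# requested PLV by a one-time Monte-Carlo lookup (there is no closed form for
# the PLV of such a mixture). M1 additionally receives a lagged copy of STN's
# band-limited in-window signal, scaled by `granger_gain` (STN -> M1
# directionality). All non-planted signal content (broadband background and
# each site's intrinsic narrowband activity) scales with `noise_sd`, so
# `noise_sd = 0` leaves only the planted coupling.

#' @rdname simon_params
#' @param band_lo,band_hi Coupled frequency band (Hz).
#' @param window_lo,window_hi Coupling window (ms post-stimulus).
#' @param plv_target Phase-locking value the coupling is calibrated to.
#' @param granger_lag Directed-influence lag in samples (at the LFP rate).
#' @param granger_gain Gain of the lagged STN copy added to M1.
#' @param noise_sd SD of the non-planted signal content.
#' @export
coupling_params <- function(band_lo = 18, band_hi = 22,
                            window_lo = 180, window_hi = 240,
                            plv_target = 0.8, granger_lag = 10,
                            granger_gain = 1, noise_sd = 0.5) {
  if (band_lo >= band_hi) abort("`band_lo` must be below `band_hi`")
  if (window_lo >= window_hi) abort("`window_lo` must be below `window_hi`")
  assert_scalar_number(plv_target, "plv_target", 0, 1)
  if (granger_lag <= 0) abort("`granger_lag` must be a positive sample count")
  list(band_lo = band_lo, band_hi = band_hi, window_lo = window_lo,
       window_hi = window_hi, plv_target = plv_target,
       granger_lag = as.integer(granger_lag), granger_gain = granger_gain,
       noise_sd = noise_sd)
}

# One-time Monte-Carlo lookup: PLV of Arg(s + a n1) vs Arg(s + a n2) for
# independent complex Gaussians, as a function of the private/shared ratio a.
plv_lookup_env <- new.env(parent = emptyenv())

plv_mixture_curve <- function() {
  if (!is.null(plv_lookup_env$curve)) return(plv_lookup_env$curve)
  grid <- exp(seq(log(0.02), log(50), length.out = 60))
  curve <- with_seed(904711L, {
    m <- 20000L
    zs <- complex(real = rnorm(m), imaginary = rnorm(m))
    z1 <- complex(real = rnorm(m), imaginary = rnorm(m))
    z2 <- complex(real = rnorm(m), imaginary = rnorm(m))
    plv <- vapply(grid, function(a) {
      Mod(mean(exp(1i * (Arg(zs + a * z1) - Arg(zs + a * z2)))))
    }, numeric(1))
    tibble(a = grid, plv = plv)
  })
  plv_lookup_env$curve <- curve
  curve
}

# Invert the lookup: ratio a achieving a requested PLV.
plv_mix_ratio <- function(plv_target) {
  if (plv_target >= 1) return(0)
  curve <- plv_mixture_curve()
  if (plv_target <= min(curve$plv)) return(max(curve$a))
  stats::approx(curve$plv, curve$a, xout = plv_target, ties = mean)$y
}

# Unit-variance narrowband Gaussian process.
narrowband <- function(n, band, srate) {
  x <- band_analytic(rnorm(n + 400), rbind(band), srate)[[1]]
  v <- Re(x[1, 201:(200 + n)])
  v / sd(v)
}

#' Simulate an STN/M1 LFP pair with planted beta coupling
#'
#' On correct incongruent trials, within `window_lo..window_hi` ms
#' post-stimulus, the two channels' band-limited components are phase-coupled
#' at a strength calibrated to `plv_target`, and M1 receives a copy of STN's
#' in-window band-limited signal delayed by `granger_lag` samples and scaled
#' by `granger_gain`. Congruent trials carry only uncoupled intrinsic
#' activity.
#'
#' @param behavior A Simon behavior tibble.
#' @param params A [coupling_params()] block.
#' @param seed Integer seed.
#' @param srate Sampling rate (default 1000 Hz).
#' @param coupling_amp Amplitude of the planted in-window band components.
#' @return A list with elements `stn` and `m1` (single-channel
#'   [new_recording()]s sharing an `events` table) and `truth` (the parameter
#'   block plus the realized mixing ratio).
#' @export
gen_lfp_pair <- function(behavior, params = coupling_params(), seed = 1,
                         srate = 1000, coupling_amp = 1) {
  assert_columns(behavior, c("trial", "condition", "correct"))
  n_trials <- nrow(behavior)
  a <- plv_mix_ratio(params$plv_target)
  band <- c(params$band_lo, params$band_hi)
  with_seed(child_seed(seed, "lfp"), {
    iti_s <- 2.0
    lead_s <- 1.0
    nsamp <- as.integer((lead_s + iti_s * n_trials + lead_s) * srate)
    stim <- as.integer(lead_s * srate + (seq_len(n_trials) - 1L) * iti_s * srate) + 1L

    x <- params$noise_sd * (pink_noise(nsamp) +
                              0.7 * narrowband(nsamp, band, srate))
    y <- params$noise_sd * (pink_noise(nsamp) +
                              0.7 * narrowband(nsamp, band, srate))

    # crossfaded coupling window (10 ms raised-cosine edges)
    wlo <- ms_to_samples(params$window_lo, srate)
    whi <- ms_to_samples(params$window_hi, srate)
    ramp <- ms_to_samples(10, srate)
    wlen <- whi - wlo + 1L
    w <- rep(1, wlen)
    if (wlen > 2L * ramp) {
      up <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
      w[seq_len(ramp)] <- up
      w[(wlen - ramp + 1L):wlen] <- rev(up)
    }
    lag <- params$granger_lag
    coupled <- which(behavior$condition == "incongruent" & behavior$correct)
    norm <- sqrt(1 + a^2)
    for (i in coupled) {
      seg <- (stim[i] + wlo):(stim[i] + whi)
      s <- narrowband(wlen, band, srate)
      n1 <- narrowband(wlen, band, srate)
      n2 <- narrowband(wlen, band, srate)
      xb <- coupling_amp * w * (s + a * n1) / norm
      yb <- coupling_amp * w * (s + a * n2) / norm
      x[seg] <- x[seg] + xb
      y[seg] <- y[seg] + yb
      if (params$granger_gain != 0) {
        y[seg + lag] <- y[seg + lag] + params$granger_gain * xb
      }
    }
    events <- tibble(trial = behavior$trial, sample = stim)
    list(stn = new_recording(x, srate, "STN", events),
         m1 = new_recording(y, srate, "M1", events),
         truth = c(params, list(mix_ratio = a, coupling_amp = coupling_amp)))
  })
}

#' Embed a signal into a synthetic multi-contact electrode array
#'
#' Places a single-channel signal across one adjacent contact pair of an
#' n-contact array (with opposite polarity on the two contacts, so the
#' corresponding bipolar montage recovers it), on top of a shared
#' common-mode background and per-contact noise. Used to exercise the
#' montage-construction and contact-selection stages on data with a known
#' best pair.
#'
#' @param signal A single-channel [new_recording()].
#' @param n_contacts Number of contacts (default 4, giving 3 bipolar pairs).
#' @param target Index of the bipolar pair that should carry the signal
#'   (1 .. n_contacts - 1).
#' @param common_sd,contact_sd SDs of the shared common-mode background and
#'   the independent per-contact noise.
#' @param seed Integer seed.
#' @return A [new_recording()] with contacts `c1..cn` and the same events.
#' @export
gen_contact_array <- function(signal, n_contacts = 4, target = 2,
                              common_sd = 2, contact_sd = 0.2, seed = 1) {
  stopifnot(inherits(signal, "recording"), nrow(signal$data) == 1L)
  if (target < 1 || target > n_contacts - 1) abort("`target` pair out of range")
  with_seed(child_seed(seed, "contacts"), {
    n <- ncol(signal$data)
    cm <- pink_noise(n) * common_sd
    X <- matrix(rnorm(n_contacts * n, 0, contact_sd), n_contacts, n)
    X <- sweep(X, 2, cm, "+")
    X[target, ] <- X[target, ] + signal$data[1, ] / 2
    X[target + 1L, ] <- X[target + 1L, ] - signal$data[1, ] / 2
    new_recording(X, signal$srate, paste0("c", seq_len(n_contacts)),
                  signal$events)
  })
}
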