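# Montage construction, contact selection, and phase-locking value.

#' Bipolar montages from adjacent contacts
#'
#' Derives `n - 1` bipolar channels from an ordered contact layout, channel
#' `k` being the literal sample-wise difference `contact_k - contact_{k+1}`,
#' named `"k-k+1"`.
#'
#' @param recording A multichannel [new_recording()].
#' @param layout Contact labels in physical order (default: the recording's
#'   channel order).
#' @return A `recording` of derived bipolar channels.
#' @export
make_bipolar <- function(recording, layout = recording$channel_names) {
  stopifnot(inherits(recording, "recording"))
  if (length(layout) < 2L) abort("need at least 2 contacts")
  dat <- recording_channel(recording, layout)
  n <- length(layout)
  out <- dat[-n, , drop = FALSE] - dat[-1, , drop = FALSE]
  new_recording(out, recording$srate,
                paste(layout[-n], layout[-1], sep = "-"),
                recording$events)
}

#' Select the STN montage with the clearest resting beta peak
#'
#' Welch spectra are computed per montage, log-power is detrended against a
#' 1/f fit (linear regression of log power on log frequency over 3-45 Hz,
#' excluding the beta band itself), and each montage is scored by the
#' maximum detrended elevation within 13-30 Hz. The montage with the highest
#' score wins; if no montage scores above zero a warning is raised and the
#' lowest-index montage is returned.
#'
#' @param rest A bipolar [new_recording()] of resting activity (>= 5 s), one
#'   row per montage.
#' @param beta_band Scored band (Hz).
#' @return A `contact_selection`: `selected` montage index, `scores` tibble,
#'   `spectra` tibble (per montage Welch spectrum and detrended power).
#' @export
select_stn_contact <- function(rest, beta_band = c(13, 30)) {
  stopifnot(inherits(rest, "recording"))
  if (ncol(rest$data) < 5 * rest$srate) {
    abort("need at least 5 s of resting data")
  }
  spectra <- purrr::map_dfr(seq_len(nrow(rest$data)), function(k) {
    ps <- welch_psd(rest$data[k, ], rest$srate)
    ps <- ps[ps$freq >= 3 & ps$freq <= 45, ]
    fitset <- ps$freq < beta_band[1] | ps$freq > beta_band[2]
    fit <- stats::lm(log10(power) ~ log10(freq), data = ps[fitset, ])
    ps$detrended <- log10(ps$power) -
      stats::predict(fit, newdata = ps)
    # light smoothing so single-bin fluctuations do not masquerade as peaks
    ps$detrended <- as.numeric(stats::filter(ps$detrended, rep(1 / 3, 3)))
    ps$detrended[is.na(ps$detrended)] <- 0
    mutate(ps, montage = k)
  })
  scores <- spectra %>%
    filter(.data$freq >= beta_band[1], .data$freq <= beta_band[2]) %>%
    group_by(montage = .data$montage) %>%
    summarise(score = max(.data$detrended), .groups = "drop")
  # 0.4 log10 units (~2.5x power elevation over the 1/f fit) separates a
  # genuine spectral peak from detrending noise on resting segments
  if (all(scores$score <= 0.4)) {
    warn("no montage shows a clear beta-band peak; defaulting to montage 1")
    selected <- 1L
  } else {
    selected <- scores$montage[which.max(scores$score)]
  }
  structure(list(selected = selected, scores = scores, spectra = spectra),
            class = "contact_selection")
}

#' Select the M1 montage with the clearest movement-related beta drop
#'
#' Scores each montage by its mean beta-band (13-30 Hz) ERSP in a
#' peri-response window (-250 to +250 ms around the response) on
#' response-locked congruent-trial epochs; the most negative score
#' (strongest desynchronization) wins. Montages showing only a power
#' increase are never selected over a desynchronizing one.
#'
#' @param response_epochs List of [epoch()]ed data, one per montage,
#'   response-locked, congruent trials only.
#' @param beta_band Scored band (Hz).
#' @param window Peri-response scoring window (ms).
#' @param baseline ERSP baseline window (ms).
#' @return A `contact_selection` with per-montage desynchronization scores
#'   (dB).
#' @export
select_motor_contact <- function(response_epochs, beta_band = c(13, 30),
                                 window = c(-250, 250),
                                 baseline = NULL) {
  stopifnot(is.list(response_epochs))
  scores <- purrr::map_dfr(seq_along(response_epochs), function(k) {
    ep <- response_epochs[[k]]
    stopifnot(inherits(ep, "epochs"))
    if (dim(ep$data)[1] < 10L) abort("need at least 10 response-locked trials")
    bl <- baseline %||% c(min(ep$times), max(ep$times))
    tf <- filter_hilbert(ep, freqs = seq(beta_band[1], beta_band[2], by = 2))
    er <- ersp(tf, baseline = bl)
    widx <- time_index(er$times, window)
    tibble(montage = k, score = mean(er$values[, widx]))
  })
  if (all(abs(scores$score) < 0.05)) {
    warn("flat beta power in all montages; tie-break to montage 1")
  }
  neg <- scores$score < 0
  selected <- if (any(neg)) scores$montage[which.min(scores$score)] else 1L
  structure(list(selected = selected, scores = scores),
            class = "contact_selection")
}

#' @export
print.contact_selection <- function(x, ...) {
  cat("<contact_selection> selected montage:", x$selected, "\n")
  print(x$scores)
  invisible(x)
}

#' Phase-locking value between two sites
#'
#' For every time-frequency point, the magnitude of the trial-averaged unit
#' phasor of the phase difference:
#' `PLV(t, f) = | n^-1 sum_r exp(i (theta_x - theta_y)) |`.
#' With a baseline window, the per-frequency baseline-window mean is
#' subtracted (baselined values may be negative).
#'
#' @param tf_x,tf_y `tfr` decompositions with identical trial counts and
#'   grids.
#' @param baseline Optional length-2 ms window for baseline subtraction.
#' @return A `plv_matrix`: `values` (freqs x timepoints, raw in `[0,1]` or
#'   baseline-subtracted), `raw`, `n` trials.
#' @export
plv <- function(tf_x, tf_y, baseline = NULL) {
  stopifnot(inherits(tf_x, "tfr"), inherits(tf_y, "tfr"))
  dx <- dim(tf_x$analytic); dy <- dim(tf_y$analytic)
  if (!identical(dx, dy)) abort("decompositions differ in trials or grid")
  if (dx[1] < 2L) abort("PLV needs at least 2 trials")
  dphi <- exp(1i * (Arg(tf_x$analytic) - Arg(tf_y$analytic)))
  raw <- apply(dphi, c(2, 3), function(v) Mod(mean(v)))
  vals <- raw
  if (!is.null(baseline)) {
    bidx <- time_index(tf_x$times, baseline)
    vals <- raw - rowMeans(raw[, bidx, drop = FALSE])
  }
  new_tf_map(vals, tf_x$freqs, tf_x$times, class = "plv_matrix",
             raw = raw, n = dx[1], baseline = baseline)
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> %d freqs x %d timepoints, n = %d trials%s\n",
              length(x$freqs), length(x$times), x$n,
              if (is.null(x$baseline)) " (raw)" else " (baselined)"))
  invisible(x)
}

#' @export
tidy.plv_matrix <- function(x, ...) {
  tibble(freq = rep(x$freqs, times = length(x$times)),
         time = rep(x$times, each = length(x$freqs)),
         plv = as.vector(x$values), raw = as.vector(x$raw))
}
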