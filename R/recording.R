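#' Continuous multichannel recording
#'
#' Lightweight container for a continuous voltage trace: a channels x samples
#' numeric matrix plus sampling rate and channel labels. Generators attach
#' event tables and ground-truth metadata as attributes.
#'
#' @param data Numeric matrix, channels x samples (a vector is treated as one
#'   channel).
#' @param srate Sampling rate in Hz.
#' @param channel_names Character vector of channel labels, one per row.
#' @param events Optional tibble of event markers with at least a `sample`
#'   column (1-based sample indices).
#'
#' @return An object of class `recording`.
#' @export
new_recording <- function(data, srate, channel_names = NULL, events = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  assert_scalar_number(srate, "srate", lower = 0, strict_lower = TRUE)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    abort("`channel_names` must have one label per channel (matrix row).")
  }
  structure(
    list(data = data, srate = srate, channel_names = as.character(channel_names),
         events = events),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat("channels:", paste(utils::head(x$channel_names, 12), collapse = ", "),
      if (length(x$channel_names) > 12) "..." else "", "\n")
  if (!is.null(x$events)) cat(sprintf("events: %d\n", nrow(x$events)))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

recording_channel <- function(x, channel) {
  idx <- match(channel, x$channel_names)
  if (any(is.na(idx))) {
    abort(sprintf("unknown channel label(s): %s",
                  paste(channel[is.na(idx)], collapse = ", ")))
  }
  x$data[idx, , drop = FALSE]
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias filters and downsamples every channel, for bringing
#' high-rate LFP acquisitions down to the analysis rate (1000 Hz by default
#' convention for the connectivity stack).
#'
#' @param recording A [new_recording()] object.
#' @param target_srate Desired sampling rate; must divide `srate` evenly.
#' @return A `recording` at the new rate (event sample indices rescaled).
#' @export
decimate_recording <- function(recording, target_srate) {
  stopifnot(inherits(recording, "recording"))
  q <- recording$srate / target_srate
  if (abs(q - round(q)) > 1e-9 || q < 1) {
    abort("`target_srate` must evenly divide the recording's sampling rate.")
  }
  q <- as.integer(round(q))
  if (q == 1L) return(recording)
  dec <- t(apply(recording$data, 1L, function(ch) signal::decimate(ch, q)))
  ev <- recording$events
  if (!is.null(ev)) ev$sample <- pmax(1L, as.integer(round(ev$sample / q)))
  new_recording(dec, target_srate, recording$channel_names, ev)
}

#' Epoch a continuous recording around events
#'
#' Cuts fixed-length windows around event samples. Time zero is the event
#' sample; the window is closed on the left and open on the right, so a
#' `c(-300, 700)` window at 500 Hz yields 500 samples at times
#' -300, -298, ..., 698 ms.
#'
#' @param recording A [new_recording()] object.
#' @param events Integer sample indices (1-based) of the lock events.
#' @param window Length-2 numeric, window in ms relative to the event.
#' @param metadata Optional tibble with one row per event, carried alongside.
#' @return An object of class `epochs`: `data` (trials x channels x samples),
#'   `times` (ms), `srate`, `channel_names`, `metadata`.
#' @export
epoch <- function(recording, events, window, metadata = NULL) {
  stopifnot(inherits(recording, "recording"), length(window) == 2L,
            window[1] < window[2])
  events <- as.integer(events)
  srate <- recording$srate
  lo <- ms_to_samples(window[1], srate)
  hi <- ms_to_samples(window[2], srate) - 1L   # right-open
  nsamp <- hi - lo + 1L
  first <- events + lo
  last <- events + hi
  bad <- which(first < 1L | last > ncol(recording$data))
  if (length(bad) > 0L) {
    abort(sprintf("event window out of bounds for trial(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (!is.null(metadata) && nrow(metadata) != length(events)) {
    abort("`metadata` must have one row per event.")
  }
  nchan <- nrow(recording$data)
  out <- array(NA_real_, dim = c(length(events), nchan, nsamp))
  for (i in seq_along(events)) {
    out[i, , ] <- recording$data[, first[i]:last[i], drop = FALSE]
  }
  structure(
    list(data = out,
         times = (lo:hi) * 1000 / srate,
         srate = srate,
         channel_names = recording$channel_names,
         metadata = metadata),
    class = "epochs"
  )
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs> %d trial(s) x %d channel(s) x %d samples @ %g Hz, %g..%g ms\n",
              d[1], d[2], d[3], x$srate, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.epochs <- function(x) dim(x$data)

# trials x samples matrix for one channel (by label or index).
epochs_channel <- function(epochs, channel) {
  if (is.character(channel)) {
    idx <- match(channel, epochs$channel_names)
    if (is.na(idx)) abort(sprintf("unknown channel label: %s", channel))
  } else idx <- channel
  epochs$data[, idx, , drop = FALSE][, 1L, ]
}

# Subset epochs by trial index, keeping metadata aligned.
epochs_subset <- function(epochs, trials) {
  epochs$data <- epochs$data[trials, , , drop = FALSE]
  if (!is.null(epochs$metadata)) {
    epochs$metadata <- epochs$metadata[trials, , drop = FALSE]
  }
  epochs
}
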