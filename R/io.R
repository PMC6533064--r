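# Plain-text serialization: TSV for tables, recordings and maps, JSON
# sidecars for metadata and reports.

behavior_tsv_cols <- c(trial = "trial", condition = "condition", side = "side",
                       rt_ms = "rt", correct = "correct", ssd_ms = "ssd",
                       stop_outcome = "stop_outcome",
                       staircase_ssd_ms = "staircase_ssd")

#' Read and write behavior tables
#'
#' Fixed-schema TSV with columns `trial`, `condition`, `side`, `rt_ms`,
#' `correct`, `ssd_ms`, `stop_outcome`, `staircase_ssd_ms`.
#'
#' @param table A behavior tibble.
#' @param path File path.
#' @return `read_behavior_tsv` returns a behavior tibble (internal column
#'   names, ms units); `write_behavior_tsv` returns `path` invisibly.
#' @export
write_behavior_tsv <- function(table, path) {
  assert_columns(table, unname(behavior_tsv_cols))
  out <- table[, unname(behavior_tsv_cols)]
  names(out) <- names(behavior_tsv_cols)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trial = "i", condition = "c", side = "c",
                           rt_ms = "d", correct = "l", ssd_ms = "d",
                           stop_outcome = "c", staircase_ssd_ms = "d"))
  names(raw) <- behavior_tsv_cols[names(raw)]
  as_tibble(raw)
}

#' Read and write continuous recordings
#'
#' Samples x channels TSV with channel labels as the header, plus a JSON
#' sidecar (`<path>.json`) holding the sampling rate and any event table.
#'
#' @param recording A [new_recording()] object.
#' @param path File path for the TSV (sidecar written alongside).
#' @return `read_recording_tsv` returns a `recording`.
#' @export
write_recording_tsv <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  df <- as.data.frame(t(recording$data))
  names(df) <- recording$channel_names
  readr::write_tsv(df, path)
  meta <- list(srate = recording$srate,
               channel_names = recording$channel_names,
               events = recording$events)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  events <- if (!is.null(meta$events) && length(meta$events) > 0) {
    as_tibble(meta$events)
  } else NULL
  new_recording(t(as.matrix(df)), meta$srate, meta$channel_names, events)
}

#' Write a time-frequency map as TSV
#'
#' One row per frequency, one column per timepoint (headers carry the grids).
#'
#' @param map An `ersp`, `beta_map`, `stat_map`, `plv_matrix`, or matrix.
#' @param path File path.
#' @export
write_map_tsv <- function(map, path) {
  vals <- map_values(map)
  freqs <- if (is.matrix(map)) seq_len(nrow(vals)) else map$freqs
  times <- if (is.matrix(map)) seq_len(ncol(vals)) else map$times
  df <- as.data.frame(vals)
  names(df) <- paste0("t", times)
  df <- cbind(freq = freqs, df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}
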