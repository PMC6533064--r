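# ggplot2 displays for the result types.

tf_raster <- function(df, fill, fill_label) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = {{ fill }})) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = fill_label) +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ersp <- function(object, ...) {
  tf_raster(tidy(object), .data$db, "dB")
}

#' @export
autoplot.beta_map <- function(object, ...) {
  tf_raster(tidy(object), .data$beta, "slope")
}

#' @export
autoplot.stat_map <- function(object, ...) {
  df <- tidy(object)
  tf_raster(df, .data$estimate, "estimate") +
    ggplot2::geom_tile(data = df[df$significant, ], fill = NA,
                       colour = "black", linewidth = 0.2)
}

#' @export
autoplot.plv_matrix <- function(object, ...) {
  tf_raster(tidy(object), .data$plv, "PLV")
}

#' @export
autoplot.granger_estimate <- function(object, ...) {
  df <- tidy(object)
  df$direction <- factor(df$direction, c("xy", "yx"),
                         c("x %->% y", "y %->% x"))
  tf_raster(df, .data$pct_change, "% change") +
    ggplot2::facet_wrap(~direction, ncol = 1,
                        labeller = ggplot2::label_parsed)
}

#' @export
autoplot.onset_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$diff)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$significant, ], colour = "#b2182b",
                        size = 0.8) +
    ggplot2::geom_vline(xintercept = object$onset, linetype = 2) +
    ggplot2::labs(x = "time (ms)", y = "stop - matched-go difference") +
    ggplot2::theme_minimal()
}

#' Plot per-montage contact-selection diagnostics
#'
#' @param x A `contact_selection` from [select_stn_contact()] (spectra) or
#'   [select_motor_contact()] (scores only).
#' @param ... Unused.
#' @export
autoplot.contact_selection <- function(x, ...) {
  object <- x
  if (!is.null(object$spectra)) {
    ggplot2::ggplot(object$spectra,
                    ggplot2::aes(.data$freq, .data$detrended,
                                 colour = factor(.data$montage))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "frequency (Hz)", y = "1/f-detrended log power",
                    colour = "montage") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$scores,
                    ggplot2::aes(factor(.data$montage), .data$score)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "montage", y = "peri-response beta ERSP (dB)") +
      ggplot2::theme_minimal()
  }
}
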