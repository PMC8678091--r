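#' Plot a stimulus series with its threshold and events
#'
#' @param object A `coact_series` tibble.
#' @param threshold Threshold line to draw (z-units).
#' @param events Optional `coact_events` tibble; crossings are marked.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.coact_series <- function(object, threshold = 1, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$z)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Time (s)", y = "Stimulus series (z)",
                  title = sprintf("%s stimulus series", object$phase[1])) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_point(
      data = tibble(time_s = events$crossing_time_s,
                    z = object$z[events$crossing + 1]),
      colour = "firebrick", size = 2)
  }
  p
}

#' Plot delay histograms per group
#'
#' Bar panels of the delay distribution (TR units), faceted by the
#' grouping keys if any.
#'
#' @param object A `coact_delay_hist` tibble from [delay_histogram()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.coact_delay_hist <- function(object, ...) {
  keys <- setdiff(names(object), c("bin_left", "bin_mid", "count"))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_mid[1:2]) * 0.95,
                      fill = "steelblue") +
    ggplot2::labs(x = "Delay (TR)", y = "Events") +
    ggplot2::theme_minimal()
  if (length(keys)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(keys, collapse = "+"))))
  }
  p
}

#' Forest plot of marginal-trend contrasts
#'
#' Estimates with confidence intervals on the probability scale, one
#' row per contrast, strongest effects first.
#'
#' @param object A `coact_contrasts` tibble from [marginal_trends()].
#' @param top Show at most this many contrasts (by adjusted p).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.coact_contrasts <- function(object, top = 30, ...) {
  keys <- setdiff(names(object),
                  c("contrast", "estimate", "se", "df", "z_ratio",
                    "p_adj", "ci_lo", "ci_hi"))
  df <- as_tibble(object)
  df$label <- do.call(paste, c(df[c("contrast", keys)], sep = " | "))
  df <- head(arrange(df, .data$p_adj), top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$label, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_adj < 0.05), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50"),
                                 name = "p_adj < 0.05") +
    ggplot2::labs(x = "Trend contrast (probability scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cell correlations by condition
#'
#' Distribution of Fisher-z cell values split by probe and phase.
#'
#' @param object A `coact_cells` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.coact_cells <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$probe, y = .data$fisher_z,
                                       fill = .data$response)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = "Probe", y = "Fisher z of mean event correlation") +
    ggplot2::theme_minimal()
}
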