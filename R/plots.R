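#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fold-change vs noise scatter (significance view)
#'
#' Standard error of the log cleaved:uncleaved ratio against the fold change
#' of cleavage, with significant responders highlighted and the
#' fold-change threshold marked — the standard diagnostic view of a
#' cleavage-sequencing comparison.
#'
#' @param records Fold-change tibble; if a `significant` column is absent,
#'   pass `n_tested` to call it here.
#' @param n_tested Optional Bonferroni family size.
#' @param fc_threshold Threshold line (default 2).
#' @return A ggplot.
#' @export
plot_fold_change <- function(records, n_tested = NULL, fc_threshold = 2) {
  if (!"significant" %in% names(records)) {
    if (is.null(n_tested)) {
      abort("Provide `n_tested` or records with a `significant` column.",
            class = "ribosense_input_error")
    }
    records <- call_significant(records, n_tested, fc_threshold = fc_threshold)
  }
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$fc, y = .data$se_log_fc,
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(1 / fc_threshold, fc_threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "fold change of cleavage",
                  y = "SE of log cleaved:uncleaved ratio",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Heatmap of a response matrix
#'
#' @param matrix Long response tibble (`sensor_id`, `condition_id`, `fc`).
#' @param order_by Optional clustering from [cluster_sensors()] used to
#'   order the sensor axis by dendrogram order.
#' @return A ggplot.
#' @export
plot_response_matrix <- function(matrix, order_by = NULL) {
  assert_columns(matrix, c("sensor_id", "condition_id", "fc"))
  data <- matrix
  if (!is.null(order_by)) {
    hc <- attr(order_by, "hclust")
    if (!is.null(hc)) {
      data$sensor_id <- factor(data$sensor_id, levels = hc$labels[hc$order])
    }
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data$condition_id,
                                     y = .data$sensor_id,
                                     fill = log2(.data$fc))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "condition", y = "sensor",
                  fill = "log2 fold change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @describeIn cross_reactivity Cumulative cross-reactivity curves: number
#'   of compounds with cross-reactivity at most C, one line per fold
#'   threshold.
#' @param object A `cross_reactivity`.
#' @param ... Unused.
#' @export
autoplot.cross_reactivity <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$C, y = .data$n_compounds,
                               colour = factor(.data$f))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cross-reactivity C (compounds)",
                  y = "compounds with XR <= C",
                  colour = "fold threshold f") +
    ggplot2::theme_minimal()
}

#' @describeIn run_selection Abundance trajectories over selection rounds
#'   (log10 scale), amplicons dashed.
#' @param object A `selection_trajectory`.
#' @param top_n Plot only the `top_n` most abundant final sensors.
#' @param ... Unused.
#' @export
autoplot.selection_trajectory <- function(object, top_n = 30, ...) {
  long <- tidy(object)
  final <- object$abundance[nrow(object$abundance), ]
  keep <- names(sort(final, decreasing = TRUE))[
    seq_len(min(top_n, length(final)))]
  long <- long[long$sensor_id %in% keep, ]
  long$is_amplicon <- long$sensor_id %in%
    object$sensor_id[object$is_amplicon]
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$round, y = .data$abundance,
                               group = .data$sensor_id,
                               linetype = .data$is_amplicon)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "selection round", y = "relative abundance",
                  linetype = "amplicon") +
    ggplot2::theme_minimal()
}

#' Dose-response curves for sensor-compound series
#'
#' @param series Dose tibble (`sensor_id`, `compound_id`,
#'   `concentration_uM`, `fc`; optional `ci95_lo`, `ci95_hi` for error
#'   bars).
#' @param fc_threshold Detection threshold line.
#' @return A ggplot.
#' @export
plot_dose_response <- function(series, fc_threshold = 2) {
  assert_columns(series, c("sensor_id", "compound_id", "concentration_uM",
                           "fc"))
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$concentration_uM, y = .data$fc,
                                    colour = .data$sensor_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point()
  if (all(c("ci95_lo", "ci95_hi") %in% names(series))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci95_lo, ymax = .data$ci95_hi), width = 0.05)
  }
  p +
    ggplot2::geom_hline(yintercept = fc_threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~compound_id) +
    ggplot2::labs(x = "concentration (uM)", y = "fold change of cleavage",
                  colour = "sensor") +
    ggplot2::theme_minimal()
}
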