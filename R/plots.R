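#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of differential expression
#'
#' Log2 fold change against -log10 p-value, with the two-criterion filter
#' thresholds drawn and passing genes highlighted.
#'
#' @param object A `netsam_de` tibble from [differential_expression()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.netsam_de <- function(object, ...) {
  fc_thr <- attr(object, "fc_threshold") %||% 2
  p_thr <- attr(object, "p_threshold") %||% 0.01
  df <- tibble::tibble(
    lfc = object$mean_case - object$mean_control,
    nlp = -log10(pmax(object$p_value, 1e-300)),
    pass = object$pass_filter
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc, y = .data$nlp,
                                   colour = .data$pass)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_thr),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_thr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "DE") +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 p-value") +
    ggplot2::theme_minimal()
}

#' ROC curve of an edge-recovery evaluation
#'
#' @param object An `edge_eval` from [edge_recovery_metrics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edge_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate") +
    ggplot2::theme_minimal()
}

#' Log-log degree distribution of a network
#'
#' Degree frequency against degree on log scales; a scale-free network is
#' close to a straight line.
#'
#' @param object A [gene_network()] or [differential_network()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_network <- function(object, ...) {
  deg <- node_degrees(object)$degree
  df <- dplyr::count(tibble::tibble(degree = deg[deg > 0]), .data$degree)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "frequency") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gene_network
#' @export
autoplot.differential_network <- autoplot.gene_network

#' AUC by method across benchmark replicates
#'
#' @param object A `netsam_benchmark` tibble from [benchmark_methods()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.netsam_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "edge-recovery AUC") +
    ggplot2::theme_minimal()
}

#' Robustness curve: AUC against SNR
#'
#' @param object A `netsam_robustness` tibble from [robustness_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.netsam_robustness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$snr, y = .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$sd_auc,
                                      ymax = .data$mean_auc + .data$sd_auc),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "signal-to-noise ratio", y = "edge-recovery AUC") +
    ggplot2::theme_minimal()
}
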