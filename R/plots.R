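#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a ROC curve
#'
#' @param object A [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  auc <- attr(object, "auc")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$FPR, y = .data$TPR)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("ROC, %s rank", attr(object, "rank")),
      subtitle = if (is.na(auc)) "AUC undefined" else sprintf("AUC = %.3f", auc),
      x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Plot the barcode gap at family rank
#'
#' Maximum intrafamily divergence against minimum distance to the nearest
#' other family; families above the 1:1 line possess a barcode gap.
#'
#' @param object A [barcode_gap_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.barcode_gap <- function(object, ...) {
  df <- object[!is.na(object$gap_present), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_intra, y = .data$min_inter,
                                   colour = .data$gap_present)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Maximum intrafamily p-distance",
                  y = "Minimum interfamily p-distance",
                  colour = "Barcode gap") +
    ggplot2::theme_minimal()
}

#' Plot divergence-versus-richness fits
#'
#' Scatter of maximum intrafamily divergence against BIN count with the
#' fitted linear, logarithmic and (if converged) asymptotic curves.
#'
#' @param object A [fit_divergence_vs_richness()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.divergence_fits <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(x = seq(min(df$x), max(df$x), length.out = 200))
  curves <- purrr::imap(object$fits, function(fit, nm) {
    if (is.null(fit)) return(NULL)
    tibble::tibble(x = grid$x, y = stats::predict(fit, newdata = grid), model = nm)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$model), linewidth = 0.8) +
    ggplot2::labs(x = "BINs per family", y = "Maximum intrafamily p-distance",
                  colour = "Model") +
    ggplot2::theme_minimal()
}
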