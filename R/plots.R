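#' Plot a distortion scan
#'
#' HOMA scores of the inner and mean pyrrole circuits against the imposed
#' total out-of-plane amplitude.
#'
#' @param object A `porph_scan` from [distortion_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.porph_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("mode", "amplitude", "homa_inner", "homa_pyrrole_mean")],
    cols = c("homa_inner", "homa_pyrrole_mean"),
    names_to = "circuit", values_to = "homa")
  df$circuit <- c(homa_inner = "inner", homa_pyrrole_mean = "pyrrole (mean)")[df$circuit]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amplitude, y = .data$homa,
                                   colour = .data$circuit)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "total out-of-plane (Å)", y = "HOMA",
                  title = sprintf("Pure %s scan", object$mode[1])) +
    ggplot2::theme_minimal()
}

#' Plot a model report as a coefficient heatmap
#'
#' Fig-9-style heatmap of the standardized LASSO coefficients (or RF
#' permutation importances) per target and feature.
#'
#' @param object A `porph_model_report`.
#' @param model `"lasso"` or `"rf"`.
#' @param include_homa Include HOMA-score targets (default FALSE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.porph_model_report <- function(object, model = "lasso",
                                        include_homa = FALSE, ...) {
  df <- coefficient_table(object, include_homa = include_homa)
  df <- df[df$model == model, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$target,
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = if (model == "lasso") "coef" else "importance",
                  title = sprintf("%s (%s representation)", model,
                                  object$meta$variant)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
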