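#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a raster
#'
#' @param object A `grid_raster`.
#' @param ... Unused.
#' @return A ggplot raster map (masked cells blank).
#' @method autoplot grid_raster
#' @export
autoplot.grid_raster <- function(object, ...) {
  df <- tidy.grid_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey92") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Map the ensemble mean suitability
#'
#' @param object An `ensemble_prediction`.
#' @param layer `"mean"` (default), `"lower"` or `"upper"`.
#' @param ... Unused.
#' @return A ggplot map on the 0-1 suitability scale.
#' @method autoplot ensemble_prediction
#' @export
autoplot.ensemble_prediction <- function(object, layer = c("mean", "lower", "upper"),
                                         ...) {
  layer <- match.arg(layer)
  autoplot.grid_raster(object[[layer]]) +
    ggplot2::scale_fill_viridis_c(na.value = "grey92", limits = c(0, 1),
                                  name = "suitability") +
    ggplot2::ggtitle(sprintf("Ensemble %s suitability (%d members)",
                             layer, ncol(object$members)))
}

#' Replicate skill against the ensemble gates
#'
#' Scatter of held-out AUC versus TSS per replicate with the gate lines;
#' runs in the upper-right quadrant enter the ensemble.
#'
#' @param object A `model_runs` tibble.
#' @param auc_min,tss_min Gates to draw (defaults 0.8, 0.7).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot model_runs
#' @export
autoplot.model_runs <- function(object, auc_min = 0.8, tss_min = 0.7, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$auc, y = .data$tss,
                               colour = .data$algorithm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = auc_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = tss_min, linetype = 2) +
    ggplot2::labs(x = "held-out AUC", y = "held-out TSS") +
    ggplot2::theme_minimal()
}

#' Plot partial-dependence curves
#'
#' @param pd Tibble from [partial_dependence()] (rows from several models
#'   or covariates may be bound together; facet by covariate).
#' @return A ggplot of the marginal-effect curves.
#' @export
plot_partial_dependence <- function(pd) {
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$value, y = .data$yhat)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = "covariate value", y = "mean predicted suitability") +
    ggplot2::theme_minimal()
}
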