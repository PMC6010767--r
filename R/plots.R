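# ggplot2 graphics for fitted models.

#' Plot the variance decomposition
#'
#' Heatmap of the fraction of variance explained by each factor in each view;
#' the standard first look at a fitted model, showing which factors are
#' shared across data modalities and which are modality-specific.
#'
#' @param object A `mofa_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mofa_fit <- function(object, ...) {
  ve <- variance_explained(object)
  ggplot2::ggplot(ve, ggplot2::aes(x = factor(.data$factor), y = .data$view,
                                   fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey97", high = "#08306b",
                                 name = expression(R^2)) +
    ggplot2::labs(x = "Factor", y = "View",
                  title = "Variance explained per factor and view") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatterplot of samples in factor space
#'
#' @param fit A `mofa_fit`.
#' @param x,y Factor indices for the axes.
#' @param colour Optional vector (named by sample or in sample order) used to
#'   colour points, e.g. a clinical covariate.
#' @return A ggplot.
#' @export
plot_factors <- function(fit, x = 1, y = 2, colour = NULL) {
  stopifnot(inherits(fit, "mofa_fit"), fit$n_factors >= max(x, y))
  df <- tibble::tibble(
    sample = rownames(fit$factors),
    fx = fit$factors[, x],
    fy = fit$factors[, y]
  )
  if (!is.null(colour)) {
    df$colour <- if (!is.null(names(colour))) colour[df$sample] else colour
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$fx, .data$fy,
                                          colour = .data$colour))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$fx, .data$fy))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("Factor %d", x), y = sprintf("Factor %d", y)) +
    ggplot2::theme_minimal()
}

#' Ranked loadings of one factor in one view
#'
#' @param fit A `mofa_fit`.
#' @param view View name.
#' @param factor Factor index.
#' @param n Number of top features to label.
#' @return A ggplot of scaled absolute loadings against rank.
#' @export
plot_weights <- function(fit, view, factor, n = 10) {
  tf <- top_features(fit, view, factor, n = Inf)
  tf$label <- ifelse(tf$rank <= n, tf$feature, NA)
  ggplot2::ggplot(tf, ggplot2::aes(x = .data$rank,
                                   y = abs(.data$scaled_weight))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), na.rm = TRUE,
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "Rank", y = "Absolute scaled loading",
                  title = sprintf("%s, factor %d", view, factor)) +
    ggplot2::theme_minimal()
}

#' Training trace of the evidence lower bound
#'
#' @param fit A `mofa_fit`.
#' @return A ggplot of the ELBO per iteration, annotated with the number of
#'   active factors.
#' @export
plot_elbo <- function(fit) {
  stopifnot(inherits(fit, "mofa_fit"))
  ggplot2::ggplot(fit$elbo_trace,
                  ggplot2::aes(.data$iteration, .data$elbo,
                               colour = factor(.data$n_factors))) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = "Iteration", y = "ELBO", colour = "Factors") +
    ggplot2::theme_minimal()
}
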