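# Tidiers for fitted models (broom-style generics).

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted factor model
#'
#' @param x A `mofa_fit`.
#' @param what `"factors"` (sample-level factor values), `"weights"`
#'   (feature loadings per view) or `"variance"` (R-squared per factor and
#'   view).
#' @param ... Unused.
#' @return A tibble; see [get_factors()], [get_weights()],
#'   [variance_explained()].
#' @exportS3Method generics::tidy
tidy.mofa_fit <- function(x, what = c("factors", "weights", "variance"), ...) {
  what <- match.arg(what)
  switch(what,
    factors = get_factors(x),
    weights = get_weights(x),
    variance = variance_explained(x)
  )
}

#' One-row summary of a fitted factor model
#'
#' @param x A `mofa_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_factors`, `n_samples`, `n_views`, `elbo`,
#'   `n_iterations`, `converged`, `n_restarts`.
#' @exportS3Method generics::glance
glance.mofa_fit <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    n_samples = length(x$sample_names),
    n_views = length(x$likelihoods),
    elbo = x$elbo,
    n_iterations = x$n_iterations,
    converged = x$converged,
    n_restarts = nrow(x$restarts)
  )
}
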