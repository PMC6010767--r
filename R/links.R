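#' Link functions for non-Gaussian views
#'
#' `link_lambda()` is the softplus rate link \eqn{\lambda(x) = \log(1 + e^x)}
#' used by the Poisson noise model; `link_sigma()` is the logistic function
#' \eqn{\sigma(x) = 1 / (1 + e^{-x})} used by the Bernoulli noise model.
#' Both are overflow-safe over the whole double range.
#'
#' @param x Numeric vector or matrix of linear-predictor values.
#' @return Numeric object of the same shape as `x`.
#' @examples
#' link_lambda(0)   # log(2)
#' link_sigma(0)    # 0.5
#' @export
link_lambda <- function(x) {
  # log(1 + e^x) = max(x, 0) + log1p(exp(-|x|)) avoids overflow for large |x|
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' @rdname link_lambda
#' @export
link_sigma <- function(x) {
  stats::plogis(x)
}

# Curvature function of the Jaakkola-Jordan logistic bound:
# lambda_jj(xi) = tanh(xi/2) / (4 xi), with the analytic limit 1/8 at xi = 0.
jj_lambda <- function(xi) {
  xi <- abs(xi)
  small <- xi < 1e-4
  out <- numeric(length(xi))
  out[!small] <- tanh(xi[!small] / 2) / (4 * xi[!small])
  # series tanh(u)/u = 1 - u^2/3 + ... at u = xi/2
  out[small] <- (1 - xi[small]^2 / 12) / 8
  dim(out) <- dim(xi)
  out
}
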