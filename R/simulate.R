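#' Simulate multi-omics data from the generative factor model
#'
#' Draws a data set from the model fitted by [fit_mofa()], with known ground
#' truth: factors `Z ~ N(0, 1)`; per view, slab weights
#' `w-hat ~ N(0, 1/alpha_km)` with the ARD precision `alpha_km` taken from the
#' view-activity pattern (1 for an active factor/view pair, 1000 for an
#' inactive one, so inactive weights are negligible), spike indicators
#' `s ~ Bernoulli(theta)` and loadings `W = S * w-hat`. Gaussian views add
#' `N(0, 1/tau)` noise; Bernoulli views draw `Bernoulli(sigma(Z W'))`; Poisson
#' views draw `Poisson(lambda(Z W'))` with the softplus rate link. Missingness
#' is applied either to random values or to whole sample rows per view.
#'
#' @param n_samples Number of samples N.
#' @param n_features Integer vector, features per view (length = number of views).
#' @param n_factors True number of factors K.
#' @param likelihoods Character vector per view: `"gaussian"`, `"bernoulli"`,
#'   `"poisson"`.
#' @param activity Logical matrix (views x factors): is factor k active in view
#'   m? Default: all active. `activity = "random"` samples each cell with
#'   probability 1/2, forcing every factor to be active in at least one view.
#' @param theta Fraction of non-zero loadings for active factors (spike-and-slab
#'   inclusion probability). Default 0.5.
#' @param tau Gaussian noise precision. Default 1.
#' @param alpha_active,alpha_inactive ARD precisions used for active/inactive
#'   factor-view pairs. Defaults 1 and 1000.
#' @param missing Fraction of entries (or of samples, see `missing_mode`) masked
#'   as missing, in `[0, 1)`. Default 0.
#' @param missing_mode `"values"` masks random entries in every view;
#'   `"assays"` masks whole sample rows in the view(s) given by `missing_view`.
#' @param missing_view View index/indices for `missing_mode = "assays"`.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A list with `data` (an [omic_views()] object) and `truth` (list with
#'   `Z`, `W` per view, `activity`, `theta`, `tau`, `likelihoods`,
#'   `missing_fraction`, and the noise-free linear predictors `eta`).
#' @examples
#' sim <- sim_multiomics(n_samples = 20, n_features = c(15, 10), n_factors = 3,
#'                       seed = 1)
#' sim$data
#' @export
sim_multiomics <- function(n_samples, n_features, n_factors,
                           likelihoods = rep("gaussian", length(n_features)),
                           activity = NULL, theta = 0.5, tau = 1,
                           alpha_active = 1, alpha_inactive = 1e3,
                           missing = 0, missing_mode = c("values", "assays"),
                           missing_view = 1, seed = 1) {
  missing_mode <- match.arg(missing_mode)
  M <- length(n_features)
  stopifnot(n_samples >= 1, all(n_features >= 1), n_factors >= 1,
            length(likelihoods) == M, missing >= 0, missing < 1)
  if (!all(likelihoods %in% c("gaussian", "bernoulli", "poisson"))) {
    abort_validation("Unknown likelihood tag in %s.", paste(likelihoods, collapse = ", "))
  }
  withr::with_seed(as.integer(seed), {
    if (is.null(activity)) {
      activity <- matrix(TRUE, M, n_factors)
    } else if (identical(activity, "random")) {
      activity <- matrix(stats::runif(M * n_factors) < 0.5, M, n_factors)
      for (k in seq_len(n_factors)) {
        if (!any(activity[, k])) activity[sample.int(M, 1), k] <- TRUE
      }
    }
    if (!is.matrix(activity) || !all(dim(activity) == c(M, n_factors))) {
      abort_validation("`activity` must be a %d x %d logical matrix.", M, n_factors)
    }
    Z <- matrix(stats::rnorm(n_samples * n_factors), n_samples, n_factors)
    samples <- sprintf("sample_%03d", seq_len(n_samples))
    rownames(Z) <- samples
    colnames(Z) <- paste0("factor_", seq_len(n_factors))
    views <- list()
    W_true <- list()
    eta_true <- list()
    view_names <- sprintf("view_%d", seq_len(M))
    for (m in seq_len(M)) {
      D <- n_features[m]
      alpha <- ifelse(activity[m, ], alpha_active, alpha_inactive)
      What <- matrix(stats::rnorm(D * n_factors), D, n_factors) *
        matrix(sqrt(1 / alpha), D, n_factors, byrow = TRUE)
      S <- matrix(stats::runif(D * n_factors) < theta, D, n_factors)
      W <- What * S
      eta <- Z %*% t(W)
      Y <- switch(likelihoods[m],
        gaussian = eta + matrix(stats::rnorm(n_samples * D, sd = sqrt(1 / tau)),
                                n_samples, D),
        bernoulli = matrix(stats::rbinom(n_samples * D, 1, link_sigma(eta)),
                           n_samples, D),
        poisson = matrix(stats::rpois(n_samples * D, link_lambda(eta)),
                         n_samples, D)
      )
      dimnames(Y) <- list(samples, sprintf("%s_f%04d", view_names[m], seq_len(D)))
      dimnames(W) <- list(colnames(Y), colnames(Z))
      mask <- matrix(TRUE, n_samples, D)
      if (missing > 0 && missing_mode == "values") {
        mask <- matrix(stats::runif(n_samples * D) >= missing, n_samples, D)
      }
      views[[view_names[m]]] <- list(Y = Y, mask = mask)
      W_true[[view_names[m]]] <- W
      eta_true[[view_names[m]]] <- eta
    }
    if (missing > 0 && missing_mode == "assays") {
      for (m in missing_view) {
        drop <- sample.int(n_samples, round(missing * n_samples))
        views[[m]]$mask[drop, ] <- FALSE
      }
      # every sample must stay observed somewhere
      if (length(missing_view) >= M) {
        abort_validation("Cannot mask whole assays in every view.")
      }
    }
    mats <- lapply(views, function(v) {
      y <- v$Y
      y[!v$mask] <- NA_real_
      y
    })
    data <- omic_views(mats, stats::setNames(likelihoods, view_names))
    truth <- list(
      Z = Z, W = W_true, activity = activity, theta = theta, tau = tau,
      likelihoods = stats::setNames(likelihoods, view_names),
      missing_fraction = missing, missing_mode = missing_mode, eta = eta_true,
      seed = as.integer(seed)
    )
    list(data = data, truth = truth)
  })
}

#' Named simulation scenarios
#'
#' Preset parameterizations of [sim_multiomics()] used throughout the package
#' for validation, mixed-likelihood comparison, view-activity recovery and
#' imputation experiments. Each scenario has a full-size variant and a
#' `"desk"` variant with fewer features for fast runs; the study design
#' (sample size, number of views, likelihood mix, missingness, true factor
#' count) is identical across variants.
#'
#' Scenarios:
#' * `model_validation`: 3 Gaussian views, N = 100, K = 10, 5% missing values.
#' * `model_comparison`: one view per likelihood (gaussian, bernoulli,
#'   poisson), N = 100, K = 10, 5% missing values.
#' * `activity_patterns`: Gaussian views only, no missing values, random
#'   view-activity pattern with ARD precisions in \{1, 1000\}; `n_factors`
#'   may be 10 (default) or 15.
#' * `imputation`: 2 Gaussian views, fully observed (masking is applied by the
#'   benchmark itself), K = 10.
#'
#' @param name Scenario name, see above.
#' @param scale `"full"` (D = 5000 per view) or `"desk"` (D = 500 per view;
#'   200 for `imputation`).
#' @param n_factors True factor count override (only used by
#'   `activity_patterns`).
#' @param seed Integer seed passed to [sim_multiomics()].
#' @return As [sim_multiomics()]: list with `data` and `truth`.
#' @examples
#' sim <- sim_scenario("model_comparison", scale = "desk", seed = 1)
#' @export
sim_scenario <- function(name = c("model_validation", "model_comparison",
                                  "activity_patterns", "imputation"),
                         scale = c("desk", "full"), n_factors = NULL, seed = 1) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  D <- if (scale == "full") 5000 else 500
  switch(name,
    model_validation = sim_multiomics(
      n_samples = 100, n_features = rep(D, 3), n_factors = n_factors %||% 10,
      likelihoods = rep("gaussian", 3), missing = 0.05, seed = seed
    ),
    model_comparison = sim_multiomics(
      n_samples = 100, n_features = rep(D, 3), n_factors = n_factors %||% 10,
      likelihoods = c("gaussian", "bernoulli", "poisson"),
      missing = 0.05, seed = seed
    ),
    activity_patterns = sim_multiomics(
      n_samples = 100, n_features = rep(D, 3), n_factors = n_factors %||% 10,
      likelihoods = rep("gaussian", 3), activity = "random",
      missing = 0, seed = seed
    ),
    imputation = sim_multiomics(
      n_samples = 100, n_features = rep(if (scale == "full") 5000 else 200, 2),
      n_factors = n_factors %||% 10, likelihoods = rep("gaussian", 2),
      missing = 0, seed = seed
    )
  )
}
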