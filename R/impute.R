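# Imputation from the fitted model and benchmark baselines.

#' Impute missing values from a fitted factor model
#'
#' Fills every unobserved entry directly from the model equation: the
#' posterior expectations give \eqn{E[Z] E[W]^T + \mu} on the Gaussian scale;
#' Bernoulli views are mapped through the logistic function (probability
#' scale) and Poisson views through the softplus rate link (rate scale).
#' Observed entries are returned untouched. Whole missing assays (samples
#' never measured in a view) are imputed the same way, borrowing strength
#' from the views in which the sample was observed.
#'
#' @param fit A `mofa_fit`.
#' @param data Data to complete; defaults to the training data stored in the
#'   fit.
#' @return A long tibble with columns `view`, `sample`, `feature`, `value`,
#'   `imputed` (`TRUE` where the value was filled in by the model).
#' @export
impute <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "mofa_fit"))
  views <- as_omic_views(data %||% fit$data, fit$likelihoods)
  Z <- fit$factors
  purrr::map_dfr(names(fit$weights), function(vn) {
    v <- views$views[[vn]]
    pred <- Z %*% t(fit$weights[[vn]]) +
      matrix(fit$intercepts[[vn]], nrow(Z), ncol(v$data), byrow = TRUE)
    pred <- switch(fit$likelihoods[[vn]],
      gaussian = pred,
      bernoulli = link_sigma(pred),
      poisson = link_lambda(pred)
    )
    vals <- ifelse(v$mask, v$data, pred)
    tibble::tibble(
      view = vn,
      sample = rep(views$sample_names, times = ncol(vals)),
      feature = rep(v$feature_names, each = nrow(vals)),
      value = as.vector(vals),
      imputed = as.vector(!v$mask)
    )
  })
}

# Feature-wise mean imputation: each missing entry gets its feature's
# observed mean (0 if the feature is never observed).
mean_impute_view <- function(y0, maskn) {
  mu <- masked_colmeans(y0, maskn > 0)
  ifelse(maskn > 0, y0, matrix(mu, nrow(y0), ncol(y0), byrow = TRUE))
}

# k-nearest-neighbour imputation in sample space. Pairwise distances are mean
# squared differences over the entries the two samples share across all
# views (so samples missing a whole assay still have neighbours through the
# other views); each missing entry is the mean over the k nearest samples
# that observe it.
knn_impute_view <- function(views, target, k = 5) {
  cat_y <- do.call(cbind, lapply(views$views, function(v) v$data * v$mask))
  cat_m <- do.call(cbind, lapply(views$views, function(v) v$mask * 1))
  N <- nrow(cat_y)
  # mean squared difference over shared observed entries
  overlap <- cat_m %*% t(cat_m)
  cross <- cat_y %*% t(cat_y)
  sq <- (cat_y^2) %*% t(cat_m)
  d2 <- (sq + t(sq) - 2 * cross) / pmax(overlap, 1)
  d2[overlap == 0] <- Inf
  diag(d2) <- Inf
  v <- views$views[[target]]
  y <- v$data * v$mask
  out <- y
  mu <- masked_colmeans(y, v$mask)
  for (n in seq_len(N)) {
    miss <- which(!v$mask[n, ])
    if (length(miss) == 0) next
    ord <- order(d2[n, ])
    for (j in miss) {
      donors <- ord[v$mask[ord, j]]
      donors <- donors[is.finite(d2[n, donors])]
      donors <- donors[seq_len(min(k, length(donors)))]
      out[n, j] <- if (length(donors) > 0) mean(y[donors, j]) else mu[j]
    }
  }
  out
}

#' Imputation benchmark with masking experiments
#'
#' Repeatedly masks observed data in a target view -- either random single
#' values or all measurements of randomly chosen samples (whole-assay
#' missingness) -- refits the factor model with a fixed number of factors,
#' imputes the masked entries, and scores the mean squared error against the
#' held-out truth. Built-in baselines: feature-wise mean imputation and
#' k-nearest-neighbour imputation (`k = 5`, sample-space neighbours, Euclidean
#' distance on observed intersections). Additional methods can be hooked in
#' as functions taking the masked [omic_views()] and the target view name and
#' returning a completed matrix.
#'
#' @param data An [omic_views()] object (or long data frame) with the ground
#'   truth; the benchmark masks a fraction of its observed entries.
#' @param mode `"values"` masks random entries; `"assays"` masks whole sample
#'   rows of the target view.
#' @param fraction Fraction of observed entries (or of samples for
#'   `"assays"`) masked per repetition; must be positive.
#' @param target_view View (name or index) in which entries are masked.
#' @param n_factors Number of factors, fixed during training (the variance
#'   criterion is ignored). Default 10.
#' @param n_repeats Number of masking repetitions. Default 15.
#' @param seed Master seed; each repetition derives its own.
#' @param extra_methods Optional named list of `function(views, target_view)`
#'   returning a completed target-view matrix (e.g. a SoftImpute wrapper).
#' @param control [mofa_control()] used for the refits.
#' @return A tibble of class `omifa_benchmark` with columns `method`, `rep`,
#'   `mse`. `summary()` reports mean MSE with standard errors.
#' @export
impute_benchmark <- function(data, mode = c("values", "assays"),
                             fraction = 0.1, target_view = 1, n_factors = 10,
                             n_repeats = 15, seed = 1, extra_methods = NULL,
                             control = mofa_control(max_iter = 100)) {
  mode <- match.arg(mode)
  views <- as_omic_views(data)
  if (is.numeric(target_view)) target_view <- names(views$views)[target_view]
  v <- views$views[[target_view]]
  if (is.null(v)) abort_validation("Unknown target view '%s'.", target_view)
  if (fraction <= 0) {
    abort_validation("`fraction` must be positive: masking nothing leaves an empty evaluation set.")
  }
  rows <- list()
  for (r in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, r)
    masked <- withr::with_seed(rep_seed, {
      mask_new <- v$mask
      if (mode == "values") {
        obs <- which(v$mask)
        hide <- sample(obs, max(1, round(fraction * length(obs))))
        mask_new[hide] <- FALSE
      } else {
        rows_obs <- which(rowSums(v$mask) > 0)
        hide_rows <- sample(rows_obs, max(1, round(fraction * length(rows_obs))))
        mask_new[hide_rows, ] <- FALSE
      }
      mask_new
    })
    held_out <- v$mask & !masked
    masked_views <- views
    masked_views$views[[target_view]]$mask <- masked
    masked_views$views[[target_view]]$data <- v$data * masked
    truth <- v$data[held_out]
    mse <- function(x) mean((x[held_out] - truth)^2)
    fit <- fit_mofa(masked_views, n_factors = n_factors, fix_n_factors = TRUE,
                    n_restarts = 1, seed = rep_seed, control = control)
    pred <- fit$factors %*% t(fit$weights[[target_view]]) +
      matrix(fit$intercepts[[target_view]], prep_n(views), ncol(v$data), byrow = TRUE)
    pred <- switch(fit$likelihoods[[target_view]],
                   gaussian = pred, bernoulli = link_sigma(pred),
                   poisson = link_lambda(pred))
    res <- c(model = mse(pred),
             mean = mse(mean_impute_view(masked_views$views[[target_view]]$data,
                                         masked * 1)),
             knn = mse(knn_impute_view(masked_views, target_view)))
    for (nm in names(extra_methods)) {
      res[nm] <- mse(extra_methods[[nm]](masked_views, target_view))
    }
    rows[[r]] <- tibble::tibble(method = names(res), rep = r, mse = unname(res))
  }
  structure(dplyr::bind_rows(rows), class = c("omifa_benchmark", "tbl_df",
                                              "tbl", "data.frame"))
}

prep_n <- function(views) length(views$sample_names)

#' @export
summary.omifa_benchmark <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$method),
    n = dplyr::n(),
    mean_mse = mean(.data$mse),
    se_mse = stats::sd(.data$mse) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}

#' @export
print.omifa_benchmark <- function(x, ...) {
  cat("Imputation benchmark (mean squared error over repetitions)\n")
  print(summary(x))
  invisible(x)
}
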