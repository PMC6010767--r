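# Interpretation suite: variance decomposition, loading inspection,
# feature-set enrichment.

# Rebuild engine-scale targets (centred data for gaussian views, centred
# pseudo-data for non-gaussian views) and masks from a fitted model.
fit_targets <- function(fit, data = NULL) {
  views <- data %||% fit$data
  if (is.null(views)) {
    rlang::abort("The fit does not store its data; pass `data` explicitly.")
  }
  views <- as_omic_views(views, fit$likelihoods)
  out <- list()
  for (vn in names(fit$weights)) {
    v <- views$views[[vn]]
    if (is.null(v)) rlang::abort(sprintf("View '%s' not present in `data`.", vn))
    maskn <- v$mask * 1
    if (fit$likelihoods[[vn]] == "gaussian") {
      mu <- fit$intercepts[[vn]]
      yt <- (v$data * maskn - matrix(mu, nrow(maskn), ncol(maskn), byrow = TRUE)) * maskn
    } else {
      yt <- fit$pseudo[[vn]]$yt
    }
    out[[vn]] <- list(yt = yt, maskn = maskn, data = v$data * maskn)
  }
  out
}

#' Variance decomposition of a fitted factor model
#'
#' Computes the fraction of variance (R-squared) that each factor explains in
#' each view, and the total explained per view using all factors jointly:
#' \deqn{R^2_{m,k} = 1 - \sum_{n,d}(y_{nd} - z_{nk} w_{kd} - \mu_d)^2 /
#'   \sum_{n,d}(y_{nd} - \mu_d)^2}
#' with sums over observed entries only and all model variables at their
#' posterior expectations. For Bernoulli and Poisson views the decomposition
#' is computed on the Gaussian pseudo-data scale produced by the likelihood
#' bounds (documented in the methods vignette).
#'
#' @param fit A `mofa_fit`.
#' @param data Training data, only needed if the fit was not stored with data.
#' @param by `"factor"` (default) for the per-factor decomposition or
#'   `"view"` for the all-factor total per view.
#' @return A tibble with columns `view`, `factor`, `r2` (`by = "factor"`), or
#'   `view`, `r2` (`by = "view"`). `r2` is `NA` for a constant view (zero
#'   total variance), with a warning.
#' @export
variance_explained <- function(fit, data = NULL, by = c("factor", "view")) {
  by <- match.arg(by)
  stopifnot(inherits(fit, "mofa_fit"))
  targets <- fit_targets(fit, data)
  Z <- fit$factors
  rows <- list()
  for (vn in names(targets)) {
    yt <- targets[[vn]]$yt
    maskn <- targets[[vn]]$maskn
    W <- fit$weights[[vn]]
    ss_tot <- sum(yt^2)
    if (ss_tot <= 0) {
      rlang::warn(sprintf("View '%s' has zero total variance; R2 undefined.", vn))
      r2k <- rep(NA_real_, fit$n_factors)
      r2v <- NA_real_
    } else if (by == "factor") {
      r2k <- vapply(seq_len(fit$n_factors), function(k) {
        cross <- as.numeric(t(Z[, k]) %*% yt %*% W[, k])
        ss_pred <- as.numeric(t(Z[, k]^2) %*% maskn %*% (W[, k]^2))
        1 - (ss_tot - 2 * cross + ss_pred) / ss_tot
      }, 0)
    } else {
      pred <- Z %*% t(W)
      r2v <- 1 - sum(maskn * (yt - pred)^2) / ss_tot
    }
    rows[[vn]] <- if (by == "factor") {
      tibble::tibble(view = vn, factor = seq_len(fit$n_factors), r2 = r2k)
    } else {
      tibble::tibble(view = vn, r2 = r2v)
    }
  }
  dplyr::bind_rows(rows)
}

#' Factor values of a fitted model
#'
#' @param fit A `mofa_fit`.
#' @return Tibble with columns `sample`, `factor`, `value` (posterior mean of
#'   the latent factor): the sample ordination coordinates.
#' @export
get_factors <- function(fit) {
  stopifnot(inherits(fit, "mofa_fit"))
  Z <- fit$factors
  tibble::tibble(
    sample = rep(rownames(Z), times = ncol(Z)),
    factor = rep(seq_len(ncol(Z)), each = nrow(Z)),
    value = as.vector(Z)
  )
}

#' Loadings of a fitted model
#'
#' Because assays live on different scales, loadings of different views are
#' not directly comparable; `scaled_weight` divides each factor's loading
#' vector within a view by its maximum absolute entry so all scaled loadings
#' lie in \[-1, 1\].
#'
#' @param fit A `mofa_fit`.
#' @param views Optional character vector restricting the views returned.
#' @param scale_method `"max_abs"` (default) or `"l2"` for unit-norm scaling.
#' @return Tibble with columns `view`, `feature`, `factor`, `weight`,
#'   `scaled_weight`, `inclusion` (posterior probability the loading is
#'   non-zero).
#' @export
get_weights <- function(fit, views = NULL, scale_method = c("max_abs", "l2")) {
  stopifnot(inherits(fit, "mofa_fit"))
  scale_method <- match.arg(scale_method)
  views <- views %||% names(fit$weights)
  purrr::map_dfr(views, function(vn) {
    W <- fit$weights[[vn]]
    Ws <- apply(W, 2, scale_loadings, method = scale_method)
    if (is.null(dim(Ws))) Ws <- matrix(Ws, nrow(W), ncol(W))
    tibble::tibble(
      view = vn,
      feature = rep(rownames(W), times = ncol(W)),
      factor = rep(seq_len(ncol(W)), each = nrow(W)),
      weight = as.vector(W),
      scaled_weight = as.vector(Ws),
      inclusion = as.vector(fit$inclusion[[vn]])
    )
  })
}

# Scale one loading vector so its largest absolute entry is 1 (or to unit L2
# norm). An all-zero vector is returned unchanged, with a warning.
scale_loadings <- function(w, method = c("max_abs", "l2")) {
  method <- match.arg(method)
  s <- if (method == "max_abs") max(abs(w)) else sqrt(sum(w^2))
  if (s == 0) {
    rlang::warn("All-zero loading vector; returned unscaled.")
    return(w)
  }
  w / s
}

#' Top features of a factor
#'
#' Ranks the features of one view by absolute loading on one factor, the
#' primary tool for annotating what a factor captures. Ties are broken by
#' feature name so the ranking is deterministic.
#'
#' @param fit A `mofa_fit`.
#' @param view View name.
#' @param factor Factor index.
#' @param n Number of features to return (all if `n` exceeds the view size).
#' @return Tibble with columns `rank`, `feature`, `weight`, `scaled_weight`,
#'   `sign`.
#' @export
top_features <- function(fit, view, factor, n = 10) {
  stopifnot(inherits(fit, "mofa_fit"))
  W <- fit$weights[[view]]
  if (is.null(W)) abort_validation("Unknown view '%s'.", view)
  stopifnot(factor >= 1, factor <= ncol(W))
  w <- W[, factor]
  ws <- scale_loadings(w)
  ord <- order(-abs(w), names(w))
  ord <- ord[seq_len(min(n, length(ord)))]
  tibble::tibble(
    rank = seq_along(ord),
    feature = names(w)[ord],
    weight = unname(w[ord]),
    scaled_weight = unname(ws[ord]),
    sign = unname(ifelse(w[ord] >= 0, "+", "-"))
  )
}

#' Read feature sets in GMT format
#'
#' @param path Path to a GMT file (one set per line: name, description, then
#'   member feature labels, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_validation("GMT file not found: %s", path)
  fgsea::gmtPathways(path)
}

#' Feature-set enrichment on factor loadings
#'
#' Annotates factors by testing, for each feature set, whether the loadings of
#' features in the set (foreground) differ in mean from the loadings of
#' features outside it (background), using a parametric two-sample t-test.
#' P-values are adjusted per factor across sets with the Benjamini-Hochberg
#' procedure, and sets are flagged significant at the given false discovery
#' rate (default 1%).
#'
#' @param fit A `mofa_fit`.
#' @param view View whose loadings are tested.
#' @param sets Named list of character vectors of feature labels (e.g. from
#'   [read_gmt()]).
#' @param factors Factor indices to test (default: all).
#' @param statistic `"signed"` (default) tests raw loadings; `"absolute"`
#'   tests absolute loadings.
#' @param alternative Test sidedness, as in [stats::t.test()]. Default
#'   two-sided.
#' @param fdr Significance threshold on the adjusted p-value. Default 0.01.
#' @param min_size Minimum number of matched features for a set to be tested
#'   (smaller sets are reported with `NA` statistics and a `note`). Default 2.
#' @return Tibble with one row per (factor, set): `factor`, `set`, `n_set`,
#'   `n_matched`, `statistic`, `p_value`, `p_adjust`, `significant`, `note`.
#'   Feature labels that match nothing in the view are counted via
#'   `n_set - n_matched`, never silently dropped.
#' @export
run_enrichment <- function(fit, view, sets, factors = NULL,
                           statistic = c("signed", "absolute"),
                           alternative = "two.sided", fdr = 0.01,
                           min_size = 2) {
  stopifnot(inherits(fit, "mofa_fit"))
  statistic <- match.arg(statistic)
  W <- fit$weights[[view]]
  if (is.null(W)) abort_validation("Unknown view '%s'.", view)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort_validation("`sets` must be a named list of feature sets.")
  }
  factors <- factors %||% seq_len(ncol(W))
  feats <- rownames(W)
  out <- purrr::map_dfr(factors, function(k) {
    w <- W[, k]
    if (statistic == "absolute") w <- abs(w)
    res <- purrr::map_dfr(names(sets), function(sn) {
      members <- unique(sets[[sn]])
      fg <- w[feats %in% members]
      bg <- w[!feats %in% members]
      if (length(fg) < min_size || length(bg) < min_size) {
        return(tibble::tibble(set = sn, n_set = length(members),
                              n_matched = length(fg), statistic = NA_real_,
                              p_value = NA_real_,
                              note = sprintf("skipped: %d matched features (need >= %d in fore- and background)",
                                             length(fg), min_size)))
      }
      tt <- stats::t.test(fg, bg, alternative = alternative, var.equal = TRUE)
      tibble::tibble(set = sn, n_set = length(members), n_matched = length(fg),
                     statistic = unname(tt$statistic), p_value = tt$p.value,
                     note = NA_character_)
    })
    res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- !is.na(res$p_adjust) & res$p_adjust < fdr
    res$factor <- k
    res
  })
  dplyr::select(out, "factor", "set", "n_set", "n_matched", "statistic",
                "p_value", "p_adjust", "significant", "note")
}
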