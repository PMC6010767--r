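#' Assemble a multi-view omics data set
#'
#' Builds the container used by [fit_mofa()]: a collection of samples-by-features
#' matrices (one per view/assay) aligned on a shared set of samples, each with an
#' observation mask and a likelihood tag. Samples are aligned by name, and the
#' sample set is the union across views: a sample absent from one assay is kept
#' as an all-missing row in that view rather than being dropped, so the latent
#' factors remain defined for every sample.
#'
#' @param data Either a data frame in long format with columns `view`, `sample`,
#'   `feature`, `value` (missing entries may be `NA` or simply absent), or a
#'   named list of numeric matrices with samples in rows (rownames = sample
#'   names, colnames = feature names). `NA` entries are treated as unobserved.
#' @param likelihoods Named character vector mapping view names to one of
#'   `"gaussian"`, `"bernoulli"`, `"poisson"`. Unnamed scalar recycles to all
#'   views. Default: all Gaussian.
#' @return An object of class `omic_views`: a list with `sample_names` and
#'   `views`, where each view holds `data` (N x D matrix), `mask` (logical,
#'   `TRUE` = observed), `likelihood` and `feature_names`.
#' @examples
#' d <- tibble::tibble(
#'   view = "rna", sample = rep(c("s1", "s2"), each = 2),
#'   feature = rep(c("g1", "g2"), 2), value = c(1, 2, NA, 4)
#' )
#' v <- omic_views(d)
#' v
#' @export
omic_views <- function(data, likelihoods = "gaussian") {
  if (is.data.frame(data)) {
    views <- views_from_long(data)
  } else if (is.list(data)) {
    views <- views_from_matrices(data)
  } else {
    abort_validation("`data` must be a long data frame or a named list of matrices.")
  }
  view_names <- names(views)
  if (is.null(names(likelihoods)) && length(likelihoods) == 1) {
    likelihoods <- stats::setNames(rep(likelihoods, length(views)), view_names)
  }
  bad <- setdiff(names(likelihoods), view_names)
  if (length(bad) > 0) {
    abort_validation("Likelihood given for unknown view(s): %s", paste(bad, collapse = ", "))
  }
  sample_names <- views[[1]]$sample_names
  out <- list(sample_names = sample_names, views = list())
  for (vn in view_names) {
    lik <- unname(likelihoods[vn] %||% "gaussian")
    if (!lik %in% c("gaussian", "bernoulli", "poisson")) {
      abort_validation("Unknown likelihood '%s' for view '%s'.", lik, vn)
    }
    v <- views[[vn]]
    check_likelihood_domain(v$data, v$mask, lik, vn)
    out$views[[vn]] <- list(
      name = vn, data = v$data, mask = v$mask, likelihood = lik,
      feature_names = colnames(v$data)
    )
  }
  structure(out, class = "omic_views")
}

views_from_long <- function(data) {
  need <- c("view", "sample", "feature", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort_validation("Long data frame is missing column(s): %s", paste(miss, collapse = ", "))
  }
  samples <- unique(as.character(data$sample))
  out <- list()
  for (vn in unique(as.character(data$view))) {
    dv <- data[data$view == vn, , drop = FALSE]
    feats <- unique(as.character(dv$feature))
    dup <- dv[duplicated(dv[c("sample", "feature")]), , drop = FALSE]
    if (nrow(dup) > 0) {
      abort_validation("Duplicate (sample, feature) entries in view '%s'.", vn)
    }
    m <- matrix(NA_real_, length(samples), length(feats),
                dimnames = list(samples, feats))
    m[cbind(match(as.character(dv$sample), samples),
            match(as.character(dv$feature), feats))] <- dv$value
    mask <- !is.na(m)
    m[!mask] <- 0
    out[[vn]] <- list(data = m, mask = mask, sample_names = samples)
  }
  for (vn in names(out)) out[[vn]]$sample_names <- samples
  out
}

views_from_matrices <- function(mats) {
  if (is.null(names(mats)) || any(names(mats) == "")) {
    abort_validation("List of view matrices must be named.")
  }
  ns <- vapply(mats, nrow, 1L)
  rn <- lapply(mats, rownames)
  if (all(vapply(rn, is.null, TRUE))) {
    if (length(unique(ns)) != 1) {
      abort_validation("Views have different row counts (%s) and no rownames to align on.",
                       paste(ns, collapse = ", "))
    }
    samples <- paste0("sample_", seq_len(ns[[1]]))
    mats <- lapply(mats, function(m) { rownames(m) <- samples; m })
  } else if (any(vapply(rn, is.null, TRUE))) {
    abort_validation("Either all or none of the view matrices must have rownames.")
  } else {
    samples <- unique(unlist(rn))
  }
  out <- list()
  for (vn in names(mats)) {
    m0 <- mats[[vn]]
    if (is.null(colnames(m0))) colnames(m0) <- paste0("feature_", seq_len(ncol(m0)))
    if (anyDuplicated(colnames(m0))) {
      abort_validation("Duplicate feature names in view '%s'.", vn)
    }
    if (anyDuplicated(rownames(m0))) {
      abort_validation("Duplicate sample names in view '%s'.", vn)
    }
    samples_here <- rownames(m0) %||% samples
    m <- matrix(NA_real_, length(samples), ncol(m0),
                dimnames = list(samples, colnames(m0)))
    m[samples_here, ] <- m0
    mask <- !is.na(m)
    m[!mask] <- 0
    out[[vn]] <- list(data = m, mask = mask, sample_names = samples)
  }
  out
}

check_likelihood_domain <- function(data, mask, likelihood, view_name) {
  obs <- data[mask]
  if (likelihood == "bernoulli" && length(obs) > 0 && !all(obs %in% c(0, 1))) {
    abort_validation("View '%s' is tagged bernoulli but contains observed values outside {0, 1}.",
                     view_name)
  }
  if (likelihood == "poisson" && length(obs) > 0 &&
      (any(obs < 0) || any(abs(obs - round(obs)) > 1e-8))) {
    abort_validation("View '%s' is tagged poisson but contains negative or non-integer observed values.",
                     view_name)
  }
  invisible(TRUE)
}

#' Validate a multi-view data set
#'
#' Scans an [omic_views()] object for structural problems. Fatal
#' inconsistencies (mismatched shapes, values outside the domain of the
#' declared likelihood, samples observed in no view) raise an error of class
#' `omifa_validation_error`; non-fatal findings (all-missing features, constant
#' features, samples missing whole assays) are returned as a diagnostics table.
#'
#' @param x An `omic_views` object.
#' @return A tibble with columns `severity`, `view`, `item`, `message`; zero
#'   rows for a fully consistent data set.
#' @export
validate_views <- function(x) {
  stopifnot(inherits(x, "omic_views"))
  n <- length(x$sample_names)
  diags <- list()
  note <- function(severity, view, item, message) {
    diags[[length(diags) + 1]] <<- tibble::tibble(
      severity = severity, view = view, item = item, message = message
    )
  }
  if (length(x$views) < 1) abort_validation("Data set has no views.")
  observed_somewhere <- rep(FALSE, n)
  for (v in x$views) {
    if (!all(dim(v$data) == dim(v$mask))) {
      abort_validation("View '%s': data and mask shapes differ.", v$name)
    }
    if (nrow(v$data) != n) {
      abort_validation("View '%s' has %d rows but the data set has %d samples.",
                       v$name, nrow(v$data), n)
    }
    check_likelihood_domain(v$data, v$mask, v$likelihood, v$name)
    observed_somewhere <- observed_somewhere | rowSums(v$mask) > 0
    nobs <- colSums(v$mask)
    for (j in which(nobs == 0)) {
      note("warning", v$name, v$feature_names[j], "feature has no observed values")
    }
    const <- which(nobs > 1 & apply_masked_var(v$data, v$mask) == 0)
    for (j in const) {
      note("warning", v$name, v$feature_names[j], "feature is constant across observed samples")
    }
    absent <- which(rowSums(v$mask) == 0)
    if (length(absent) > 0 && length(absent) < n) {
      note("info", v$name, paste(x$sample_names[absent], collapse = ","),
           sprintf("%d sample(s) missing this whole assay", length(absent)))
    }
  }
  if (!all(observed_somewhere)) {
    abort_validation("Sample(s) observed in no view: %s",
                     paste(x$sample_names[!observed_somewhere], collapse = ", "))
  }
  if (length(diags) == 0) {
    return(tibble::tibble(severity = character(), view = character(),
                          item = character(), message = character()))
  }
  dplyr::bind_rows(diags)
}

apply_masked_var <- function(x, mask) {
  n <- colSums(mask)
  mu <- masked_colmeans(x, mask)
  ss <- colSums((x - matrix(mu, nrow(x), ncol(x), byrow = TRUE))^2 * mask)
  ifelse(n > 1, ss / (n - 1), NA_real_)
}

#' @export
print.omic_views <- function(x, ...) {
  cat(sprintf("Multi-omics data set: %d samples, %d view(s)\n",
              length(x$sample_names), length(x$views)))
  for (v in x$views) {
    cat(sprintf("  %-12s %5d features  %-9s  %.1f%% observed\n",
                v$name, ncol(v$data), v$likelihood, 100 * mean(v$mask)))
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.omic_views <- function(x, ...) {
  purrr::map_dfr(x$views, function(v) {
    vals <- ifelse(v$mask, v$data, NA_real_)
    tibble::tibble(
      view = v$name,
      sample = rep(x$sample_names, times = ncol(vals)),
      feature = rep(v$feature_names, each = nrow(vals)),
      value = as.vector(vals)
    )
  })
}

# Coerce user input (omic_views or long data frame) for fitting.
as_omic_views <- function(data, likelihoods = "gaussian") {
  if (inherits(data, "omic_views")) data else omic_views(data, likelihoods)
}
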