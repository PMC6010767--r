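# File input/output: delimited view matrices and the model container.

#' Read view matrices from delimited files
#'
#' Reads one TSV/CSV matrix per view (header row of feature names, first
#' column of sample names) and assembles an [omic_views()] data set. Samples
#' are aligned by name across files and the sample set is their union: a
#' sample absent from a file becomes an all-missing row in that view. Empty
#' cells and `NA` become masked entries.
#'
#' @param paths Character vector of file paths; names become view names
#'   (defaults to file basenames without extension).
#' @param likelihoods Named character vector of likelihood tags per view
#'   (default gaussian).
#' @param transpose Logical (recycled): `TRUE` for files stored with features
#'   in rows, which are transposed at read time.
#' @return An [omic_views()] object.
#' @export
read_views <- function(paths, likelihoods = "gaussian", transpose = FALSE) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  transpose <- rep_len(transpose, length(paths))
  mats <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p)) abort_validation("Input file not found: %s", p)
    reader <- if (grepl("\\.csv$", p, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
    df <- reader(p, show_col_types = FALSE, progress = FALSE,
                 name_repair = "minimal")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      abort_validation("Duplicate %s names in %s.",
                       if (transpose[i]) "feature" else "sample", p)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (anyDuplicated(colnames(m))) {
      abort_validation("Duplicate %s names in %s.",
                       if (transpose[i]) "sample" else "feature", p)
    }
    if (transpose[i]) m <- t(m)
    mats[[names(paths)[i]]] <- m
  }
  omic_views(mats, likelihoods)
}

#' Write view matrices to delimited files
#'
#' Inverse of [read_views()]: one TSV per view (`<view>.tsv` in `dir`),
#' samples in rows, masked entries written as `NA`.
#'
#' @param views An [omic_views()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_views <- function(views, dir) {
  stopifnot(inherits(views, "omic_views"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in views$views) {
    vals <- ifelse(v$mask, v$data, NA_real_)
    df <- tibble::as_tibble(vals)
    df <- dplyr::bind_cols(tibble::tibble(sample = views$sample_names), df)
    p <- file.path(dir, paste0(v$name, ".tsv"))
    readr::write_tsv(df, p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

OMIFA_FORMAT_VERSION <- 1L

mat_to_json <- function(m) {
  list(dim = dim(m), dimnames = dimnames(m), values = as.vector(m))
}

mat_from_json <- function(x) {
  m <- matrix(unlist(x$values), x$dim[[1]], x$dim[[2]])
  if (!is.null(x$dimnames) && length(x$dimnames) == 2) {
    dimnames(m) <- lapply(x$dimnames, function(d) unlist(d) %||% NULL)
  }
  m
}

#' Save and load a fitted model
#'
#' Serializes a `mofa_fit` to a single versioned JSON container holding all
#' posterior expectations, the ELBO trace, pruning events, configuration and
#' (if stored) the training data, and restores it losslessly: reloading
#' reproduces labels exactly and numeric values to full double precision, so
#' downstream analyses give identical results before and after a round trip.
#'
#' @param fit A `mofa_fit`.
#' @param path File path (conventionally `.json`).
#' @return `write_mofa` returns `path` invisibly; `read_mofa` returns the
#'   restored `mofa_fit`. Loading a file with a newer format version raises
#'   an explicit error.
#' @export
write_mofa <- function(fit, path) {
  stopifnot(inherits(fit, "mofa_fit"))
  payload <- list(
    format = "omifa_model",
    format_version = OMIFA_FORMAT_VERSION,
    n_factors = fit$n_factors,
    sample_names = fit$sample_names,
    likelihoods = as.list(fit$likelihoods),
    factors = mat_to_json(fit$factors),
    weights = lapply(fit$weights, mat_to_json),
    inclusion = lapply(fit$inclusion, mat_to_json),
    alpha = fit$alpha,
    theta = fit$theta,
    tau = fit$tau,
    intercepts = fit$intercepts,
    pseudo = lapply(fit$pseudo, function(p) lapply(p, mat_to_json)),
    elbo = fit$elbo,
    elbo_trace = fit$elbo_trace,
    pruning_events = fit$pruning_events,
    restarts = fit$restarts,
    converged = fit$converged,
    n_iterations = fit$n_iterations,
    config = fit$config,
    control = unclass(fit$control),
    data = if (!is.null(fit$data)) {
      list(sample_names = fit$data$sample_names,
           views = lapply(fit$data$views, function(v) {
             list(name = v$name, likelihood = v$likelihood,
                  data = mat_to_json(v$data), mask = mat_to_json(v$mask * 1))
           }))
    }
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_mofa
#' @export
read_mofa <- function(path) {
  if (!file.exists(path)) abort_validation("Model file not found: %s", path)
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = FALSE)
  if (!identical(x$format, "omifa_model")) {
    abort_validation("%s is not an omifa model container.", path)
  }
  if (x$format_version > OMIFA_FORMAT_VERSION) {
    abort_validation("Model file has format version %d; this build reads up to %d.",
                     x$format_version, OMIFA_FORMAT_VERSION)
  }
  num <- function(v) {
    out <- unlist(v)
    stats::setNames(as.numeric(out), names(out))
  }
  tib <- function(v) dplyr::bind_rows(lapply(v, tibble::as_tibble))
  data <- NULL
  if (!is.null(x$data)) {
    mats <- lapply(x$data$views, function(v) {
      m <- mat_from_json(v$data)
      mask <- mat_from_json(v$mask) > 0
      m[!mask] <- NA_real_
      m
    })
    names(mats) <- vapply(x$data$views, `[[`, "", "name")
    liks <- vapply(x$data$views, `[[`, "", "likelihood")
    names(liks) <- names(mats)
    data <- omic_views(mats, liks)
  }
  fit <- list(
    n_factors = as.integer(x$n_factors),
    factors = mat_from_json(x$factors),
    weights = lapply(x$weights, mat_from_json),
    inclusion = lapply(x$inclusion, mat_from_json),
    alpha = lapply(x$alpha, num),
    theta = lapply(x$theta, num),
    tau = lapply(x$tau, num),
    intercepts = lapply(x$intercepts, num),
    pseudo = lapply(x$pseudo, function(p) lapply(p, mat_from_json)),
    likelihoods = num_chr(x$likelihoods),
    sample_names = unlist(x$sample_names),
    elbo = as.numeric(x$elbo),
    elbo_trace = tib(x$elbo_trace),
    update_trace = NULL,
    pruning_events = if (length(x$pruning_events) > 0) {
      tib(x$pruning_events)
    } else {
      tibble::tibble(iteration = integer(), factor = integer())
    },
    restarts = tib(x$restarts),
    converged = isTRUE(x$converged),
    n_iterations = as.integer(x$n_iterations),
    config = x$config,
    control = do.call(mofa_control, drop_extra_control(x$control)),
    data = data,
    format_version = as.integer(x$format_version)
  )
  structure(fit, class = "mofa_fit")
}

num_chr <- function(v) {
  out <- unlist(v)
  stats::setNames(as.character(out), names(out))
}

drop_extra_control <- function(ctl) {
  ctl <- lapply(ctl, unlist)
  ctl[intersect(names(ctl), names(formals(mofa_control)))]
}
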