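#' Training control parameters
#'
#' Collects the tunable knobs of the variational training loop. Defaults are
#' the package's standard study conditions; see the methods vignette for the
#' rationale behind each.
#'
#' @param burn_in Iterations at the start of training during which the
#'   spike-and-slab sparsity is deactivated (inclusion probabilities clamped
#'   to 1) to avoid premature splitting of factors. Default 10.
#' @param max_iter Maximum number of variational iterations. Default 300.
#' @param tol Relative ELBO change between consecutive iterations below which
#'   training is considered converged. Default 1e-5.
#' @param prune_every After burn-in, factors are checked for pruning every
#'   this many iterations. Default 5.
#' @param prior_alpha,prior_tau Shape and rate of the uninformative Gamma
#'   priors on the ARD precisions and the gaussian noise precisions.
#'   Default `c(1e-5, 1e-5)`.
#' @param prior_theta Shape parameters of the Beta prior on the sparsity
#'   levels. Default `c(1, 1)` (uniform).
#' @param track_updates If `TRUE`, record the ELBO after every coordinate
#'   update inside each iteration (diagnostic; slows training). Default `FALSE`.
#' @param store_data If `TRUE` (default) the fitted object keeps the training
#'   data, so downstream functions need no extra arguments.
#' @param verbose Print per-iteration ELBO and factor count.
#' @return A named list of class `mofa_control`.
#' @export
mofa_control <- function(burn_in = 10, max_iter = 300, tol = 1e-5,
                         prune_every = 5,
                         prior_alpha = c(1e-5, 1e-5),
                         prior_theta = c(1, 1),
                         prior_tau = c(1e-5, 1e-5),
                         track_updates = FALSE, store_data = TRUE,
                         verbose = FALSE) {
  stopifnot(burn_in >= 0, max_iter >= 1, tol > 0, prune_every >= 1,
            all(prior_alpha > 0), all(prior_theta > 0), all(prior_tau > 0))
  structure(list(burn_in = burn_in, max_iter = max_iter, tol = tol,
                 prune_every = prune_every, prior_alpha = prior_alpha,
                 prior_theta = prior_theta, prior_tau = prior_tau,
                 track_updates = track_updates, store_data = store_data,
                 verbose = verbose),
            class = "mofa_control")
}

# One full training run: initialization, burn-in, coordinate updates,
# ELBO-monitored convergence and variance-based factor pruning.
train_once <- function(views, prep, n_factors, variance_threshold, fix_n_factors,
                       seed, control) {
  state <- init_state(prep, n_factors, control, seed)
  trace <- vector("list", control$max_iter)
  update_trace <- list()
  pruning_events <- list()
  elbo_prev <- NA_real_
  converged <- FALSE
  iter <- 0
  track <- function(iter, step) {
    if (control$track_updates) {
      e <- as.numeric(compute_elbo(state, prep, control))
      update_trace[[length(update_trace) + 1]] <<-
        tibble::tibble(iteration = iter, step = step, elbo = e)
    }
  }
  for (iter in seq_len(control$max_iter)) {
    sparsity_active <- iter > control$burn_in
    for (m in seq_along(state$views)) {
      state$views[[m]] <- update_weights_view(state$views[[m]], state$Z,
                                              sparsity_active)
    }
    track(iter, "weights")
    state <- update_factors(state, prep)
    track(iter, "factors")
    if (sparsity_active) {
      for (m in seq_along(state$views)) {
        state$views[[m]] <- update_sparsity_view(state$views[[m]], control)
      }
      track(iter, "sparsity")
    }
    for (m in seq_along(state$views)) {
      state$views[[m]] <- update_ard_view(state$views[[m]], control)
    }
    track(iter, "ard")
    for (m in seq_along(state$views)) {
      if (prep$views[[m]]$likelihood == "gaussian") {
        state$views[[m]] <- update_noise_view(state$views[[m]], prep$views[[m]],
                                              state$Z, control)
      } else {
        state$views[[m]] <- refresh_bound_view(state$views[[m]], prep$views[[m]],
                                               state$Z)
      }
    }
    track(iter, "noise_bounds")
    elbo <- as.numeric(compute_elbo(state, prep, control))
    pruned_now <- integer(0)
    # Pruning and convergence are evaluated on the same cadence: every
    # `prune_every` iterations after burn-in, comparing the ELBO with its
    # value at the previous check. A per-iteration criterion is too brittle
    # (coordinate ascent can plateau transiently while a redundant factor is
    # still being shrunk by the ARD prior).
    at_check <- sparsity_active &&
      (iter - control$burn_in) %% control$prune_every == 0
    if (at_check && !fix_n_factors) {
      pr <- prune_factors(state, prep, variance_threshold)
      state <- pr$state
      pruned_now <- pr$pruned
      if (length(pruned_now) > 0) {
        pruning_events[[length(pruning_events) + 1]] <-
          tibble::tibble(iteration = iter, factor = pruned_now)
      }
    }
    trace[[iter]] <- tibble::tibble(iteration = iter, elbo = elbo,
                                    n_factors = state$K,
                                    n_pruned = length(pruned_now))
    if (control$verbose) {
      message(sprintf("iter %4d  elbo %.4f  K = %d", iter, elbo, state$K))
    }
    if (state$K == 0) break
    if (at_check) {
      small_change <- is.finite(elbo_prev) &&
        abs(elbo - elbo_prev) < control$tol * abs(elbo)
      if (small_change && length(pruned_now) == 0) {
        converged <- TRUE
        break
      }
      elbo_prev <- elbo
    }
  }
  list(state = state,
       elbo = as.numeric(compute_elbo(state, prep, control)),
       elbo_trace = dplyr::bind_rows(trace[!vapply(trace, is.null, TRUE)]),
       update_trace = if (control$track_updates) dplyr::bind_rows(update_trace) else NULL,
       pruning_events = if (length(pruning_events) > 0) {
         dplyr::bind_rows(pruning_events)
       } else {
         tibble::tibble(iteration = integer(), factor = integer())
       },
       converged = converged, n_iterations = iter, seed = seed)
}

#' Fit the multi-omics factor model
#'
#' Decomposes multiple omics matrices over shared samples into latent factors
#' and view-specific sparse loadings by mean-field variational Bayes. Training
#' starts from `n_factors` factors, deactivates sparsity during a burn-in
#' period, prunes factors that explain less than `variance_threshold` of the
#' variance in every view, and monitors convergence through the evidence lower
#' bound (ELBO). Several independent restarts are run and the model with the
#' highest final ELBO is returned.
#'
#' @param data An [omic_views()] object, or a long data frame with columns
#'   `view`, `sample`, `feature`, `value`.
#' @param likelihoods Passed to [omic_views()] when `data` is a data frame.
#' @param n_factors Initial number of factors. Default 25.
#' @param variance_threshold Minimum fraction of variance explained (in at
#'   least one view) for a factor to survive pruning. Default 0.02.
#' @param fix_n_factors If `TRUE`, keep exactly `n_factors` factors and ignore
#'   the variance criterion. Default `FALSE`.
#' @param n_restarts Number of random restarts; the restart with the highest
#'   final ELBO is kept (ties broken by lowest restart index). Default 10.
#' @param seed Master seed; restart seeds are derived from it deterministically.
#' @param control A [mofa_control()] list.
#' @return An object of class `mofa_fit` with posterior expectations
#'   (`factors`, per-view `weights`, inclusion probabilities, ARD and noise
#'   precisions), the ELBO trace, pruning events, restart summary and (by
#'   default) the training data. Use [tidy()], [glance()],
#'   [variance_explained()], [top_features()], [run_enrichment()], [impute()]
#'   on it.
#' @examples
#' sim <- sim_multiomics(n_samples = 40, n_features = c(60, 40), n_factors = 2,
#'                       seed = 1)
#' fit <- fit_mofa(sim$data, n_factors = 4, n_restarts = 1, seed = 1,
#'                 control = mofa_control(max_iter = 60))
#' fit
#' @export
fit_mofa <- function(data, likelihoods = "gaussian", n_factors = 25,
                     variance_threshold = 0.02, fix_n_factors = FALSE,
                     n_restarts = 10, seed = 1, control = mofa_control()) {
  views <- as_omic_views(data, likelihoods)
  diags <- validate_views(views)
  if (nrow(diags) > 0 && control$verbose) {
    message(sprintf("validate_views: %d non-fatal finding(s).", nrow(diags)))
  }
  prep <- prep_data(views)
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    runs[[r]] <- train_once(views, prep, n_factors, variance_threshold,
                            fix_n_factors, derive_seed(seed, r - 1), control)
    if (control$verbose) {
      message(sprintf("restart %d/%d: elbo %.4f, K = %d",
                      r, n_restarts, runs[[r]]$elbo, runs[[r]]$state$K))
    }
  }
  elbos <- vapply(runs, `[[`, 0, "elbo")
  best <- which.max(elbos)  # ties: first (lowest restart index)
  run <- runs[[best]]
  restarts <- tibble::tibble(restart = seq_len(n_restarts), elbo = elbos,
                             n_factors = vapply(runs, function(x) x$state$K, 0L),
                             converged = vapply(runs, `[[`, TRUE, "converged"),
                             selected = seq_len(n_restarts) == best)
  as_mofa_fit(run, views, prep, control,
              config = list(n_factors = n_factors,
                            variance_threshold = variance_threshold,
                            fix_n_factors = fix_n_factors,
                            n_restarts = n_restarts, seed = seed),
              restarts = restarts)
}

# Freeze a training run into the user-facing fitted object (posterior
# expectations only, plus what downstream analyses need).
as_mofa_fit <- function(run, views, prep, control, config, restarts) {
  state <- run$state
  K <- state$K
  fac_names <- if (K > 0) paste0("factor_", seq_len(K)) else character(0)
  Zm <- state$Z$M
  colnames(Zm) <- fac_names
  view_names <- vapply(prep$views, `[[`, "", "name")
  weights <- list()
  inclusion <- list()
  alpha <- list()
  theta <- list()
  tau <- list()
  intercepts <- list()
  pseudo <- list()
  for (m in seq_along(prep$views)) {
    sv <- state$views[[m]]
    pv <- prep$views[[m]]
    W <- sv$W$Ew
    dimnames(W) <- list(pv$feature_names, fac_names)
    g <- sv$W$gamma
    dimnames(g) <- dimnames(W)
    weights[[pv$name]] <- W
    inclusion[[pv$name]] <- g
    alpha[[pv$name]] <- stats::setNames(sv$alpha$shape / sv$alpha$rate, fac_names)
    theta[[pv$name]] <- stats::setNames(sv$theta$a / (sv$theta$a + sv$theta$b),
                                        fac_names)
    intercepts[[pv$name]] <- stats::setNames(sv$intercept, pv$feature_names)
    if (pv$likelihood == "gaussian") {
      tau[[pv$name]] <- stats::setNames(sv$tau$shape / sv$tau$rate,
                                        pv$feature_names)
    } else {
      pseudo[[pv$name]] <- list(yt = sv$pseudo$yt, rho = sv$pseudo$rho)
    }
  }
  structure(list(
    n_factors = K,
    factors = Zm,
    weights = weights,
    inclusion = inclusion,
    alpha = alpha,
    theta = theta,
    tau = tau,
    intercepts = intercepts,
    pseudo = pseudo,
    likelihoods = stats::setNames(vapply(prep$views, `[[`, "", "likelihood"),
                                  view_names),
    sample_names = prep$sample_names,
    elbo = run$elbo,
    elbo_trace = run$elbo_trace,
    update_trace = run$update_trace,
    pruning_events = run$pruning_events,
    restarts = restarts,
    converged = run$converged,
    n_iterations = run$n_iterations,
    config = config,
    control = control,
    data = if (isTRUE(control$store_data)) views else NULL,
    format_version = 1L
  ), class = "mofa_fit")
}

#' @export
print.mofa_fit <- function(x, ...) {
  cat(sprintf("Multi-omics factor model: %d factor(s), %d sample(s), %d view(s)\n",
              x$n_factors, length(x$sample_names), length(x$likelihoods)))
  cat(sprintf("  ELBO %.2f after %d iteration(s)%s; %d restart(s)\n",
              x$elbo, x$n_iterations,
              if (x$converged) " (converged)" else "",
              nrow(x$restarts)))
  ve <- variance_explained(x, by = "view")
  for (i in seq_len(nrow(ve))) {
    cat(sprintf("  %-12s (%s): %.1f%% variance explained\n",
                ve$view[i], x$likelihoods[[ve$view[i]]], 100 * ve$r2[i]))
  }
  invisible(x)
}
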