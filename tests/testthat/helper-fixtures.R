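# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, fixture_env)) {
    assign(key, force(expr), fixture_env)
  }
  get(key, fixture_env)
}

# A small mixed-likelihood simulation and its fit, reused across test files.
fixture_small_sim <- function() {
  memo("small_sim", sim_multiomics(
    n_samples = 40, n_features = c(50, 30), n_factors = 3,
    likelihoods = c("gaussian", "gaussian"), seed = 101
  ))
}

fixture_small_fit <- function() {
  memo("small_fit", fit_mofa(
    fixture_small_sim()$data, n_factors = 6, n_restarts = 1, seed = 11,
    control = mofa_control(max_iter = 120)
  ))
}

# Random but internally consistent engine state over a tiny gaussian data
# set, after a few real updates so all moments are non-trivial.
fixture_tiny_state <- function(seed = 5, N = 6, D = c(5, 4), K = 2,
                               missing = 0.15, iterations = 3) {
  key <- paste("tiny", seed, N, K, iterations, missing, sep = "_")
  memo(key, {
    sim <- sim_multiomics(N, D, K, missing = missing, seed = seed)
    prep <- omifa:::prep_data(sim$data)
    control <- mofa_control()
    state <- omifa:::init_state(prep, K, control, seed)
    for (it in seq_len(iterations)) {
      for (m in seq_along(state$views)) {
        state$views[[m]] <- omifa:::update_weights_view(state$views[[m]],
                                                        state$Z, it > 1)
      }
      state <- omifa:::update_factors(state, prep)
      for (m in seq_along(state$views)) {
        if (it > 1) {
          state$views[[m]] <- omifa:::update_sparsity_view(state$views[[m]], control)
        }
        state$views[[m]] <- omifa:::update_ard_view(state$views[[m]], control)
        state$views[[m]] <- omifa:::update_noise_view(state$views[[m]],
                                                      prep$views[[m]], state$Z,
                                                      control)
      }
    }
    list(state = state, prep = prep, control = control, sim = sim)
  })
}

# Minimal hand-made fit object (weights only), for downstream unit tests
# that do not need a trained model.
fake_fit_weights <- function(W, view = "view_1") {
  structure(list(
    n_factors = ncol(W),
    weights = stats::setNames(list(W), view),
    inclusion = stats::setNames(list(matrix(1, nrow(W), ncol(W),
                                            dimnames = dimnames(W))), view),
    likelihoods = stats::setNames("gaussian", view),
    sample_names = character(0)
  ), class = "mofa_fit")
}
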