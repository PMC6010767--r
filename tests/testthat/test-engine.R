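# Coordinate updates against brute-force oracles, and the ELBO itself.

test_that("factor update matches the brute-force oracle on a small instance", {
  fx <- fixture_tiny_state(seed = 5, N = 6, D = c(5, 4), K = 2)
  state <- omifa:::update_factors(fx$state, fx$prep)
  oracle <- oracle_factor_update(
    lapply(fx$state$views, function(sv) sv$pseudo),
    lapply(fx$state$views, function(sv) sv$W),
    fx$state$K
  )
  expect_equal(unname(state$Z$M), oracle$M, tolerance = 1e-10)
  for (n in seq_len(fx$prep$N)) {
    expect_equal(matrix(state$Z$Svec[n, ], 2, 2), oracle$S[, , n],
                 tolerance = 1e-10)
  }
})

test_that("a sample with no observed data falls back to the standard-normal prior", {
  sim <- sim_multiomics(5, c(4, 3), 2, seed = 2)
  for (vn in names(sim$data$views)) {
    sim$data$views[[vn]]$mask[3, ] <- FALSE
    sim$data$views[[vn]]$data[3, ] <- 0
  }
  prep <- omifa:::prep_data(sim$data)
  fx_ctl <- mofa_control()
  state <- omifa:::init_state(prep, 2, fx_ctl, 1)
  state <- omifa:::update_factors(state, prep)
  expect_equal(unname(state$Z$M[3, ]), c(0, 0))
  expect_equal(matrix(state$Z$Svec[3, ], 2, 2), diag(2))
})

test_that("K = 1 factor posterior mean equals the hand-derived scalar formula", {
  withr::with_seed(31, {
    N <- 5; D <- 4
    w <- rnorm(D)
    tau <- runif(D, 0.5, 2)
    y <- matrix(rnorm(N * D), N, D)
    dimnames(y) <- list(paste0("s", 1:N), paste0("f", 1:D))
    views <- omic_views(list(v = y))
    prep <- omifa:::prep_data(views)
    ctl <- mofa_control()
    state <- omifa:::init_state(prep, 1, ctl, 1)
    # point-mass weights and fixed noise precisions
    state$views[[1]]$W <- list(gamma = matrix(1, D, 1), mu = matrix(w, D, 1),
                               s2 = matrix(0, D, 1), Ew = matrix(w, D, 1),
                               Ew2 = matrix(w^2, D, 1))
    state$views[[1]]$pseudo$rho <- matrix(tau, N, D, byrow = TRUE)
    yt <- state$views[[1]]$pseudo$yt
    state <- omifa:::update_factors(state, prep)
    for (n in seq_len(N)) {
      expected <- sum(tau * w * yt[n, ]) / (1 + sum(tau * w^2))
      expect_equal(state$Z$M[n, 1], expected, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  })
})

test_that("spike-and-slab weight update matches the loop oracle (with and without sparsity)", {
  for (sparsity in c(TRUE, FALSE)) {
    fx <- fixture_tiny_state(seed = 7, N = 6, D = c(5, 4), K = 2)
    sv <- fx$state$views[[1]]
    Ealpha <- sv$alpha$shape / sv$alpha$rate
    Elnth <- digamma(sv$theta$a) - digamma(sv$theta$a + sv$theta$b)
    Eln1mth <- digamma(sv$theta$b) - digamma(sv$theta$a + sv$theta$b)
    got <- omifa:::update_weights_view(sv, fx$state$Z, sparsity)
    oracle <- oracle_weight_update(sv$pseudo$yt, sv$pseudo$rho, fx$state$Z$M,
                                   fx$state$Z$Svec, sv$W$Ew, Ealpha,
                                   Elnth, Eln1mth, sparsity_active = sparsity)
    expect_equal(unname(got$W$gamma), oracle$gamma, tolerance = 1e-9)
    expect_equal(unname(got$W$mu), oracle$mu, tolerance = 1e-9)
    expect_equal(unname(got$W$s2), oracle$s2, tolerance = 1e-9)
    expect_equal(unname(got$W$Ew), oracle$Ew, tolerance = 1e-9)
    if (!sparsity) expect_true(all(got$W$gamma == 1))
  }
})

test_that("a fully masked feature falls back to its prior in the weight update", {
  fx <- fixture_tiny_state(seed = 9, N = 6, D = c(5, 4), K = 2)
  prep <- fx$prep
  sv <- fx$state$views[[1]]
  sv$pseudo$rho[, 2] <- 0  # feature 2 unobserved everywhere
  sv$pseudo$yt[, 2] <- 0
  # symmetric Beta posterior so E[theta] = 1/2 exactly
  sv$theta$a <- rep(1, 2)
  sv$theta$b <- rep(1, 2)
  got <- omifa:::update_weights_view(sv, fx$state$Z, TRUE)
  Ealpha <- sv$alpha$shape / sv$alpha$rate
  expect_equal(unname(got$W$gamma[2, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(got$W$mu[2, ]), c(0, 0))
  expect_equal(unname(got$W$s2[2, ]), unname(1 / Ealpha), tolerance = 1e-12)
})

test_that("overwhelming evidence drives the inclusion probability to one", {
  withr::with_seed(40, {
    N <- 60
    z <- rnorm(N)
    y <- matrix(5 * z + rnorm(N, sd = 0.1), N, 1,
                dimnames = list(paste0("s", 1:N), "f1"))
    views <- omic_views(list(v = y))
    prep <- omifa:::prep_data(views)
    ctl <- mofa_control()
    state <- omifa:::init_state(prep, 1, ctl, 1)
    state$Z$M[, 1] <- z
    state$Z$Svec[, 1] <- 0
    state$Z$Sdiag[, 1] <- 0
    state$Z$E2 <- state$Z$M^2
    state$views[[1]]$pseudo$rho[] <- 100  # precise noise
    got <- omifa:::update_weights_view(state$views[[1]], state$Z, TRUE)
    expect_gt(got$W$gamma[1, 1], 0.99)
  })
})

test_that("ARD update matches conjugate arithmetic and shrinks dead factors", {
  fx <- fixture_tiny_state(seed = 11, N = 6, D = c(5, 4), K = 2)
  ctl <- fx$control
  sv <- fx$state$views[[1]]
  got <- omifa:::update_ard_view(sv, ctl)
  D <- nrow(sv$W$Ew)
  Ealpha_old <- sv$alpha$shape / sv$alpha$rate
  for (k in 1:2) {
    rate <- ctl$prior_alpha[2]
    for (d in seq_len(D)) {
      g <- sv$W$gamma[d, k]
      rate <- rate + 0.5 * (g * (sv$W$mu[d, k]^2 + sv$W$s2[d, k]) +
                              (1 - g) / Ealpha_old[k])
    }
    expect_equal(got$alpha$shape[k], ctl$prior_alpha[1] + D / 2)
    expect_equal(got$alpha$rate[k], rate, tolerance = 1e-12)
  }
  # near-zero slab weights drive E[alpha] far above 1
  sv0 <- sv
  sv0$W$gamma[] <- 1
  sv0$W$mu[] <- 1e-6
  sv0$W$s2[] <- 1e-8
  got0 <- omifa:::update_ard_view(sv0, ctl)
  expect_true(all(got0$alpha$shape / got0$alpha$rate > 100))
  # no features: posterior equals the prior
  svE <- sv
  svE$W <- lapply(svE$W, function(x) x[integer(0), , drop = FALSE])
  gotE <- omifa:::update_ard_view(svE, ctl)
  expect_equal(gotE$alpha$shape / gotE$alpha$rate,
               rep(ctl$prior_alpha[1] / ctl$prior_alpha[2], 2))
})

test_that("sparsity update is the conjugate Beta count update", {
  fx <- fixture_tiny_state(seed = 13, N = 6, D = c(5, 4), K = 2)
  sv <- fx$state$views[[1]]
  D <- nrow(sv$W$gamma)
  got <- omifa:::update_sparsity_view(sv, fx$control)
  for (k in 1:2) {
    expect_equal(got$theta$a[k], fx$control$prior_theta[1] + sum(sv$W$gamma[, k]),
                 tolerance = 1e-12)
    expect_equal(got$theta$b[k],
                 fx$control$prior_theta[2] + D - sum(sv$W$gamma[, k]),
                 tolerance = 1e-12)
  }
  # all gamma = 1: E[theta] -> (1 + D) / (2 + D)
  sv1 <- sv; sv1$W$gamma[] <- 1
  got1 <- omifa:::update_sparsity_view(sv1, fx$control)
  expect_equal(unname(got1$theta$a / (got1$theta$a + got1$theta$b)),
               rep((1 + D) / (2 + D), 2), tolerance = 1e-12)
  # all gamma = 0.5 with the uniform prior: E[theta] = 1/2
  sv5 <- sv; sv5$W$gamma[] <- 0.5
  got5 <- omifa:::update_sparsity_view(sv5, fx$control)
  expect_equal(unname(got5$theta$a / (got5$theta$a + got5$theta$b)),
               c(0.5, 0.5), tolerance = 1e-12)
})

test_that("noise update recovers a known residual precision", {
  withr::with_seed(50, {
    N <- 400; D <- 6; K <- 1
    z <- rnorm(N)
    w <- rnorm(D)
    y <- z %*% t(w) + matrix(rnorm(N * D), N, D)   # residual variance 1
    dimnames(y) <- list(paste0("s", 1:N), paste0("f", 1:D))
    views <- omic_views(list(v = y))
    prep <- omifa:::prep_data(views)
    ctl <- mofa_control()
    state <- omifa:::init_state(prep, 1, ctl, 1)
    state$Z$M[, 1] <- z
    state$Z$Svec[, 1] <- 0; state$Z$Sdiag[, 1] <- 0; state$Z$E2 <- state$Z$M^2
    state$views[[1]]$W <- list(gamma = matrix(1, D, 1), mu = matrix(w, D, 1),
                               s2 = matrix(0, D, 1), Ew = matrix(w, D, 1),
                               Ew2 = matrix(w^2, D, 1))
    # centring was applied to the data, not to z w: recentre targets on truth
    state$views[[1]]$pseudo$yt <- (y - matrix(prep$views[[1]]$mu, N, D,
                                              byrow = TRUE)) * prep$views[[1]]$maskn
    wc <- colMeans(z %*% t(w))
    got <- omifa:::update_noise_view(state$views[[1]], prep$views[[1]],
                                     state$Z, ctl)
    Etau <- got$tau$shape / got$tau$rate
    expect_true(all(abs(Etau - 1) < 0.25))
    expect_lt(abs(mean(Etau) - 1), 0.05)
  })
})

test_that("noise update ignores masked entries entirely", {
  fx <- fixture_tiny_state(seed = 17, N = 6, D = c(5, 4), K = 2,
                           missing = 0.3)
  prep2 <- fx$prep
  prep2$views[[1]]$y0 <- prep2$views[[1]]$y0 +
    (1 - prep2$views[[1]]$maskn) * 99  # junk where masked
  a <- omifa:::update_noise_view(fx$state$views[[1]], fx$prep$views[[1]],
                                 fx$state$Z, fx$control)
  b <- omifa:::update_noise_view(fx$state$views[[1]], prep2$views[[1]],
                                 fx$state$Z, fx$control)
  expect_identical(a$tau, b$tau)
})

test_that("ELBO equals the term-by-term naive oracle on a small gaussian instance", {
  fx <- fixture_tiny_state(seed = 19, N = 6, D = c(5, 4), K = 2)
  elbo <- omifa:::compute_elbo(fx$state, fx$prep, fx$control)
  oracle <- oracle_elbo_gaussian(fx$state, fx$prep, fx$control)
  expect_equal(as.numeric(elbo), oracle, tolerance = 1e-8)
})

test_that("with no observed data the ELBO is minus the total KL, which is non-negative", {
  m <- matrix(NA_real_, 4, 3, dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  views <- structure(list(
    sample_names = rownames(m),
    views = list(v = list(name = "v", data = matrix(0, 4, 3, dimnames = dimnames(m)),
                          mask = matrix(FALSE, 4, 3), likelihood = "gaussian",
                          feature_names = colnames(m)))
  ), class = "omic_views")
  prep <- omifa:::prep_data(views)
  ctl <- mofa_control()
  state <- omifa:::init_state(prep, 2, ctl, 1)
  state <- omifa:::update_factors(state, prep)  # prior fallback everywhere
  elbo <- omifa:::compute_elbo(state, prep, ctl)
  comps <- attr(elbo, "components")
  expect_equal(unname(comps["lik_v"]), 0)
  expect_lte(as.numeric(elbo), 0)
  expect_equal(as.numeric(elbo), -sum(comps[startsWith(names(comps), "kl_")]),
               tolerance = 1e-12)
})

test_that("a non-finite ELBO raises an error naming the offending term", {
  fx <- fixture_tiny_state(seed = 23, N = 6, D = c(5, 4), K = 2)
  st <- fx$state
  st$views[[1]]$tau$rate[1] <- -1  # poisoned noise posterior
  suppressWarnings(
    expect_error(omifa:::compute_elbo(st, fx$prep, fx$control),
                 "lik_view_1|kl_tau_view_1")
  )
})
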