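# Mean-field variational inference engine.
#
# Variational family: q(Z) is Gaussian, factorized across samples but with a
# full K x K covariance per sample; q(s_dk, what_dk) is a spike-and-slab pair
# with inclusion probability gamma_dk, a Gaussian slab N(mu_dk, s2_dk) given
# inclusion, and the slab at its prior N(0, 1/E[alpha_k]) given exclusion;
# q(alpha), q(theta), q(tau) are conjugate Gamma/Beta/Gamma. Bernoulli and
# Poisson views are reduced to Gaussian pseudo-observations by quadratic
# lower bounds on their log-likelihoods (Jaakkola-Jordan for the logistic
# model; a bounded-curvature bound for the Poisson model with softplus rate
# link). All coordinate updates are exact, so the ELBO is non-decreasing for
# Gaussian views and non-decreasing after each bound refresh otherwise.
#
# Throughout, data matrices are stored with zeros at unobserved positions and
# every sum over the data is mask-weighted, so values stored at masked cells
# can never leak into any result.

# ---- data preparation -------------------------------------------------------

# Freeze the per-view quantities the engine needs: zeroed data, numeric mask,
# observation counts, the fixed feature-wise intercept for gaussian views
# (observed mean; data are centred once here) and the constant curvature bound
# for poisson views.
prep_data <- function(views) {
  stopifnot(inherits(views, "omic_views"))
  N <- length(views$sample_names)
  pviews <- lapply(views$views, function(v) {
    maskn <- v$mask * 1
    y0 <- v$data * maskn
    nobs <- colSums(maskn)
    pv <- list(name = v$name, likelihood = v$likelihood, D = ncol(y0),
               y0 = y0, maskn = maskn, nobs = nobs,
               feature_names = v$feature_names)
    if (v$likelihood == "gaussian") {
      pv$mu <- masked_colmeans(y0, v$mask)
      pv$yc <- (y0 - matrix(pv$mu, N, ncol(y0), byrow = TRUE)) * maskn
    }
    if (v$likelihood == "poisson") {
      if (any(y0 > 1e6)) {
        abort_validation(
          "View '%s': poisson counts above 1e6 are outside the numerical range of the quadratic bound.",
          v$name)
      }
      pv$curv <- 0.25 + 0.17 * y0          # curvature bound per entry
      pv$lfact <- lgamma(y0 + 1) * maskn   # log y! at observed entries
    }
    pv
  })
  list(N = N, M = length(pviews), views = pviews,
       sample_names = views$sample_names)
}

# ---- state initialization ---------------------------------------------------

init_state <- function(prep, n_factors, control, seed) {
  stopifnot(n_factors >= 1)
  K <- as.integer(n_factors)
  N <- prep$N
  withr::with_seed(as.integer(seed), {
    M <- matrix(stats::rnorm(N * K), N, K)
    Z <- list(M = M,
              Svec = matrix(rep(as.vector(diag(K)), each = N), N, K * K),
              Sdiag = matrix(1, N, K),
              logdet = rep(0, N),
              E2 = M^2 + 1)
    views <- lapply(prep$views, function(pv) {
      D <- pv$D
      sv <- list(
        W = list(gamma = matrix(1, D, K), mu = matrix(0, D, K),
                 s2 = matrix(1, D, K), Ew = matrix(0, D, K),
                 Ew2 = matrix(1, D, K)),
        alpha = list(shape = rep(control$prior_alpha[1], K),
                     rate = rep(control$prior_alpha[2], K)),
        theta = list(a = rep(control$prior_theta[1], K),
                     b = rep(control$prior_theta[2], K)),
        tau = NULL, xi = NULL, intercept = NULL, pseudo = NULL
      )
      if (pv$likelihood == "gaussian") {
        sv$tau <- list(shape = rep(control$prior_tau[1], D),
                       rate = rep(control$prior_tau[2], D))
        sv$intercept <- pv$mu
        sv$pseudo <- list(yt = pv$yc,
                          rho = matrix(sv$tau$shape / sv$tau$rate,
                                       N, D, byrow = TRUE) * pv$maskn)
      } else {
        # xi (bernoulli) / zeta (poisson) start at the |linear predictor|,
        # which is zero under the zero-weight initialization
        sv$xi <- matrix(0, N, D)
        sv$intercept <- rep(0, D)
      }
      sv
    })
    state <- list(K = K, Z = Z, views = views)
    for (m in seq_along(prep$views)) {
      pv <- prep$views[[m]]
      if (pv$likelihood != "gaussian") {
        state$views[[m]] <- refresh_bound_view(state$views[[m]], pv, state$Z)
      }
    }
    state
  })
}

# ---- shared moment computations --------------------------------------------

# D x K^2 matrix whose row d is vec(E[w_d] E[w_d]' + diag(var w_d)), plus the
# variance matrix itself. Used to assemble per-sample factor precisions and
# per-entry second moments with single matrix products.
ew_outer_stack <- function(W) {
  K <- ncol(W$Ew)
  vw <- pmax(W$Ew2 - W$Ew^2, 0)
  W2 <- W$Ew[, rep(seq_len(K), times = K), drop = FALSE] *
        W$Ew[, rep(seq_len(K), each = K), drop = FALSE]
  diagcols <- (seq_len(K) - 1) * K + seq_len(K)
  W2[, diagcols] <- W2[, diagcols] + vw
  list(W2 = W2, vw = vw)
}

# First and second posterior moments of the linear predictor z_n . w_d
# (without intercept): E[x] and E[x^2], both N x D.
predictor_moments <- function(Z, W) {
  st <- ew_outer_stack(W)
  Xhat <- Z$M %*% t(W$Ew)
  Ex2 <- Xhat^2 + Z$Svec %*% t(st$W2) + (Z$M^2) %*% t(st$vw)
  list(Xhat = Xhat, Ex2 = Ex2)
}

# ---- coordinate updates -----------------------------------------------------

# Joint spike-and-slab update of all weights in one view, Gauss-Seidel over
# factors (each factor sees the freshest values of the others). During
# burn-in (sparsity_active = FALSE) the inclusion probability is clamped to 1
# and only the slab moments update.
update_weights_view <- function(sv, Z, sparsity_active) {
  K <- ncol(Z$M)
  W <- sv$W
  rho <- sv$pseudo$rho
  RY <- rho * sv$pseudo$yt
  Ealpha <- sv$alpha$shape / sv$alpha$rate
  ElnTheta <- digamma(sv$theta$a) - digamma(sv$theta$a + sv$theta$b)
  Eln1mTheta <- digamma(sv$theta$b) - digamma(sv$theta$a + sv$theta$b)
  for (k in seq_len(K)) {
    idx <- ((k - 1) * K + 1):(k * K)
    ZZk <- Z$M * Z$M[, k] + Z$Svec[, idx, drop = FALSE]  # col j = E[z_j z_k]
    G <- crossprod(rho, ZZk)                              # D x K
    s2 <- 1 / (Ealpha[k] + G[, k])
    term1 <- as.vector(crossprod(RY, Z$M[, k]))
    term2 <- rowSums(G * W$Ew) - G[, k] * W$Ew[, k]
    mu <- (term1 - term2) * s2
    if (sparsity_active) {
      lo <- ElnTheta[k] - Eln1mTheta[k] +
        0.5 * (log(Ealpha[k]) + log(s2)) + 0.5 * mu^2 / s2
      g <- stats::plogis(lo)
    } else {
      g <- rep(1, length(mu))
    }
    W$gamma[, k] <- g
    W$mu[, k] <- mu
    W$s2[, k] <- s2
    W$Ew[, k] <- g * mu
    W$Ew2[, k] <- g * (mu^2 + s2)
  }
  sv$W <- W
  sv
}

# Gaussian posterior over each sample's K factor values, combining the
# standard-normal prior with all observed (pseudo-)gaussian evidence. A sample
# with no observed data in any view falls back to the prior exactly.
update_factors <- function(state, prep) {
  K <- state$K
  N <- prep$N
  Pstack <- matrix(0, N, K * K)
  B <- matrix(0, N, K)
  for (m in seq_along(state$views)) {
    sv <- state$views[[m]]
    st <- ew_outer_stack(sv$W)
    Pstack <- Pstack + sv$pseudo$rho %*% st$W2
    B <- B + (sv$pseudo$rho * sv$pseudo$yt) %*% sv$W$Ew
  }
  M <- matrix(0, N, K)
  Svec <- matrix(0, N, K * K)
  Sdiag <- matrix(0, N, K)
  logdet <- numeric(N)
  IK <- diag(K)
  for (n in seq_len(N)) {
    P <- IK + matrix(Pstack[n, ], K, K)
    P <- (P + t(P)) / 2
    ch <- tryCatch(chol(P), error = function(e) {
      rlang::abort(sprintf("Factor precision not positive definite for sample %d.", n))
    })
    S <- chol2inv(ch)
    M[n, ] <- S %*% B[n, ]
    Svec[n, ] <- as.vector(S)
    Sdiag[n, ] <- diag(S)
    logdet[n] <- -2 * sum(log(diag(ch)))
  }
  rownames(M) <- prep$sample_names
  state$Z <- list(M = M, Svec = Svec, Sdiag = Sdiag, logdet = logdet,
                  E2 = M^2 + Sdiag)
  state
}

# Conjugate Gamma update of the ARD precision per factor, from expected
# squared slab weights (slab at prior for the excluded component).
update_ard_view <- function(sv, control) {
  D <- nrow(sv$W$Ew)
  Ealpha_old <- sv$alpha$shape / sv$alpha$rate
  prior_var <- matrix(1 / Ealpha_old, max(D, 1), length(Ealpha_old),
                      byrow = TRUE)[seq_len(D), , drop = FALSE]
  Ewhat2 <- sv$W$gamma * (sv$W$mu^2 + sv$W$s2) +
    (1 - sv$W$gamma) * prior_var
  sv$alpha$shape <- rep(control$prior_alpha[1] + D / 2, length(Ealpha_old))
  sv$alpha$rate <- control$prior_alpha[2] + 0.5 * colSums(Ewhat2)
  sv
}

# Conjugate Beta update of the sparsity level per factor.
update_sparsity_view <- function(sv, control) {
  D <- nrow(sv$W$gamma)
  g <- colSums(sv$W$gamma)
  sv$theta$a <- control$prior_theta[1] + g
  sv$theta$b <- control$prior_theta[2] + D - g
  sv
}

# Conjugate Gamma update of the per-feature noise precision of a gaussian
# view, from expected squared residuals at observed entries only. Returns the
# view state with refreshed pseudo precisions.
update_noise_view <- function(sv, pv, Z, control) {
  pm <- predictor_moments(Z, sv$W)
  resid2 <- colSums(pv$maskn * (sv$pseudo$yt^2 - 2 * sv$pseudo$yt * pm$Xhat + pm$Ex2))
  sv$tau$shape <- control$prior_tau[1] + pv$nobs / 2
  sv$tau$rate <- control$prior_tau[2] + 0.5 * pmax(resid2, 0)
  Etau <- sv$tau$shape / sv$tau$rate
  sv$pseudo$rho <- matrix(Etau, nrow(pv$maskn), pv$D, byrow = TRUE) * pv$maskn
  sv
}

# ---- variational bounds for non-gaussian views ------------------------------

# Refresh the bound parameters of a non-gaussian view at their optimal values
# (xi^2 = E[x^2] for bernoulli; zeta = E[x] for poisson), then rebuild the
# equivalent gaussian pseudo-observations and site precisions, and update the
# feature offset at its exact maximizer (the precision-weighted mean of the
# pseudo-data residuals), so every step of the refresh is coordinate ascent
# on the bounded ELBO.
refresh_bound_view <- function(sv, pv, Z, update_intercept = TRUE) {
  N <- nrow(pv$y0)
  mu_row <- matrix(sv$intercept, N, pv$D, byrow = TRUE)
  pm <- predictor_moments(Z, sv$W)
  Ex <- pm$Xhat + mu_row
  Ex2 <- pm$Ex2 + 2 * pm$Xhat * mu_row + mu_row^2
  if (pv$likelihood == "bernoulli") {
    xi <- sqrt(pmax(Ex2, 0))
    lj <- jj_lambda(xi)
    ytil <- (pv$y0 - 0.5) / (2 * lj)
    rho_raw <- 2 * lj
  } else { # poisson
    zeta <- Ex
    lam <- pmax(link_lambda(zeta), 1e-300)
    fp <- link_sigma(zeta) * (1 - pv$y0 / lam)
    ytil <- zeta - fp / pv$curv
    rho_raw <- pv$curv
    xi <- zeta
  }
  sv$xi <- xi
  if (update_intercept) {
    w <- rho_raw * pv$maskn
    sw <- colSums(w)
    sv$intercept <- ifelse(sw > 0, colSums(w * (ytil - pm$Xhat)) / pmax(sw, 1e-300), 0)
  }
  mu_new <- matrix(sv$intercept, N, pv$D, byrow = TRUE)
  sv$pseudo <- list(yt = (ytil - mu_new) * pv$maskn, rho = rho_raw * pv$maskn)
  sv
}

# Expected value of the quadratic lower bound on a non-gaussian view's
# log-likelihood, at the current bound parameters and posterior moments.
bound_value_view <- function(sv, pv, Z) {
  N <- nrow(pv$y0)
  mu_row <- matrix(sv$intercept, N, pv$D, byrow = TRUE)
  pm <- predictor_moments(Z, sv$W)
  Ex <- pm$Xhat + mu_row
  Ex2 <- pm$Ex2 + 2 * pm$Xhat * mu_row + mu_row^2
  if (pv$likelihood == "bernoulli") {
    xi <- sv$xi
    lj <- jj_lambda(xi)
    term <- stats::plogis(xi, log.p = TRUE) +
      ((2 * pv$y0 - 1) * Ex - xi) / 2 - lj * (Ex2 - xi^2)
  } else {
    zeta <- sv$xi
    lam <- pmax(link_lambda(zeta), 1e-300)
    f <- lam - pv$y0 * log(lam)
    fp <- link_sigma(zeta) * (1 - pv$y0 / lam)
    term <- -(f + fp * (Ex - zeta) +
                0.5 * pv$curv * (Ex2 - 2 * zeta * Ex + zeta^2)) - pv$lfact
  }
  sum(term * pv$maskn)
}

# ---- ELBO -------------------------------------------------------------------

kl_gamma <- function(shape, rate, shape0, rate0) {
  (shape - shape0) * digamma(shape) - lgamma(shape) + lgamma(shape0) +
    shape0 * (log(rate) - log(rate0)) + shape * (rate0 - rate) / rate
}

kl_beta <- function(a, b, a0, b0) {
  lbeta(a0, b0) - lbeta(a, b) +
    (a - a0) * digamma(a) + (b - b0) * digamma(b) +
    (a0 - a + b0 - b) * digamma(a + b)
}

# Full evidence lower bound for the current state: expected (bounded)
# log-likelihood per view minus KL divergences of every variational factor to
# its prior. Raises if any component is non-finite, naming the term.
compute_elbo <- function(state, prep, control) {
  comps <- c()
  Z <- state$Z
  N <- prep$N
  K <- state$K
  for (m in seq_along(prep$views)) {
    pv <- prep$views[[m]]
    sv <- state$views[[m]]
    if (pv$likelihood == "gaussian") {
      pm <- predictor_moments(Z, sv$W)
      resid2 <- colSums(pv$maskn * (sv$pseudo$yt^2 - 2 * sv$pseudo$yt * pm$Xhat + pm$Ex2))
      Etau <- sv$tau$shape / sv$tau$rate
      Elntau <- digamma(sv$tau$shape) - log(sv$tau$rate)
      lik <- 0.5 * sum(pv$nobs * (Elntau - log(2 * pi))) - 0.5 * sum(Etau * resid2)
      kl_tau <- sum(kl_gamma(sv$tau$shape, sv$tau$rate,
                             control$prior_tau[1], control$prior_tau[2]))
    } else {
      lik <- bound_value_view(sv, pv, Z)
      kl_tau <- 0
    }
    Ealpha <- sv$alpha$shape / sv$alpha$rate
    Elnalpha <- digamma(sv$alpha$shape) - log(sv$alpha$rate)
    ElnTheta <- digamma(sv$theta$a) - digamma(sv$theta$a + sv$theta$b)
    Eln1mTheta <- digamma(sv$theta$b) - digamma(sv$theta$a + sv$theta$b)
    g <- sv$W$gamma
    D <- pv$D
    Ea_row <- matrix(Ealpha, D, K, byrow = TRUE)
    Ewhat2 <- g * (sv$W$mu^2 + sv$W$s2) + (1 - g) / Ea_row
    Elnp_w <- sum(matrix(0.5 * Elnalpha, D, K, byrow = TRUE) -
                    0.5 * log(2 * pi) - 0.5 * Ea_row * Ewhat2)
    Elnp_s <- sum(g * matrix(ElnTheta, D, K, byrow = TRUE) +
                    (1 - g) * matrix(Eln1mTheta, D, K, byrow = TRUE))
    Elnq_sw <- sum(xlogx(g) + xlogx(1 - g) -
                     0.5 * g * (log(2 * pi * exp(1)) + log(sv$W$s2)) -
                     0.5 * (1 - g) * (log(2 * pi * exp(1)) - log(Ea_row)))
    kl_sw <- Elnq_sw - Elnp_w - Elnp_s
    kl_alpha <- sum(kl_gamma(sv$alpha$shape, sv$alpha$rate,
                             control$prior_alpha[1], control$prior_alpha[2]))
    kl_theta <- sum(kl_beta(sv$theta$a, sv$theta$b,
                            control$prior_theta[1], control$prior_theta[2]))
    comps[paste0("lik_", pv$name)] <- lik
    comps[paste0("kl_sw_", pv$name)] <- kl_sw
    comps[paste0("kl_alpha_", pv$name)] <- kl_alpha
    comps[paste0("kl_theta_", pv$name)] <- kl_theta
    comps[paste0("kl_tau_", pv$name)] <- kl_tau
  }
  comps["kl_z"] <- 0.5 * (sum(Z$Sdiag) + sum(Z$M^2)) - 0.5 * N * K -
    0.5 * sum(Z$logdet)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad) > 0) {
    rlang::abort(sprintf("Non-finite ELBO component(s): %s", paste(bad, collapse = ", ")))
  }
  elbo <- sum(comps[startsWith(names(comps), "lik_")]) -
    sum(comps[startsWith(names(comps), "kl_")])
  attr(elbo, "components") <- comps
  elbo
}

# ---- variance explained (engine scale) --------------------------------------

# Fraction of variance explained per factor (rows = views, cols = factors) and
# per view with all factors jointly, computed from posterior expectations over
# observed entries, on the centred data scale for gaussian views and the
# centred pseudo-data scale for non-gaussian views.
r2_engine <- function(state, prep) {
  K <- state$K
  M_views <- length(prep$views)
  per_factor <- matrix(NA_real_, M_views, K)
  per_view <- rep(NA_real_, M_views)
  Mz <- state$Z$M
  for (m in seq_len(M_views)) {
    pv <- prep$views[[m]]
    sv <- state$views[[m]]
    yt <- sv$pseudo$yt
    Ew <- sv$W$Ew
    ss_tot <- sum(yt^2)
    if (ss_tot <= 0) next  # constant view: undefined, left NA
    for (k in seq_len(K)) {
      cross <- as.numeric(t(Mz[, k]) %*% yt %*% Ew[, k])
      ss_pred <- as.numeric(t(Mz[, k]^2) %*% pv$maskn %*% (Ew[, k]^2))
      per_factor[m, k] <- 1 - (ss_tot - 2 * cross + ss_pred) / ss_tot
    }
    pred <- Mz %*% t(Ew)
    per_view[m] <- 1 - sum(pv$maskn * (yt - pred)^2) / ss_tot
  }
  rownames(per_factor) <- names(per_view) <- vapply(prep$views, `[[`, "", "name")
  list(per_factor = per_factor, per_view = per_view)
}

# ---- pruning ----------------------------------------------------------------

# Drop every factor whose variance explained is below `threshold` in all
# views; shrink all per-factor state consistently. Returns the new state and
# the indices (in the pre-pruning numbering) of dropped factors.
prune_factors <- function(state, prep, threshold) {
  if (threshold <= 0 || state$K == 0) {
    return(list(state = state, pruned = integer(0)))
  }
  r2 <- r2_engine(state, prep)$per_factor
  best <- apply(r2, 2, function(col) {
    if (all(is.na(col))) -Inf else max(col, na.rm = TRUE)
  })
  drop <- which(best < threshold)
  if (length(drop) == 0) return(list(state = state, pruned = integer(0)))
  keep <- setdiff(seq_len(state$K), drop)
  state <- subset_factors(state, keep)
  if (state$K == 0) {
    rlang::warn("All factors pruned: no factor explains variance above the threshold.")
  }
  list(state = state, pruned = drop)
}

subset_factors <- function(state, keep) {
  K_old <- state$K
  K <- length(keep)
  Z <- state$Z
  N <- nrow(Z$M)
  Svec <- matrix(0, N, K * K)
  logdet <- numeric(N)
  for (n in seq_len(N)) {
    S <- matrix(Z$Svec[n, ], K_old, K_old)[keep, keep, drop = FALSE]
    Svec[n, ] <- as.vector(S)
    # principal submatrix of a PD matrix is PD; determinant() also covers
    # degenerate point-mass states used in diagnostics
    logdet[n] <- if (K > 0) {
      as.numeric(determinant(S, logarithm = TRUE)$modulus)
    } else 0
  }
  state$Z <- list(M = Z$M[, keep, drop = FALSE], Svec = Svec,
                  Sdiag = Z$Sdiag[, keep, drop = FALSE], logdet = logdet,
                  E2 = Z$E2[, keep, drop = FALSE])
  state$views <- lapply(state$views, function(sv) {
    sv$W <- lapply(sv$W, function(x) x[, keep, drop = FALSE])
    sv$alpha <- lapply(sv$alpha, function(x) x[keep])
    sv$theta <- lapply(sv$theta, function(x) x[keep])
    sv
  })
  state$K <- K
  state
}
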