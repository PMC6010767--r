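# Independent naive-loop oracles. These deliberately share no code with the
# package internals: every sum is an explicit loop over samples, features and
# factors, computed from first principles.

# Exact Bernoulli log-likelihood at linear predictor x (logit scale).
oracle_bernoulli_loglik <- function(y, x) {
  p <- 1 / (1 + exp(-x))
  ifelse(y == 1, log(p), log1p(-p))
}

# Exact Poisson log-likelihood with softplus rate link.
oracle_poisson_loglik <- function(y, x) {
  stats::dpois(y, log(1 + exp(x)), log = TRUE)
}

# Jaakkola-Jordan bound on the Bernoulli log-likelihood, scalar form.
oracle_jj_bound <- function(y, x, xi) {
  lam <- ifelse(abs(xi) < 1e-8, 1 / 8, tanh(abs(xi) / 2) / (4 * abs(xi)))
  log(1 / (1 + exp(-abs(xi)))) + ((2 * y - 1) * x - abs(xi)) / 2 -
    lam * (x^2 - xi^2)
}

# Bounded-curvature quadratic bound on the Poisson log-likelihood.
oracle_poisson_bound <- function(y, x, zeta) {
  lam <- function(t) log(1 + exp(t))
  f <- lam(zeta) - y * log(lam(zeta))
  fp <- (1 / (1 + exp(-zeta))) * (1 - y / lam(zeta))
  c_y <- 0.25 + 0.17 * y
  -(f + fp * (x - zeta) + 0.5 * c_y * (x - zeta)^2) - lgamma(y + 1)
}

# Brute-force factor update for a state with per-view pseudo data. Inputs are
# plain lists: pseudo[[m]]$yt / $rho (N x D), W[[m]]$Ew / $Ew2 (D x K).
oracle_factor_update <- function(pseudo, W, K) {
  N <- nrow(pseudo[[1]]$yt)
  M_out <- matrix(0, N, K)
  S_out <- array(0, c(K, K, N))
  for (n in seq_len(N)) {
    P <- diag(K)
    b <- numeric(K)
    for (m in seq_along(pseudo)) {
      Ew <- W[[m]]$Ew
      vw <- W[[m]]$Ew2 - W[[m]]$Ew^2
      for (d in seq_len(ncol(pseudo[[m]]$yt))) {
        r <- pseudo[[m]]$rho[n, d]
        if (r == 0) next
        for (j in seq_len(K)) {
          for (k in seq_len(K)) {
            Eww <- if (j == k) Ew[d, j]^2 + vw[d, j] else Ew[d, j] * Ew[d, k]
            P[j, k] <- P[j, k] + r * Eww
          }
          b[j] <- b[j] + r * Ew[d, j] * pseudo[[m]]$yt[n, d]
        }
      }
    }
    S <- solve(P)
    M_out[n, ] <- S %*% b
    S_out[, , n] <- S
  }
  list(M = M_out, S = S_out)
}

# Brute-force spike-and-slab weight update for one view, sequential over
# factors (matching the stated Gauss-Seidel update order), from the
# variational update equations derived by hand.
oracle_weight_update <- function(yt, rho, Zm, Zsvec, Ew_start, Ealpha,
                                 Elntheta, Eln1mtheta, sparsity_active = TRUE) {
  N <- nrow(yt); D <- ncol(yt); K <- ncol(Zm)
  Ew <- Ew_start
  out <- list(gamma = matrix(NA_real_, D, K), mu = matrix(NA_real_, D, K),
              s2 = matrix(NA_real_, D, K))
  Ezz <- function(n, j, k) {
    S <- matrix(Zsvec[n, ], K, K)
    S[j, k] + Zm[n, j] * Zm[n, k]
  }
  for (k in seq_len(K)) {
    for (d in seq_len(D)) {
      prec <- Ealpha[k]
      b <- 0
      for (n in seq_len(N)) {
        r <- rho[n, d]
        if (r == 0) next
        prec <- prec + r * Ezz(n, k, k)
        contrib <- Zm[n, k] * yt[n, d]
        for (j in seq_len(K)) {
          if (j != k) contrib <- contrib - Ezz(n, j, k) * Ew[d, j]
        }
        b <- b + r * contrib
      }
      s2 <- 1 / prec
      mu <- b * s2
      if (sparsity_active) {
        lo <- Elntheta[k] - Eln1mtheta[k] + 0.5 * log(Ealpha[k] * s2) +
          0.5 * mu^2 / s2
        g <- 1 / (1 + exp(-lo))
      } else {
        g <- 1
      }
      out$gamma[d, k] <- g
      out$mu[d, k] <- mu
      out$s2[d, k] <- s2
      Ew[d, k] <- g * mu
    }
  }
  out$Ew <- Ew
  out
}

# Naive double-loop R-squared per factor and view on target matrices.
oracle_r2 <- function(yt, maskn, Zm, Ew) {
  K <- ncol(Zm)
  ss_tot <- 0
  for (n in seq_len(nrow(yt))) {
    for (d in seq_len(ncol(yt))) {
      if (maskn[n, d] > 0) ss_tot <- ss_tot + yt[n, d]^2
    }
  }
  vapply(seq_len(K), function(k) {
    ss_res <- 0
    for (n in seq_len(nrow(yt))) {
      for (d in seq_len(ncol(yt))) {
        if (maskn[n, d] > 0) {
          ss_res <- ss_res + (yt[n, d] - Zm[n, k] * Ew[d, k])^2
        }
      }
    }
    1 - ss_res / ss_tot
  }, 0)
}

# Benjamini-Hochberg adjustment, naive sort-based construction.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Pooled two-sample t statistic, textbook formula.
oracle_t2 <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Term-by-term ELBO for a gaussian-only model, every sum an explicit loop.
oracle_elbo_gaussian <- function(state, prep, control) {
  N <- prep$N; K <- state$K
  total <- 0
  # data terms
  for (m in seq_along(prep$views)) {
    pv <- prep$views[[m]]
    sv <- state$views[[m]]
    Etau <- sv$tau$shape / sv$tau$rate
    Elntau <- digamma(sv$tau$shape) - log(sv$tau$rate)
    for (d in seq_len(pv$D)) {
      for (n in seq_len(N)) {
        if (pv$maskn[n, d] == 0) next
        S <- matrix(state$Z$Svec[n, ], K, K)
        Ex <- 0; Ex2 <- 0
        for (k in seq_len(K)) Ex <- Ex + state$Z$M[n, k] * sv$W$Ew[d, k]
        for (j in seq_len(K)) {
          for (k in seq_len(K)) {
            Ezz <- S[j, k] + state$Z$M[n, j] * state$Z$M[n, k]
            Eww <- if (j == k) sv$W$gamma[d, j] * (sv$W$mu[d, j]^2 + sv$W$s2[d, j])
                   else sv$W$Ew[d, j] * sv$W$Ew[d, k]
            Ex2 <- Ex2 + Ezz * Eww
          }
        }
        y <- sv$pseudo$yt[n, d]
        total <- total + 0.5 * (Elntau[d] - log(2 * pi)) -
          0.5 * Etau[d] * (y^2 - 2 * y * Ex + Ex2)
      }
    }
  }
  # KL(q(Z) || N(0, I)) per sample
  for (n in seq_len(N)) {
    S <- matrix(state$Z$Svec[n, ], K, K)
    total <- total - 0.5 * (sum(diag(S)) + sum(state$Z$M[n, ]^2) - K -
                              determinant(S, logarithm = TRUE)$modulus)
  }
  kl_gamma_o <- function(a, b, a0, b0) {
    (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
      a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  }
  kl_beta_o <- function(a, b, a0, b0) {
    lbeta(a0, b0) - lbeta(a, b) + (a - a0) * digamma(a) +
      (b - b0) * digamma(b) + (a0 - a + b0 - b) * digamma(a + b)
  }
  for (m in seq_along(prep$views)) {
    pv <- prep$views[[m]]
    sv <- state$views[[m]]
    Ealpha <- sv$alpha$shape / sv$alpha$rate
    Elnalpha <- digamma(sv$alpha$shape) - log(sv$alpha$rate)
    Elnth <- digamma(sv$theta$a) - digamma(sv$theta$a + sv$theta$b)
    Eln1mth <- digamma(sv$theta$b) - digamma(sv$theta$a + sv$theta$b)
    for (d in seq_len(pv$D)) {
      for (k in seq_len(state$K)) {
        g <- sv$W$gamma[d, k]
        mu <- sv$W$mu[d, k]; s2 <- sv$W$s2[d, k]
        Ewhat2 <- g * (mu^2 + s2) + (1 - g) / Ealpha[k]
        elnp <- 0.5 * Elnalpha[k] - 0.5 * log(2 * pi) - 0.5 * Ealpha[k] * Ewhat2 +
          g * Elnth[k] + (1 - g) * Eln1mth[k]
        hs <- -(ifelse(g > 0, g * log(g), 0) + ifelse(g < 1, (1 - g) * log(1 - g), 0))
        hw <- g * 0.5 * log(2 * pi * exp(1) * s2) +
          (1 - g) * 0.5 * log(2 * pi * exp(1) / Ealpha[k])
        total <- total + elnp + hs + hw
      }
    }
    for (k in seq_len(state$K)) {
      total <- total - kl_gamma_o(sv$alpha$shape[k], sv$alpha$rate[k],
                                  control$prior_alpha[1], control$prior_alpha[2])
      total <- total - kl_beta_o(sv$theta$a[k], sv$theta$b[k],
                                 control$prior_theta[1], control$prior_theta[2])
    }
    for (d in seq_len(pv$D)) {
      total <- total - kl_gamma_o(sv$tau$shape[d], sv$tau$rate[d],
                                  control$prior_tau[1], control$prior_tau[2])
    }
  }
  as.numeric(total)
}
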