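# Variance decomposition, loadings, enrichment.

test_that("variance decomposition matches the naive double-loop oracle", {
  fit <- fixture_small_fit()
  sim <- fixture_small_sim()
  ve <- variance_explained(fit)
  for (vn in names(fit$weights)) {
    v <- sim$data$views[[vn]]
    maskn <- v$mask * 1
    mu <- fit$intercepts[[vn]]
    yt <- (v$data * maskn - matrix(mu, nrow(maskn), ncol(maskn), byrow = TRUE)) * maskn
    oracle <- oracle_r2(yt, maskn, fit$factors, fit$weights[[vn]])
    expect_equal(ve$r2[ve$view == vn], oracle, tolerance = 1e-10)
  }
})

test_that("perfect one-factor reconstruction gives R2 of one, zero weights give zero", {
  withr::with_seed(55, {
    N <- 20; D <- 10
    z <- rnorm(N)
    z <- z - mean(z)               # centred factor: intercepts are exactly 0
    w <- rnorm(D)
    y <- z %*% t(w)                # noiseless rank-1 view
    dimnames(y) <- list(paste0("s", 1:N), paste0("f", 1:D))
    fit <- fake_fit_weights(matrix(w, D, 1, dimnames = list(colnames(y), "factor_1")))
    fit$factors <- matrix(z, N, 1, dimnames = list(rownames(y), "factor_1"))
    fit$intercepts <- list(view_1 = stats::setNames(rep(0, D), colnames(y)))
    fit$data <- omic_views(list(view_1 = y))
    ve <- variance_explained(fit)
    expect_equal(ve$r2, 1, tolerance = 1e-10)
    fit$weights$view_1[] <- 0
    expect_equal(variance_explained(fit)$r2, 0, tolerance = 1e-12)
  })
})

test_that("per-factor R2 approximately sums to the joint R2 on near-orthogonal fits", {
  sim <- sim_multiomics(80, c(120, 100), 4, seed = 77)
  fit <- fit_mofa(sim$data, n_factors = 6, n_restarts = 1, seed = 3,
                  control = mofa_control(max_iter = 150))
  per_f <- variance_explained(fit)
  per_v <- variance_explained(fit, by = "view")
  sums <- dplyr::summarise(dplyr::group_by(per_f, view), s = sum(r2))
  merged <- dplyr::inner_join(sums, per_v, by = "view")
  expect_true(all(abs(merged$s - merged$r2) < 0.05))
})

test_that("a constant view yields undefined R2 with a warning", {
  y <- matrix(3, 5, 4, dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  fit <- fake_fit_weights(matrix(0, 4, 1, dimnames = list(colnames(y), "factor_1")))
  fit$factors <- matrix(0, 5, 1, dimnames = list(rownames(y), "factor_1"))
  fit$intercepts <- list(view_1 = stats::setNames(rep(3, 4), colnames(y)))
  fit$data <- omic_views(list(view_1 = y))
  expect_warning(ve <- variance_explained(fit), "zero total variance")
  expect_true(all(is.na(ve$r2)))
})

test_that("loading scaling maps to [-1, 1], preserves order, and warns on zero vectors", {
  expect_equal(omifa:::scale_loadings(c(2, -4)), c(0.5, -1))
  expect_warning(out <- omifa:::scale_loadings(c(0, 0)), "All-zero")
  expect_equal(out, c(0, 0))
  withr::with_seed(3, {
    w <- rnorm(50)
    s <- omifa:::scale_loadings(w)
    expect_equal(order(-abs(s)), order(-abs(w)))
    expect_equal(max(abs(s)), 1)
    l2 <- omifa:::scale_loadings(w, method = "l2")
    expect_equal(sqrt(sum(l2^2)), 1)
  })
})

test_that("top_features ranks by absolute weight with deterministic tie-breaks", {
  W <- matrix(c(0.1, -0.9, 0.5, 0.5, 0.2, 0, 0, 0, 0, 0), 5, 2,
              dimnames = list(c("a", "b", "c", "d", "e"), c("factor_1", "factor_2")))
  fit <- fake_fit_weights(W)
  tf <- top_features(fit, "view_1", 1, n = 3)
  expect_equal(tf$feature, c("b", "c", "d"))  # |0.5| tie broken by name
  expect_equal(tf$sign, c("-", "+", "+"))
  expect_equal(tf$scaled_weight, c(-1, 0.5 / 0.9, 0.5 / 0.9), tolerance = 1e-12)
  # n beyond D returns everything, in the naive sort order
  all_tf <- top_features(fit, "view_1", 1, n = 100)
  expect_equal(nrow(all_tf), 5)
  naive <- rownames(W)[order(-abs(W[, 1]), rownames(W))]
  expect_equal(all_tf$feature, naive)
})

test_that("a planted dominant feature ranks first after a real fit", {
  sim <- sim_multiomics(50, c(40, 30), 2, seed = 13)
  boosted <- sim$data$views$view_1$data
  z1 <- sim$truth$Z[, 1]
  boosted[, 7] <- 10 * z1 + rnorm(50, sd = 0.1)
  sim$data$views$view_1$data <- boosted
  fit <- fit_mofa(sim$data, n_factors = 4, n_restarts = 1, seed = 2,
                  control = mofa_control(max_iter = 80))
  cc <- abs(cor(fit$factors, z1))
  k1 <- which.max(cc)
  tf <- top_features(fit, "view_1", k1, n = 1)
  expect_equal(tf$feature, colnames(boosted)[7])
})

test_that("enrichment t statistics match the textbook formula and BH matches a naive loop", {
  withr::with_seed(123, {
    D <- 200
    W <- matrix(rnorm(D), D, 1,
                dimnames = list(sprintf("g%03d", 1:D), "factor_1"))
    fit <- fake_fit_weights(W)
    sets <- lapply(1:25, function(i) sample(rownames(W), 15))
    names(sets) <- paste0("set", 1:25)
    res <- run_enrichment(fit, "view_1", sets, factors = 1)
    for (i in seq_len(nrow(res))) {
      fg <- W[rownames(W) %in% sets[[res$set[i]]], 1]
      bg <- W[!rownames(W) %in% sets[[res$set[i]]], 1]
      expect_equal(res$statistic[i], oracle_t2(fg, bg), tolerance = 1e-10)
    }
    expect_equal(res$p_adjust, oracle_bh(res$p_value), tolerance = 1e-12)
    expect_true(all(res$p_adjust >= res$p_value - 1e-15))
  })
})

test_that("BH agrees with the naive implementation on random p-vectors", {
  withr::with_seed(9, {
    for (i in 1:20) {
      p <- runif(sample(3:50, 1))
      expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("null enrichment p-values are uniform and a planted set is detected", {
  withr::with_seed(77, {
    D <- 500
    w <- rnorm(D)
    planted <- sample.int(D, 25)
    w[planted] <- w[planted] + 1.5
    W <- matrix(w, D, 1, dimnames = list(sprintf("g%03d", 1:D), "factor_1"))
    fit <- fake_fit_weights(W)
    # null sets avoid the planted features
    null_pool <- setdiff(rownames(W), rownames(W)[planted])
    sets <- lapply(1:200, function(i) sample(null_pool, 20))
    names(sets) <- paste0("null", 1:200)
    res <- run_enrichment(fit, "view_1", sets, factors = 1)
    ks <- stats::ks.test(res$p_value, "punif")
    expect_gt(ks$p.value, 0.01)
    # planted set: strongly significant at FDR 1%
    sets$planted <- rownames(W)[planted]
    res2 <- run_enrichment(fit, "view_1", sets, factors = 1)
    expect_true(res2$significant[res2$set == "planted"])
  })
})

test_that("under-sized sets are skipped with a reason, never silently dropped", {
  W <- matrix(rnorm(20), 20, 1, dimnames = list(letters[1:20], "factor_1"))
  fit <- fake_fit_weights(W)
  sets <- list(ok = letters[1:5], tiny = "a", alien = c("zz", "yy"))
  res <- run_enrichment(fit, "view_1", sets, factors = 1)
  expect_equal(nrow(res), 3)
  expect_true(is.na(res$p_value[res$set == "tiny"]))
  expect_match(res$note[res$set == "tiny"], "skipped")
  expect_equal(res$n_matched[res$set == "alien"], 0)
  expect_false(is.na(res$p_value[res$set == "ok"]))
})

test_that("tidiers return the documented tabular shapes", {
  fit <- fixture_small_fit()
  td <- tidy(fit)
  expect_equal(nrow(td), length(fit$sample_names) * fit$n_factors)
  expect_named(td, c("sample", "factor", "value"))
  tw <- tidy(fit, "weights")
  expect_equal(nrow(tw), (50 + 30) * fit$n_factors)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_factors, fit$n_factors)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_factors(fit, 1, min(2, fit$n_factors)), "ggplot")
  expect_s3_class(plot_weights(fit, "view_1", 1, n = 5), "ggplot")
  expect_s3_class(plot_elbo(fit), "ggplot")
})
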