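---
title: "Sparse Bayesian factor analysis for multi-omics data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Bayesian factor analysis for multi-omics data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omifa)
```

## The problem

Multi-omics studies measure several molecular layers — expression, methylation,
mutations, drug response, and so on — on the same set of samples. Each assay is
a samples-by-features matrix with its own scale, noise character and missing
pattern, and in cohort studies it is routine for a sizeable fraction of samples
to lack one or more whole assays. The analysis goal `omifa` addresses is
unsupervised: find a small number of latent **factors** — axes of sample-level
variation — that jointly explain these matrices, say *which* factor is active
in *which* assay, and expose the features that drive each factor.

## The model

Given $M$ views $\mathbf{Y}^1,\dots,\mathbf{Y}^M$ with shared samples
($N \times D_m$ each), the model is a group factor analysis:

$$\mathbf{Y}^m = \mathbf{Z}\,\mathbf{W}^{m\top} + \boldsymbol\epsilon^m,$$

with a single factor matrix $\mathbf{Z}$ ($N \times K$) common to all views and
view-specific loading matrices $\mathbf{W}^m$ ($D_m \times K$). Factors have a
standard normal prior. Sparsity of the loadings is imposed at two levels:

* **View-and-factor level (ARD).** Each loading column has precision
  $\alpha_{km}$ with an uninformative Gamma prior. When a factor carries no
  signal in a view, its posterior precision grows without bound and the whole
  column is shrunk to zero — this is what lets the model state that a factor is
  active in some views and silent in others, and what deactivates surplus
  factors.
* **Feature level (spike-and-slab).** Each loading is the product
  $w_{dk} = s_{dk}\hat w_{dk}$ of a Bernoulli indicator
  $s_{dk}\sim\mathrm{Ber}(\theta_{km})$ and a normal slab
  $\hat w_{dk}\sim N(0, 1/\alpha_{km})$, with a Beta prior on the sparsity
  level $\theta_{km}$. This concentrates each factor on a small set of
  features, which is what makes loadings interpretable.

Noise is view-specific. Continuous views use heteroscedastic Gaussian noise
$\epsilon_{nd}\sim N(0, 1/\tau_d)$ with Gamma priors on the precisions. Binary
views use a Bernoulli likelihood through the logistic link $\sigma(x)$; count
views use a Poisson likelihood through the softplus rate link
$\lambda(x)=\log(1+e^x)$.

## Inference

Inference is mean-field variational Bayes: coordinate ascent on the evidence
lower bound (ELBO). The variational family factorizes over samples, features
and parameters, with two deliberate strengthenings:

* $q(\mathbf{z}_n)$ keeps the full $K \times K$ covariance within a sample.
  The exact partition is a free modelling choice; the full within-sample
  covariance is the strongest tractable option at the factor counts used here
  ($K \lesssim 50$) and noticeably improves behaviour when factors correlate
  during early training.
* $q(s_{dk}, \hat w_{dk})$ is updated jointly (inclusion probability plus
  conditional slab moments), with the excluded branch at its prior given the
  current ARD expectation.

All updates are conjugate and exact, so for Gaussian-only data **every**
coordinate update provably does not decrease the ELBO; the test suite checks
this at relative tolerance $10^{-8}$ after every single update.

Bernoulli and Poisson views are handled by quadratic lower bounds on their
log-likelihoods, which turn each observation into a Gaussian pseudo-observation
with a site precision, so the Gaussian updates apply unchanged:

* logistic: the Jaakkola–Jordan bound, with curvature
  $\lambda(\xi)=\tanh(\xi/2)/(4\xi)$ and the analytic limit $1/8$ at
  $\xi = 0$; the per-entry bound parameter is set to its optimum
  $\xi^2 = E[x^2]$ each iteration;
* Poisson (softplus link): a fixed-curvature bound with per-entry constant
  $1/4 + 0.17\,y$, tangent at the expansion point $\zeta = E[x]$, refreshed
  each iteration.

Both bounds are valid everywhere (never above the exact log-likelihood) and
tight at their optimum; both properties are property-tested against direct
likelihood evaluation. With bounds in place the ELBO is non-decreasing after
each bound refresh, which is what the mixed-likelihood monotonicity test
asserts at the iteration level.

**Missing data.** Every sum over observations is mask-weighted. A missing
entry contributes no evidence anywhere; a sample missing an entire assay is an
all-false mask row, so its factor values are inferred from the views where it
was observed and fall back to the prior if it was observed nowhere. Data
stored behind the mask can never influence any result (tested by flipping
masked values and requiring bit-identical fits).

**Intercepts.** Gaussian views are centred per feature on their observed mean
once, before inference, and the mean is restored for imputation and variance
decomposition. Non-Gaussian views get an explicit per-feature offset on the
linear-predictor scale, updated at each bound refresh as the precision-weighted
mean of the pseudo-data residuals. That weighted form (rather than a plain
pseudo-data mean) is the exact maximizer of the bounded ELBO, which keeps the
refresh a true coordinate-ascent step; with a plain mean the monotonicity
guarantee above would not hold.

## Training procedure

`fit_mofa()` orchestrates:

1. **Initialization** (seeded): factor means from a standard normal, loadings
   at their prior, inclusion probabilities clamped to 1.
2. **Burn-in** (default 10 iterations): the spike-and-slab is deactivated —
   inclusion stays clamped at 1 and the sparsity levels are not updated — so
   factors establish themselves before sparsity can split or starve them.
3. **Updates** in a fixed order per iteration: weights (Gauss–Seidel over
   factors, so each factor sees the freshest others), factors, sparsity
   levels, ARD precisions, noise precisions, bound refreshes. The order is a
   free choice fixed for reproducibility.
4. **Pruning**: every `prune_every` (default 5) iterations after burn-in, any
   factor explaining less than `variance_threshold` (default 2%) of the
   variance in *every* view is removed. Setting `fix_n_factors = TRUE` keeps
   the factor count and ignores the criterion.
5. **Convergence** is declared when the relative ELBO change *between
   consecutive prune checks* falls below `tol` (default $10^{-5}$) with
   nothing left to prune. The windowed comparison matters: per-iteration
   changes can transiently dip near zero while the ARD prior is still slowly
   extinguishing a redundant factor, and stopping there would freeze a model
   with one factor too many.
6. **Restarts**: the optimization is non-convex, so `n_restarts` independent
   runs (default 10) are trained from seeds derived deterministically from the
   master seed, and the run with the highest final ELBO is returned; ties go
   to the lowest restart index.

Default prior hyperparameters are $\mathrm{Gamma}(10^{-5}, 10^{-5})$ for ARD
and noise precisions and $\mathrm{Beta}(1,1)$ for sparsity levels —
uninformative but proper, and numerically safe. They are exposed in
`mofa_control()`; the scaling-equivariance property test documents exactly how
the Gamma rates must co-scale if a view is rescaled.

## Downstream analyses

* **Variance decomposition** (`variance_explained()`): for factor $k$ and view
  $m$, $R^2_{m,k} = 1 - \sum_{nd}(y_{nd} - z_{nk}w_{kd} - \mu_d)^2 /
  \sum_{nd}(y_{nd}-\mu_d)^2$ over observed entries, with all variables at
  posterior expectations; `by = "view"` uses all factors jointly. For
  non-Gaussian views the decomposition is computed on the Gaussian pseudo-data
  scale of the final bound — the natural scale on which the model itself
  operates; R-squared on a probability or count scale is not well defined for
  these likelihoods, and this choice is stated here because the numbers are
  not comparable across scales.
* **Loadings** (`get_weights()`, `top_features()`): assays live on different
  scales, so per-factor loading vectors are scaled by their maximum absolute
  entry into $[-1, 1]$ for display ("scale by its absolute value" admits two
  readings; the max-abs reading keeps cross-view axes comparable, and an L2
  option is provided). Ranking uses raw absolute loadings with name-based tie
  breaks for determinism.
* **Enrichment** (`run_enrichment()`): per factor and feature set, a pooled
  two-sample t-test of in-set versus out-of-set loadings, BH-adjusted across
  sets within each factor, flagged at FDR 1% by default. The test is on raw
  signed loadings by default (a set enriched with both signs can be probed
  with `statistic = "absolute"`); sidedness is configurable, two-sided by
  default. Sets with fewer than two matched features are reported as skipped,
  never dropped silently.
* **Imputation** (`impute()`): missing entries are filled from the model
  equation $E[\mathbf{Z}]E[\mathbf{W}]^\top + \mu$, passed through
  $\sigma(\cdot)$ for Bernoulli views (probability scale) and
  $\lambda(\cdot)$ for Poisson views (rate scale).
  `impute_benchmark()` runs the masking experiment — random values or whole
  assays hidden, model refitted at fixed $K$, MSE against the held-out truth —
  with feature-mean and kNN baselines built in ($k = 5$, sample-space
  neighbours, Euclidean distance over shared observed entries across all
  views). Other imputers (e.g. a SoftImpute wrapper) can be hooked in via
  `extra_methods`.

## The simulator and what it does (and does not) emulate

`sim_multiomics()` draws data sets from the generative model itself:
$Z \sim N(0,1)$; per view, slab weights $N(0, 1/\alpha_{km})$ with
$\alpha_{km} \in \{1, 10^3\}$ encoding the view-activity pattern, spike
indicators at inclusion rate $\theta$ (default 0.5 — the fraction of non-zero
loadings per active factor, a value a feature-level sparse factor would
plausibly have and deliberately neither dense nor degenerate), Gaussian noise
at precision $\tau = 1$ (signal-to-noise of order one per feature); Bernoulli
and Poisson views sampled through their links; missingness at random values or
whole assay rows. `sim_scenario()` freezes the study designs used by the
validation suite: `model_comparison` (one view per likelihood, $N = 100$, 10
true factors, 5% missing), `activity_patterns` (Gaussian views, no missing
values, random activity with every factor active somewhere, 10 or 15 true
factors), `model_validation` and `imputation`. Each has a full variant
($D = 5000$ per view) and a `desk` variant ($D = 500$; 200 for imputation)
with the same design; the test suite and the acceptance script run the desk
variants, which this package treats as its standard evaluation sizes.

Because the simulator *is* the model, passing recovery tests shows the
inference machinery is correct and well calibrated — it does **not** show the
model fits real omics data, where effects are non-linear, noise is
non-Gaussian in un-modelled ways (zero inflation, batch structure), features
are correlated beyond the factor structure, and missingness is not at random.
Those claims require real-data validation outside the scope of the test suite.

## Numerical choices and degenerate inputs

* Log-odds for inclusion are formed with `plogis`; $\xi = 0$ uses the analytic
  curvature limit; softplus and logistic links are overflow-safe across the
  double range; Poisson counts above $10^6$ are rejected as outside the
  bound's useful numerical range.
* The per-sample factor precision $I + \sum \rho\, E[ww^\top]$ is symmetrized
  before Cholesky factorization; positive definiteness is guaranteed by the
  prior and asserted.
* A feature with no observed values falls back to its prior in every update; a
  constant view has undefined $R^2$ and is reported as `NA` with a warning;
  pruning to zero factors is allowed but flagged.
* All randomness (initialization, simulation, masking, restart seeds) derives
  from user-supplied seeds; fits are bit-reproducible.

## Known limitations

* The model is linear; strongly non-linear structure across features or views
  is summarized at best by multiple linear factors.
* Factors are identified only up to sign and, when activity patterns do not
  separate them, up to rotation; recovery tests therefore match factors by
  maximal absolute correlation before scoring.
* Bernoulli and Poisson views contribute through bounds, not exact
  likelihoods: their ELBO contributions are conservative and their variance
  decompositions live on the pseudo-data scale.
* One sample group only: no explicit batch or group structure, no covariates,
  no zero-inflated or binomial likelihoods.

## A worked example

```{r example, eval = FALSE}
sim <- sim_multiomics(n_samples = 60, n_features = c(120, 100), n_factors = 3,
                      seed = 1)
fit <- fit_mofa(sim$data, n_factors = 6, n_restarts = 2, seed = 1)
glance(fit)
variance_explained(fit)
top_features(fit, "view_1", factor = 1)
completed <- impute(fit)
autoplot(fit)
```
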