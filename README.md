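# lgnet — microbial interaction networks from irregular longitudinal abundance data

Cross-sectional network pipelines (SPIEC-EASI and relatives) estimate a
sparse precision matrix Ω = Σ⁻¹ from transformed abundances and read the
microbial interaction network off its nonzero pattern — but they assume
independent samples. Longitudinal cohorts break that assumption: samples
from the same subject are correlated, unequally spaced, and series
lengths differ wildly between subjects.

`lgnet` estimates sparse microbial interaction networks from exactly such
data, for microbiome researchers with per-subject time series of
(log-ratio transformed) abundances. It fits a stationary Gaussian
graphical model in which subject *i*'s stacked observations have
covariance Φᵢ ⊗ Σ with (Φᵢ)ⱼₖ = exp(−τᵢ|tᵢⱼ − tᵢₖ|): one network Ω
shared by everyone, temporal correlation decaying exponentially with time
distance at dampening rate τᵢ. The L1-penalized MLE

  min over Ω, τ of −2 ℓₙ(Ω, τ | y) + nλ‖Ω‖₁

is computed by alternating a graphical-lasso step on the weighted
second-moment matrix S̄(τ) with updates of the dampening parameters:

* `model = "homogeneous"` — one shared τ, 1-D likelihood maximization;
* `model = "heterogeneous"` — subject-level τᵢ ~ Exp(α) treated as
  missing data, Monte-Carlo EM with the closed-form rate update
  α̂ = m / Σᵢ E[τᵢ];
* `model = "covariate"` — prior rates αᵢ = exp(αᵀxᵢ) log-linear in
  subject covariates, BFGS for the coefficient update.

Around the estimator: solution paths with extended-BIC selection
(EBIC = −2ℓ̂ + |G|·log n + |G|·log p / T, T = 2), a synthetic-data engine
(random G-Wishart precision matrices, irregular Poisson designs,
heterogeneous sub-communities, left-censoring), recovery evaluation
(TPR/FPR, connection probabilities, ROC/AUC) against plain graphical-lasso
and neighborhood-selection baselines, ALR preprocessing for compositional
counts, and a permutation test for concordance between an estimated
network and a phylogenetic tree.

## Worked example

```r
library(lgnet)
sim <- simulate_sggm(p = 20, m = 10, mean_ni = 10, edge_density = 0.1,
                     scenario = "homogeneous", tau = 0.1, seed = 42)
sim$data
#> Longitudinal abundance data: 10 subjects, 20 taxa, 93 observations
#>   observations per subject: 7-15 (mean 9.3)

path <- sggm_path(sim$data, nlambda = 8, seed = 1)
summary(path)
#>       lambda n_edges   loglik      ebic selected
#> 1 0.93005739       0 1181.481 -2362.962    FALSE
#> 2 0.60624521       6 1262.771 -2489.360    FALSE
#> 3 0.39517266      42 1419.732 -2586.185     TRUE
#> 4 0.25758790      91 1452.255 -2355.738    FALSE
#> ...

fit <- select_network(path)
fit
#> Stationary Gaussian graphical model fit (homogeneous)
#>   20 taxa, 10 subjects, 93 observations; lambda = 0.3952
#>   edges: 42 of 190 pairs
#>   dampening rate tau = 0.01321
#>   log-likelihood = 1419.732; NOT converged after 30 iteration(s)

tpr_fpr(fit, sim$truth)
#>       tpr       fpr
#> 0.6538462 0.1524390
```

Reading the output: the path sweeps eight penalties from the empty graph
downward; EBIC picks λ ≈ 0.395 with 42 of 190 possible edges. Against the
simulated truth the selected network recovers 65% of the true edges at a
15% false-positive rate. The dampening estimate τ̂ ≈ 0.013 says adjacent
samples (unit spacing) correlate at exp(−0.013) ≈ 0.99 — strongly
dependent series, which is exactly when modelling the correlation pays
off. The `NOT converged` flag reports the iteration cap for this dense-ish
penalty; see the methods vignette (`vignettes/sggm-methods.Rmd`) for the
local-solution semantics behind it.

Real data enter either as a wide table via `longitudinal_data()` /
`read_longitudinal()` (already-transformed values) or as raw counts via
`alr_transform()`. Network–phylogeny concordance:

```r
pt <- permutation_test(fit, ape::read.tree("tree.nwk"), n_perm = 5000)
```

A thin command-line interface over the same functions ships in
`inst/cli/lgnet.R` (subcommands `simulate`, `fit`, `path`, `evaluate`,
`permtest`).

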