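---
title: "Stationary Gaussian graphical models for irregular longitudinal microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stationary Gaussian graphical models for irregular longitudinal microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgnet)
```

## The model

Microbial interaction networks are usually read off the precision matrix
$\Omega = \Sigma^{-1}$ of a Gaussian model for transformed abundances: a
zero off-diagonal entry $\omega_{jk}$ means taxa $j$ and $k$ are
conditionally independent given all others, and the nonzero pattern of
$\Omega$ is the network. Cross-sectional pipelines (SPIEC-EASI and
relatives) estimate $\Omega$ by the L1-penalized Gaussian likelihood and
assume independent samples. Longitudinal cohorts violate that assumption:
samples from the same subject are correlated, and in practice they are
collected at irregular times with very different series lengths per
subject.

`lgnet` implements a *stationary* Gaussian graphical model for this
setting. Subject $i$ contributes observations $y_{it}\in\mathbb R^p$ at
strictly increasing times $t_{i1} < \dots < t_{in_i}$, each marginally
$N_p(0,\Sigma)$ (abundances are centered by the loader), sharing one
network $\Omega$ across subjects and times. Within a subject, the
correlation between time points decays exponentially with their distance,
so the stacked vector $y_i$ has covariance

$$\mathrm{Var}(y_i) = \Phi_i \otimes \Sigma, \qquad
  (\Phi_i)_{jk} = \exp(-\tau_i\,|t_{ij} - t_{ik}|).$$

The dampening rate $\tau_i > 0$ measures how fast the community decorrelates:
large $\tau_i$ is effectively independent sampling, small $\tau_i$ strongly
correlated series. The exponential kernel makes $\Phi_i^{-1}$ tridiagonal
(a continuous-time AR(1) / Ornstein–Uhlenbeck Markov property), which every
likelihood computation in the package exploits; the uniform and
squared-exponential kernels sometimes used for spatial designs are not
implemented.

Three dampening models are fitted by `sggm()`:

* **homogeneous** — one shared $\tau$;
* **heterogeneous** — subject-level $\tau_i \sim \mathrm{Exp}(\alpha)$
  treated as missing data;
* **covariate-adjusted** — prior rates $\alpha_i = \exp(\alpha^\top x_i)$
  depending log-linearly on subject covariates (sex, treatment group, ...),
  with $x_i = (1, x_{i1}, \dots, x_{iq})^\top$.

All three minimize the L1-penalized negative log-likelihood
$-2\,\ell_n(\Omega,\cdot) + n\lambda\|\Omega\|_1$. The likelihood reduces,
through the identity
$y_i^\top(\Phi_i^{-1}\otimes\Omega)y_i = \mathrm{tr}(S_i(\tau_i)\,\Omega)$,
to a graphical-lasso problem on the weighted second-moment matrix
$\bar S(\tau) = n^{-1}\sum_i S_i(\tau_i)$, so each solver alternates a
graphical-lasso step with an update of the dampening parameters:

* homogeneous: 1-D likelihood maximization over $\tau$ (a local,
  trust-region Brent step on $\log\tau$ — see *Degeneracy* below);
* heterogeneous: a Monte-Carlo EM step — the $\tau_i$ posterior
  (exponential prior times Gaussian likelihood) is sampled by inverse CDF
  on a 2048-point log-spaced grid over $[10^{-4}, 10^4]$, and the prior
  rate update is the closed form $\hat\alpha = m / \sum_i E[\tau_i]$;
* covariate-adjusted: the same E-step with per-subject rates
  $\exp(\alpha^\top x_i)$, and a BFGS minimization (with analytic gradient
  and Newton polish to gradient norm $10^{-8}$) of the smooth convex
  M-step objective $\sum_i(-\alpha^\top x_i + e^{\alpha^\top x_i}E[\tau_i])$.
  Covariates are standardized internally and the coefficients
  back-transformed, purely for conditioning.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | — | L1 penalty on $\Omega$ (same scale as the entries of $\bar S$) |
| `penalize_diag` | `FALSE` | whether the penalty covers $\mathrm{diag}(\Omega)$ |
| `tau_init` | 0.1 | starting shared rate (homogeneous) |
| `alpha_init` | 10 | starting prior rate, i.e. prior mean dampening 0.1 |
| `h` | 500 | Monte-Carlo draws per subject per E-step (final pass $10h$) |
| `tol` | $10^{-3}$ | stop when the dampening parameter and the max-norm change of $\Omega$ both move less than this (rates measured relatively) |
| `max_outer` | 30 | outer-iteration cap |
| `edge_threshold` | $10^{-8}$ | $|\hat\omega_{jk}|$ above this counts as an edge |

Time units are arbitrary but must be consistent within a dataset; $\tau$
is in reciprocal time units. Reference points: $\tau = 0.36$ at unit
spacing leaves lag-one correlation $e^{-0.36}\approx 0.70$ (weak
dependence between estimates), $\tau = 0.018$ leaves $0.98$ (strong).

**Why the diagonal is not penalized by default.** The L1 notation in the
penalized objective can be read as covering the diagonal, and the flag is
exposed. But with a penalized diagonal the fitted
$\hat\omega_{jj} \approx 1/(\bar s_{jj} + \lambda)$ shrinks with
$\lambda$, and the dampening updates are exquisitely sensitive to the
overall scale of $\Omega$: the subject-level posterior of $\tau_i$ has an
exponent of order $p(n_i-1)/2$ multiplying $\log|\Phi_i|$, and an
under-scaled $\Omega$ lets that term dominate and drags $\tau$ toward
zero. Leaving the diagonal unpenalized (the SPIEC-EASI / `huge`
convention) anchors the scale and removes this failure mode.

## Degeneracy of the joint objective, and how the solvers handle it

For strongly correlated high-dimensional data (small true $\tau$,
$p$ comparable to or larger than the total sample), the *joint* penalized
objective is unbounded along $\tau \to 0$: as $\Phi_i$ approaches the
singular all-ones matrix, $\bar S(\tau)$ inflates and the graphical-lasso
step can rescale $\Omega$ so that the likelihood grows without limit. The
profiled objective (minimizing over $\Omega$ at each $\tau$) is then
monotone decreasing toward the $\tau$ lower bound at sparse penalties, so
a global optimizer would always return the degenerate branch.

The solvers therefore track *local* solutions, which is also what a
Newton-type update from a finite starting point does: the homogeneous
$\tau$-step searches one decade each way around the current iterate, and
all solvers stop by the finite-tolerance rule above. At sparse penalties
a stable interior solution usually exists and is found; at dense
penalties the iteration may drift toward small $\tau$ and report
`converged = FALSE` at the iteration cap. This regime matters for model
selection (below) and is the main caveat when interpreting the
heterogeneous fits' $\hat\alpha$ at small penalties: the per-subject
forecasts $\hat\tau_i$ are trustworthy on the stable branch, not after a
drift.

Monte-Carlo EM engineering: the expensive E-step quantities (per-subject
quadratic-form grids) depend only on $\Omega$, so each outer iteration
solves the prior-rate fixed point to convergence by cheap re-weighted E/M
cycles before the single graphical-lasso step — each cycle is an exact EM
step, so the monotonicity of EM is preserved. Draws reuse one fixed set
of per-subject uniforms across iterations (common random numbers), making
the outer map deterministic; an Aitken $\Delta^2$ extrapolation of the
log-rate parameters, applied every third iteration with a clamped step,
accelerates the geometric EM convergence. Seeded runs are therefore
bit-reproducible.

## Solution paths and model selection

`sggm_path()` fits a decreasing penalty grid with warm starts. Because
the scale of $\bar S$ depends strongly on the fitted dampening rate, the
default grid is anchored by pilot fits: the penalty is repeatedly reset
to the smallest value that empties the graph under its own fitted
dampening until it stabilizes, then `nlambda` log-spaced values down to
`lambda_min_ratio` times that anchor are used.

Selection uses the extended BIC,
$\mathrm{EBIC} = -2\hat\ell + |G|\log n + |G|\log p\,/\,T$ with $T = 2$,
$|G|$ the number of undirected edges and $n$ the number of observation
rows. For the homogeneous model $\hat\ell$ is the exact (constant-adjusted)
log-likelihood. The heterogeneous/covariate marginal likelihood has no
closed form; the package uses the expected complete-data log-likelihood
at convergence — including the $E[\log|\Phi_i|]$ term estimated from the
refinement draws and the exponential-prior terms — and flags it as a
surrogate in reports. Because this surrogate is evaluated on whichever
branch (stable or drifted) the EM landed on, EBIC comparisons across the
branch boundary inherit that discontinuity; the selected operating point
for dense, strongly-correlated designs can therefore vary between
replicates. This is a property of the estimator family, not of the
implementation, and it is the main reason network-level operating points
for the heterogeneous model are reported as averages over replicates.

For the neighborhood-selection baseline no likelihood exists; the package
selects by the standard Gaussian pseudo-likelihood EBIC
$\sum_j n\log(\mathrm{RSS}_j/n) + |G|\log n + |G|\log p / T$ over the
AND-symmetrized path (OR available). Both baselines operate on
unit-variance (correlation-scale) pooled data, as the cross-sectional
pipelines they represent do.

## The synthetic-data engine

`simulate_sggm()` reproduces the simulation design the estimators are
evaluated on:

* **truth**: an Erdős–Rényi adjacency at the requested edge density;
  weights by default from a G-Wishart draw $W_G(3, I)$ (full Wishart draw
  plus iterative graphical completion), the standard generator for random
  sparse precision matrices, giving realistically strong partial
  correlations. A diagonal-dominance scheme (`method = "dominance"`,
  weights $\pm U[0.3, 0.7]$, dominance margin 0.5, correlation rescale)
  is kept as an alternative; its partial correlations are uniformly weak
  (around 0.1 at density 0.1), which makes network recovery by any
  likelihood criterion essentially impossible at realistic sample sizes.
* **design**: $n_i \sim$ Poisson(`mean_ni`) truncated to $\ge 2$ (so
  every subject informs the dampening rate), gaps
  $\max\{\mathrm{Poisson}(1), 0.5\}$, times starting at 0.
* **data**: matrix-normal draws $y_i \sim N(0, \Phi_i \otimes \Sigma)$
  via the Cholesky factors of the two Kronecker components.
* **scenarios**: shared $\tau$ (presets `s1`–`s4` = 0.36, 0.14, 0.049,
  0.018); random $\tau_i \sim \mathrm{Exp}(\alpha)$; covariate-driven
  rates with $x_1 \sim N(0,1)$, $x_2 \sim \mathrm{Bernoulli}(0.5)$ and
  intercept 4 (so the mean dampening is $e^{-4} \approx 0.018$ under null
  effects); and a two-community split (first half of the taxa community
  A) with independent blocks and separate rates.
* **left-censoring** (`censor_left`): per taxon, values below the
  empirical $q_1$-quantile are replaced by that quantile with probability
  $q_2$ — zero inflation on the transformed scale.

What the generator does *not* emulate: compositional count sampling
(multinomial read depth), taxon-specific dampening within a community,
non-Gaussian tails, and time-varying networks. Passing tests on this
engine show the estimators recover the generative model they assume (plus
the two stated violations — sub-communities and censoring); they do not
certify behavior on raw sequencing counts, which must first pass through
`alr_transform()` or an equivalent compositional treatment.

## Network–phylogeny concordance

`alr_transform()` prepares compositional counts: taxa observed in fewer
than 10% of rows are pooled into a composite reference, per-taxon zeros
are replaced by (minimum positive value)/10, and each remaining taxon is
log-ratioed against the composite. `distance_vectors()` computes paired
shortest-path distances between taxa in the estimated network and in the
phylogenetic tree (tree treated as a graph, internal nodes traversed, hop
counts by default — branch-length weighting is an option); pairs with no
connecting network path are excluded. `permutation_test()` relabels the
network's taxa uniformly at random, keeping the structure fixed, and
reports the one-sided add-one p-value for the Pearson correlation between
the two distance vectors (Spearman available). Permutations act on the
precomputed distance matrix, so even thousands of permutations are cheap.

## Numerical choices

* Graphical-lasso subproblem: blockwise coordinate descent
  (RcppArmadillo), warm-started along paths through the lasso
  coefficients only (the working covariance is always rebuilt from the
  current input — warm-starting it across different inputs is unsound);
  convergence at $10^{-4}$ (relative to the mean absolute off-diagonal),
  loosened to $10^{-3}$ inside EM iterations with a tight final pass; a
  retry ladder (cold start, diagonal ridge, tighter tolerance) guards the
  near-singular inputs the drift regime produces, and an M-step that
  still fails ends the EM gracefully at the last valid iterate.
* $\tau$ domain $[10^{-4}, 10^4]$ throughout, avoiding the singular
  $\Phi$ limit.
* Edges are entries with $|\hat\omega_{jk}| > 10^{-8}$; EBIC ties break
  toward the sparser (larger-penalty) model.
* Degenerate inputs: all-$n_i = 1$ data fall back to the plain graphical
  lasso with a warning ($\tau$ unidentifiable); duplicate times, missing
  values and rank-deficient designs are rejected with descriptive errors.

## Problem sizes used in the shipped checks

The package's own test suite and the reproduction script run scaled-down
versions of the simulation study: 10 replicates per simulation cell
(the study used 50), penalty grids of 8–12 points down to 0.05–0.1 of
the anchor, an outer-iteration cap of 20 in the reproduction script,
ROC batches at $p = 40$, and parameter-recovery runs at $p = 20$. These sizes are the package's choice of a desk-scale experiment;
all generative settings (sample sizes per cell, dampening rates, edge
density, censoring levels) are the study's.

**Where parameter estimates are read.** Along a path, the dampening
estimate reported for recovery purposes is taken from the sparse anchor
fit (largest penalty): there the iteration sits on the stable branch and
$\hat\tau$ (or $1/\hat\alpha$) tracks the generative rate; estimates
from deeper, drift-affected fits are biased low.

## Known limitations

* The joint penalized MLE is degenerate along $\tau \to 0$ for dense
  penalties in high dimensions; estimates there are local and
  cap-dependent, and $\hat\alpha$ from drifted fits should not be
  interpreted.
* The EBIC surrogate for the latent-rate models is not the marginal
  likelihood; selected operating points on strongly-correlated dense
  designs are replicate-variable.
* Stationarity: one network for the whole observation window. Cohorts
  with interventions mid-study violate this.
* One dampening rate per subject (or per community in the two-community
  generator); taxon-specific rates are a model violation the estimators
  tolerate but do not model.
* Heavy left-censoring (40% quantile at 70% replacement) injects jumps
  into within-subject increments; the temporal weighting amplifies these
  artifacts and edge ranking can fall below the pooled cross-sectional
  baselines in that regime. Moderate censoring narrows the advantage
  without removing it.
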