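---
title: "Models and methods behind eyescale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eyescale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eyescale` implements a complete comparative-analysis pipeline for the
macroevolution of insect eye size: allometric phylogenetic regressions at the
individual and species level, phylogenetic signal and homogeneous-rate
trait-evolution models, a Bayesian variable-rates regression with
reversible-jump MCMC, a penalized-likelihood multi-rate Brownian model, and a
habitat analysis built from transect monitoring records and a tree-cover
raster. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the methodology left real
choices open. Every empirical statement here is a property that the package's
test suite or `scripts/acceptance.R` computes.

## Trait data and allometry

All traits are log10-transformed before analysis (the transform is guarded so
it cannot be applied twice). Eye surface area (mm^2) scales allometrically
with forewing length (mm), the standard butterfly body-size proxy, so the core
regression is

$$\log_{10}(\text{eye}) = \beta_0 + \beta_1 \log_{10}(\text{wing}) + \dots$$

Two regression levels are offered:

* **`fit_pglmm()`** — an individual-level phylogenetic linear mixed model,
  $y = X\beta + u + e$ with $u \sim N(0, \sigma^2_p C)$ a species-level random
  effect whose covariance $C$ is the phylogenetic variance-covariance matrix,
  and $e$ i.i.d. residual noise. The variance ratio
  $\theta = \sigma^2_p/\sigma^2_e$ is profiled by one-dimensional maximum
  likelihood; $\beta$ and $\sigma^2_e$ then have closed forms. ML (never REML)
  is used so AIC comparisons across fixed-effect structures — body size alone,
  additive and interactive sex terms, family terms — are meaningful.
  Three-way interactions are deliberately not offered. The boundary
  $\theta = 0$ (no phylogenetic effect) is checked explicitly because the
  profile optimum can legitimately sit there.
* **`fit_pgls()`** — species-level generalized least squares on
  species-averaged traits under a choice of correlation structures: Brownian
  motion (BM), Pagel's lambda, Ornstein-Uhlenbeck (OU), or non-phylogenetic
  white noise. Free structure parameters are profiled by Brent search; the
  log-likelihood is the exact multivariate-normal density with all constants,
  so AIC values are comparable across structures.

Wald p-values use a t reference with $n - k$ degrees of freedom at the species
level and a normal approximation at the individual level; both are flagged
approximate in the summaries.

The contribution of shared ancestry is summarized by the likelihood-ratio
partial $R^2 = 1 - \exp(-\tfrac{2}{n}(\ell_{\text{phylo}} -
\ell_{\text{non-phylo}}))$ comparing the phylogenetic fit to the same-formula
ordinary regression. Several related $R^2$ flavors exist; the likelihood-based
one is implemented and the choice is recorded in the result object
(`flavor = "R2_lik"`).

**Relative eye size** is the vector of raw (response-scale) residuals from the
species-level BM regression. Residuals-as-data is known to be fragile in
multiple regression, so downstream stages use them only where a body-size
covariate cannot enter the model (signal estimation, trait-evolution model
fits, the multi-rate model).

## Covariance transforms

`vcv_transform()` implements the structure transforms on the BM covariance
$C$ (entries: shared root-to-ancestor path length; diagonal: root-to-tip
distance):

* *lambda*: off-diagonals multiplied by $\lambda \in [0,1]$, diagonal
  untouched. The transform is linear in $\lambda$, which the tests exploit.
* *OU*: $V_{ij} = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
  (1 - e^{-2\alpha t_{ij}})$ with $d_{ij}$ the patristic distance and $t_{ij}$
  the shared depth. This non-ultrametric, root-state ("non-stationary") form
  reduces to the familiar stationary OU covariance on ultrametric trees and
  approaches BM as $\alpha \to 0$. It is slightly more flexible than the
  stationary `corMartins` form, which matters when interpreting
  cross-implementation likelihood comparisons.
* *EB* (early burst): rate decays as $e^{rt}$ from the root, giving
  $V = \sigma^2(e^{rC} - 1)/r$ elementwise, $r \le 0$, with BM the $r = 0$
  boundary.
* *white*: $\sigma^2 I$.

Trees need not be ultrametric; zero-length branches are tolerated (PSD is
checked to a relative tolerance of 1e-10). Tip order follows the tree; all
joins are by species label, never by index.

## Phylogenetic signal and model selection

`pagel_lambda()` maximizes the MVN likelihood over $\lambda \in [0,1]$ with
the mean and rate profiled analytically, by Brent search plus explicit
boundary checks (Brent never lands exactly on 0 or 1, and BM data place the
optimum at the boundary about half the time). A grid profile is exported for
plotting and a 1-df likelihood-ratio test against $\lambda = 0$ is reported.
Because the null value sits on the boundary in the BM-vs-lambda comparison,
that LRT statistic is a 50:50 mixture of 0 and $\chi^2_1$; the p-values are
conservative, not uniform, and the test suite asserts validity (type-I rate at
most nominal), not uniformity.

`fit_continuous()` fits BM, OU, EB, trend (directional drift; identifiable
only on non-ultrametric trees and otherwise flagged non-converged) and white
noise, each by exact MVN likelihood with the ancestral state and rate profiled
and any shape parameter optimized by Brent search within documented bounds:
$\alpha \in [10^{-8}, 50]/h$ and $r \in [-10, 0]/h$ with $h$ the tree height.
Model comparison uses AICc and Akaike weights; non-converged fits stay in the
output, flagged, and are excluded from the weights. A caveat worth knowing: on
BM-generated data with 59 taxa, OU (one extra parameter, interior optimum)
overtakes BM by AICc in roughly a fifth of replicates — genuine small-sample
overfitting, not an implementation artifact (the likelihoods cross-check
against independent implementations).

`posterior_sensitivity()` replays the signal estimate or the model selection
across a posterior tree set, summarizing the per-tree estimates (median and
95% interval) or the modal best model.

## Variable-rates regression (reversible-jump MCMC)

The Bayesian variable-rates model asks where trait evolution departs from a
single background Brownian rate. Rate scalars $r$ attach to single branches or
whole clades (a clade scalar multiplies the stem branch and every branch
below); the effective rate of a branch is the product of the scalars covering
it, and branches without an active scalar have $r = 1$ exactly. The sampled
state is (regression coefficients, background rate $\sigma^2$, Pagel's
$\lambda$, active scalar set), with likelihood
$y \sim N(X\beta, \sigma^2 V_\lambda(r))$.

Priors follow the published convention where one exists: scalars are
gamma(shape 1.1) with the scale rescaled so the prior median is exactly 1;
coefficients are uniform(-100, 100); $\lambda$ is uniform(0, 1). Two pieces
are not published anywhere and are this package's own documented choices:

* the **background-rate prior**, exponential(rate 0.1) — proper (required for
  marginal likelihoods) and diffuse on the scale of log-trait regressions; it
  is shared by the homogeneous and variable-rates models, so it largely
  cancels from the Bayes factor;
* the **prior on the number of active scalars**: Poisson with mean
  $n_{\text{positions}} \cdot e^{-3}$, with scalar placement uniform in a way
  that matches the birth proposal (so the dimension-change proposal terms
  cancel and birth/death accept on the tempered likelihood ratio plus the
  count-prior ratio). The mean is chosen so that any particular scalar has
  prior odds of about $e^{-3}$: a candidate must improve the log-likelihood by
  roughly 3 nats — strong evidence by the conventional log-Bayes-factor
  yardstick — before the posterior favors keeping it. Without a decaying
  count prior the sampler accumulates scalars on short branches whose rates
  are unidentifiable (we verified this failure mode directly).

One structural subtlety deserves emphasis: the background rate and a
near-global rate scaling are not separately identified — multiplying
$\sigma^2$ by $c$ while dividing every effective branch rate by $c$ leaves
the likelihood exactly unchanged, and with diffuse priors the chain diffuses
along this ridge (we observed runs expressing a clade shift as "everything
else compressed, $\sigma^2$ inflated twelvefold"). The sampler therefore
canonicalizes every posterior sample to the representative of its
equivalence class whose **median branch rate is 1**: background is anchored
at the typical branch and scalars are read relative to it, which is also the
convention in which branch scalars are conventionally reported. The
transformation is exact (the likelihood is invariant), so marginal
likelihoods and Bayes factors are unaffected.

Moves: each iteration updates either one continuous parameter (random walk;
$\lambda$ reflected into $[0,1]$, $\log\sigma^2$ with its Jacobian) or the
scalar set with the 25% birth / 25% death / 50% perturb mix, births proposing
the new value from the scalar prior and perturbations using a log-normal
random walk. Proposal scales default to 0.3 for $\lambda$ and 1.3 for
$\log r$; narrower $\lambda$ proposals were observed to trap the sampler in a
$\lambda$-vs-scalar valley where genuine 15+ nat rate shifts went undetected.
The likelihood core is compiled (RcppArmadillo): the covariance is rebuilt
from the branch incidence matrix and Cholesky-factorized at every evaluation,
which keeps the desk-scale default — 3 chains of 200 000 iterations, burn-in
20 000, thinning 20 — around half a minute on one CPU. Production-scale runs
(the hundred-million-iteration regime) use the same code with an explicit
configuration override.

Diagnostics (`mcmc_diagnostics()`) report effective sample sizes from Geyer's
initial-positive-sequence autocorrelation estimator and the split
Gelman-Rubin statistic, with the conventional thresholds (1000 and 1.2) as
configurable flags. These are implemented in the package because no MCMC
diagnostics package is among its dependencies.

Marginal likelihoods use stepping-stone sampling along the
$t_k = (k/K)^{1/0.3}$ ladder (quantiles of Beta(0.3, 1), concentrating rungs
near the prior), K = 32 by default; the generic `stepping_stone()` estimator
is validated against the conjugate normal-mean closed form to within 0.1
nats. The Bayes factor is $2(\log \text{ML}_{\text{complex}} -
\log \text{ML}_{\text{simple}})$, with values above 2 read as support for the
variable-rates model. `consensus_scaled_tree()` multiplies each branch by the
posterior mean of its scalar, the standard way to visualize stretched
(fast-evolving) clades.

## Penalized-likelihood multi-rate Brownian motion

`multirate_bm()` lets $\ln \sigma^2$ itself evolve: one value per node, edge
rates the exponential of the mean of the two endpoint values, and objective

$$\ell(y \mid \text{edge rates}) + \lambda_{\text{pen}} \cdot
  \ell_{\text{BM}}(\ln \sigma^2 \mid \text{tree})$$

where the penalty is the Brownian log-density of the node log-rates on the
same tree with unit rate-of-rates. Small penalties allow rapid rate change;
large ones shrink toward homogeneity, and the fitted rate variance decreases
monotonically in $\lambda_{\text{pen}}$. Because no single penalty is optimal
a priori, the model runs at $\lambda_{\text{pen}} \in \{0.1, 1, 10, 50\}$ by
default and clades that deviate consistently across penalties are the robust
signal. Optimization is BFGS over the $2n - 1$ node values, started from the
homogeneous-BM rate; edge lengths are floored at 1e-8 in the penalty to guard
zero-length branches.

## Habitat quantification and community-weighted means

The habitat proxy is percent tree cover from a raster (10 m cells in the
emulated design), extracted along monitoring transects. Each transect segment
is buffered by 10 m on each side into a capsule with rounded end caps (the
original workflow does not state the cap type; rounded is the choice here).
The fraction of each raster cell inside the capsule is computed by
supersampling the cell at 32x32 points by default — within 0.1% of the exact
area at that resolution, and configurable downward for large simulation
sweeps (the calibration tests use 4-8). Cells with coverage fraction below
0.002 and missing cells are excluded from both numerator and denominator of
the weighted mean $\sum f_i v_i / \sum f_i$. Coordinates are planar meters;
no geodesy.

Species habitat is presence-based: every species recorded on a segment
receives that segment's weighted cover once (abundance plays no role here),
and the species statistic is the median over its segments. Abundance enters
only the community-weighted means, $\sum_s a_s t_s / \sum_s a_s$ per segment,
which are regressed on segment cover by OLS.

`habitat_pgls()` regresses species-averaged eye size on standardized median
cover (and standardized forewing length unless testing absolute eye size).
Its default correlation structure departs deliberately from a plain BM PGLS:
species means computed from a handful of individuals carry sampling noise,
and under a pure BM structure that white component inflates the short-branch
contrasts enough to make the habitat test badly anticonservative (nominal
95% intervals covering the null far less often than advertised). The default
therefore profiles Pagel's lambda **and** adds the known sampling variance
of each species mean (pooled within-species variance over sample size,
`species_mean_noise()`) to the residual diagonal — a measurement-error PGLS,
available generally through `fit_pgls(mean_noise = )`. The package's own
200-replicate null calibration (in the test suite) verifies that the
default's 95% interval covers the null at its nominal rate. The plain
variant remains available
(`structure = "BM", measurement_error = FALSE`) for comparability with
analyses that ignore measurement error.

## The synthetic-data generator

`sim_config()` fixes the study conditions the generator emulates: 59 species;
443 individuals in two sexes when an exact total is requested (4-8 per
species otherwise); log-log allometric slope 0.55 with a +0.11 male offset on
the log10 scale; Brownian forewing evolution (variance 0.03 per unit tree
height, giving the tight scaling regime where the slope is estimated to about
±0.04); a species-level eye-size deviation with Brownian variance 0.01
(residual relative eye size SD ≈ 0.1); within-species individual size
variation (variance 0.002) shared allometrically between wing and eye, plus
measurement noise (variance 0.0025) on eye size. One monophyletic clade — the
group with the longest stem branch among groups of workable size, emulating
an old, anatomically distinct family like the skippers — evolves its eye-size
deviation at 10x the background rate. The long-stem choice matters: a recent
clade with a short stem frequently leaves no detectable likelihood signal of
a 10x rate, whereas an old clade accumulates a large shared deviation on its
stem.

Monitoring data: a spatially autocorrelated cover field (Gaussian-smoothed
white noise rescaled to [0, 100]); straight transects of fixed-length
segments; Bernoulli presence with a logistic response to the mismatch between
segment cover and a species' habitat optimum (association strength 8 by
default; 0 makes occupancy habitat-blind), Poisson abundance given presence;
two species withheld from monitoring to emulate the common mismatch between
the measured and the monitored species sets. The trait-habitat coupling
`habitat_effect` defaults to 0 — the no-association regime — and when nonzero
adds `habitat_effect * z(optimum)` to species eye size.

What the generator does **not** emulate: real geography or projection
effects, multi-year temporal dynamics and detectability, non-Brownian wing
evolution, family-correlated habitat preferences, and topological uncertainty
in the posterior tree sets (branch lengths are jittered log-normally on a
fixed topology). Calibration results on these synthetic data therefore speak
to the correctness of the estimators under the stated generating model, not
to robustness against those real-data complications.

## Problem sizes and numerical choices

The test suite and acceptance checks run at sizes chosen to exercise each
property well inside a routine desktop budget: 5-taxon trees for exact-oracle
comparisons; 50 replicates at 59 taxa for signal recovery; 100 replicates for
model-selection calibration; 20 replicates of 443 individuals for slope
recovery; one 3x200k-iteration null run plus ten seeded shift runs for the
variable-rates model; 200 replicates for the habitat null calibration.
Optimizers: Brent with tolerance 1e-8 on profile likelihoods (with explicit
boundary evaluation), BFGS with relative tolerance 1e-10 for the multi-rate
model, Nelder-Mead for the two-parameter measurement-error PGLS. Cholesky
factorization failure anywhere is treated as likelihood $-\infty$ (rejected
proposal) rather than an error. Single-data-draw MCMC calibrations are exact
only up to the randomness of the draw: on occasional null datasets Brownian
motion genuinely mimics a mild clade shift, and the sampler (correctly)
reports it; the fixed-seed tests document the typical, not the worst, case.

## Known limitations

* PGLMM p-values are normal approximations; no Satterthwaite or bootstrap
  refinement is offered.
* The variable-rates sampler updates one coordinate per iteration; for trees
  far larger than a few hundred tips a blocked or marginalized sampler would
  mix better.
* `multirate_bm()` reports the penalized optimum only — no curvature-based
  uncertainty on the edge rates.
* The habitat workflow assumes projected planar coordinates and segments
  small relative to raster extent; partially off-raster segments are retained
  with a warning (whether the original workflow did so is unstated).
* OU model selection at n ≈ 60 over-selects OU on BM data at a known rate
  (see above); treat single-dataset AICc wins of OU over BM with caution,
  exactly as the empirical literature advises.
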