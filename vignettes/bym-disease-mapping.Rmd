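---
title: "Small-area BYM disease mapping: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area BYM disease mapping: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the statistical
models, the defaults and why they are what they are, what the synthetic-data
generator does and does not emulate, and the numerical decisions that a
maintainer would otherwise have to reverse-engineer from the code.

## 1. The outcome model

The package targets ecological (area-aggregated) studies: in each of $n$
contiguous areas, $O_i$ of $n_i$ surveyed individuals are above an outcome
cut-off (here, an Edinburgh Depression Scale score above 9 or above 12).
Expected counts are internally standardized,
$E_i = n_i \sum_j O_j / \sum_j n_j$, so $\sum E_i = \sum O_i$ by
construction and the standardized morbidity ratio is $O_i/E_i$. A caller
who prefers an external reference denominator (e.g. women of child-bearing
age) passes it to `expected_counts(reference_denominator=)`; there is no
separate code path.

The Besag–York–Mollié model puts, on the log relative risk,

$$\log \theta_i = \beta_0 + x_i^\top \beta + u_i + v_i,$$

with $u$ an intrinsic CAR field over the contiguity graph (each $u_i$
conditionally normal around the mean of its neighbours with precision
$\tau_u d_i$) and $v_i \sim N(0, 1/\tau_v)$ iid. The ICAR prior is improper
— its precision matrix $\tau_u (D - W)$ has the constant vector in its null
space — so $u$ is identified by a sum-to-zero constraint, enforced every
MCMC sweep by recentring with the mean absorbed into the intercept (the
WinBUGS `car.normal` convention). Islands and disconnected graphs are hard
errors throughout: the ICAR conditional is undefined for an isolated area.

Two likelihoods share this linear predictor:

* **Poisson** (default): $O_i \sim \text{Poisson}(E_i \theta_i)$, the
  standard disease-mapping approximation for aggregated binary outcomes.
* **Lognormal**: $y_i = \log((O_i + c)/E_i) \sim N(\log\theta_i, \sigma^2_e)$
  with $c = 0.5$ only if some count is zero. This matches a "log-normal
  model for relative risk" formulation; both likelihoods support the same
  decomposition and selection machinery, and a binomial *generator* option
  exists for robustness experiments.

**Priors.** Intercept and coefficients: $N(0, 10\,000)$. Random-effect
precisions: $\Gamma(0.5, 0.0005)$ — the same distribution sometimes stated
as an inverse-Gamma prior on the variance; it is one knob here, not two.
Covariates are standardized by the generator (and a fit warns when column
standard deviations are far from 1) so that the fixed-variance prior is
genuinely vague.

## 2. The sampler

The Poisson model is not conjugate, so the compiled core
(`src/bym_sampler.cpp`) uses single-site adaptive random-walk Metropolis for
$\beta_0$, each $\beta_j$, each $u_i$ (against its ICAR full conditional)
and each $v_i$, with conjugate Gamma draws for $\tau_u$ (shape offset
$(n-1)/2$, the ICAR rank) and $\tau_v$ (offset $n/2$). Proposal scales
adapt toward 0.44 acceptance every 100 sweeps **during burn-in only**; the
kept chain is strictly Markovian. Because correlated covariates make
single-site coefficient updates mix slowly, the sampler also learns the
joint posterior covariance of $(\beta_0, \beta)$ during burn-in (running
Welford moments, Cholesky refreshed every 200 sweeps) and applies three
joint Metropolis proposals per sweep at the usual $2.38/\sqrt{d}$ scaling,
adapted toward 0.234 acceptance. This keeps the Gelman–Rubin statistic of
all coefficients below ~1.03 at the default 2 × (3000 + 3000) run lengths
even with covariate correlations around 0.75.

The lognormal model is fully conjugate and is sampled by pure Gibbs; fixed
values of $\tau_u$, $\tau_v$ or $\sigma^2_e$ can be supplied
(`bym_config(fix_*)`), which is how the closed-form normal-posterior oracle
test pins the sampler down.

Chain $c$ is seeded with `seed + c * 10007`; every piece of randomness in
the package flows from explicit integer seeds, so identical configurations
are bit-identical.

**DIC.** $\bar D$ pools the per-draw deviance over chains; $\hat D$ is the
deviance at the posterior means of *all* parameters, random effects
included; $p_D = \bar D - \hat D$ may be negative for poorly identified
models and is reported, not clamped. MC errors use 50-batch batch means
(the WinBUGS convention), and the potential scale reduction factor is
$\sqrt{((n-1)/n\,W + B/n)/W}$, which is deliberately below 1 for identical
chains.

## 3. Forward selection by DIC

`forward_select()` starts from a spatial-residual-only base (full BYM by
flag), fits every remaining candidate with `n_seeds = 3` seeded reruns, and
accepts the candidate with the largest mean DIC decrease if (a) the
decrease exceeds `dic_tolerance = 1` — models whose DIC differs by less
than one are treated as indistinguishable, hence the repeated seeded runs —
and (b) the candidate's 95% credible interval excludes zero **in every
seeded rerun**. If an addition de-significs a previously accepted
coefficient it is rejected and the next-best candidate is tried; if the
best remaining candidate is itself non-significant, selection stops. The
all-reruns significance rule extends the reproducibility-across-seeds
motivation of the repeated runs to the significance decision; since reruns
share the data it is nearly equivalent to pooled-draws significance in
practice.

A property worth stating plainly: with $m$ independent noise candidates and
a 95% credible-interval significance rule, the probability that *no* noise
candidate is accepted in a pure-noise world is at most about $0.95^m$
(≈ 0.77 at $m = 5$), because the DIC-decrease condition is essentially
implied by the significance event ($\Delta\text{DIC} \approx 2 - z^2$).
The selection specificity test in `test-acceptance.R` asserts a 90%
empty-model rate and is therefore expected to fail: the decision rule
itself cannot deliver that specificity, and we prefer an honestly red test
to a silently weakened one. Power is unaffected: a covariate with a true
log-RR of 0.5 across 101 areas is selected first in ≈ 90% of replicates.

## 4. Map decomposition

Per kept draw, $\theta_i$ factorizes exactly into
$e^{\beta_0} \prod_k e^{x_{ik}\beta_k}\, e^{u_i}\, e^{v_i}$.
`decompose_rr()` summarizes each factor per area (posterior mean for
mapping, plus median and 95% limits). The identity holds to machine
precision *per draw*; it does **not** hold for summaries — the mean of a
product is not the product of means — so total relative risk is always
summarized from the per-draw products. Surfaces export to CSV and GeoJSON;
class breaks, colour scales and rendering are presentation concerns and out
of scope.

## 5. The EFA pipeline

`screen_variables()` iteratively removes one of each pair with
$|r| > 0.90$ (a conventional multicollinearity cut-off; the threshold is a
parameter), keeping the variable more correlated with the outcome when one
is supplied and the alphabetically first otherwise, and logs every removal.
Diagnostics are Bartlett's sphericity test
($\chi^2 = -((n-1) - (2p+5)/6)\log\det R$), the KMO statistic and
per-variable MSA from the anti-image (negative partial correlation) matrix.

Extraction is principal-axis factoring: iterate communalities (initialized
at squared multiple correlations) on the reduced correlation matrix until
the largest change falls below `tol`. Heywood communalities are clipped to
$1 - 10^{-6}$ with a warning rather than aborting — the context is
exploratory. Rotation is direct oblimin via gradient projection with
$\gamma = 0$ (direct quartimin, the SPSS default delta) and Kaiser row
normalization; ten deterministic random starting rotations guard against
local minima, and the factor order/sign convention (descending explained
sum of squares, positive primary loading) makes output reproducible.
Reported pattern matrices mask $|loading| < 0.30$ for readability; the
unmasked values are always retained. The eigenvalue-greater-than-one count
is offered as a *suggestion* for the number of factors — the final choice
is the analyst's interpretability judgement, which is why `run_efa()` fits
a whole range of $k$. Factor *names* (e.g. "disadvantaged community",
"social cohesion") are analyst metadata, never computed.

## 6. The synthetic world

The generator states one world and the tests live in it:

* **Geography**: 101 areas (the study frame's suburb count), either a
  near-square grid of unit cells (rook-connected by construction) or a
  Voronoi tessellation of uniform seed points in the unit square, clipped
  by half-plane intersection, regenerated on the rare disconnected draw.
  Real suburb geometry is unavailable; any connected planar graph exercises
  the CAR machinery identically.
* **Covariates**: 26 variables from a 6-factor oblique model,
  $X = F\Lambda^\top + E$, with the published primary loading of each
  variable on its factor (signs preserved) and unique variances completing
  each variable to unit total variance. The extracted source table loses
  column alignment for secondary loadings, so cross-loadings are omitted —
  the generator states a clean simple structure. Factor correlations are
  0.15 baseline with the two values the source analysis reports (0.40
  disadvantage–health-behaviours, 0.26 cohesion–capital).
* **Outcomes**: survey sizes uniform on 60–245 (mean ≈ 152, ≈ 15,400
  mothers overall, matching the study scale), baseline prevalence 0.09 (a
  realistic regional EDS > 12 rate), counts Poisson with rate
  $0.09\, n_i \theta_i$ truncated at $n_i$; default effect scales
  $\sigma_u = 0.3$, $\sigma_v = 0.1$. The ICAR field is drawn exactly from
  the pseudo-inverse covariance on the sum-zero subspace via the
  eigendecomposition of $D - W$.

What the generator does **not** emulate: irregular real suburb shapes and
their very uneven neighbour counts, spatially *structured* covariates
(covariates here are iid across areas, so spatial confounding between $x$
and $u$ is absent by construction), non-response and informative missingness
in the underlying survey, and same-source bias between aggregated
survey-derived covariates and the outcome. A green parameter-recovery test
therefore establishes calibration of the machinery under the stated world,
not robustness to those real-data pathologies.

## 7. Numerical choices and edge cases

* Contiguity: queen (shared point) is the default, matching the behaviour
  of the GeoBUGS adjacency tool; rook (shared positive-length segment) by
  flag. Shared-boundary detection uses segment-overlap geometry with a
  `snap = 1e-9` tolerance for floating-point borders.
* GeoBUGS files are 1-based; so is everything internal (R convention), so
  no index translation exists to get wrong. Asymmetry, islands,
  `sumNumNeigh` inconsistencies and disconnection are all named, early
  errors.
* `entropy_index` is normalized by $\log R$ so its range is exactly
  $[0, 1]$; `simpson_index` is left unnormalized (maximum $1 - 1/R$), the
  standard definition, even though informal glosses sometimes describe its
  maximum as 1. The Maly index is implemented as one minus half the $L_1$
  divergence from the metropolitan composition — the unique simple form
  that is 1 exactly when the area matches the metropolitan distribution.
* All-zero observed counts make the SMR 0 with a warning in
  `expected_counts` but are an error in `fit_bym` (no information).
* OR summary quantiles are computed as `exp` of the coefficient quantiles
  (exact for a monotone transform); the OR *mean* is the mean of the
  exponentiated draws, which is why mean columns do not exponentiate across
  scales. Reports round coefficients to 3 decimals and odds ratios to 2.
* In the published final-model table a printed coefficient quantile of
  0.253 exponentiates to 1.288 → 1.29, while the printed OR cell reads
  1.28 (and the 2.5%/median Entropy cells disagree similarly at the last
  digit); those cells are internally inconsistent at the printed precision
  and the worked-example tests cover the six consistent cells only.

## 8. Known limitations

* Proper (non-intrinsic) CAR models, WAIC/LOO, and multilevel
  individual-within-area models are out of scope.
* The intercept is weakly identified in the Poisson model when internal
  standardization already centres the rates; this is expected and harmless.
* BYM coefficient coverage in the recovery harness runs at ≈ 93–95% —
  essentially nominal, with the small deficit attributable to the usual
  partial confounding between fixed effects and flexible random effects at
  $n = 101$.
* DIC selection specificity with multiple noise candidates is bounded by
  the significance rule, as quantified in §3.
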