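---
title: "Testing climatic constraints on arboreality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing climatic constraints on arboreality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arboclim)
```

`arboclim` asks a comparative question: do species that use the
arboreal microhabitat occupy a distinguishable climatic envelope from
terrestrial species, once shared evolutionary history is accounted for?
This vignette documents the statistical models the package implements,
the assumptions behind them, the synthetic world used to validate them,
and the numerical and design choices a user or reviewer should know
about.

## 1. The two complementary analyses

The question is attacked from two sides that fail in different ways.

**The comparative (envelope) route** reduces each species' occurrence
climate to a fixed-dimensional summary — five statistics (5th and 25th
percentiles, mean, 75th and 95th percentiles) for each of twelve
bioclimatic variables — so that species become rows of a matrix and
microhabitat becomes a grouping factor in a multivariate phylogenetic
ANOVA. Summaries are comparable across species with wildly different
numbers of records, but they discard the spatial structure of ranges.

**The niche-modeling route** keeps all locality information: each
species gets a maximum-entropy suitability surface over the shared
raster, pairs of species get overlap scores, and microhabitat is tested
on pairwise overlap after adjusting for geographic and phylogenetic
proximity. This route needs no summarization but inherits the
non-independence of pairs.

Agreement between the two is the designed-for evidence pattern.

## 2. Phylogenetic ANOVA with randomized residual permutation

### Model

For the species-by-traits matrix $Y$ (standardized summaries, PC
scores, or one variable's five statistics) and group factor $X$, the
model is $Y = XB + E$ with row covariance proportional to the Brownian
matrix $C$ derived from the chronogram: $C_{ij}$ equals the shared
root-to-MRCA path length (`phylo_covariance()`, validated in tests
against both an independent path-sum oracle and `ape::vcv`). GLS
estimation whitens with $P = C^{-1/2}$ (symmetric eigen-factorization;
eigenvalues below $10^{-12}$ of the maximum raise an error naming the
likely cause, near-duplicate tips) and fits OLS to $(PY, PX)$.

The test statistic is the trace form
$F = \big(\mathrm{tr}(S_m)/\mathrm{df}_1\big) / \big(\mathrm{tr}(S_r)/\mathrm{df}_2\big)$,
the sum over trait dimensions of model and residual sums of squares in
the whitened space. Wilks-type statistics are deliberately out of
scope; the trace form is the standard choice for high-dimensional,
possibly rank-deficient trait matrices.

### Permutation scheme

Significance comes from randomized residual permutation: residual rows
of the intercept-only reduced model (in the whitened space) are
shuffled, added back to the reduced-model fit, and the full model
refit. The observed arrangement counts as one permutation, so
$p = \#\{F^{(b)} \ge F_{obs}\} / (B + 1)$ and $p$ can never be zero.
Permutations that exactly reproduce the observed grouping tie with
$F_{obs}$ up to floating-point noise; exceedance is therefore counted
with a $10^{-8}$ relative tolerance so ties resolve consistently (this
also makes the two-group pairwise test agree exactly with the overall
test on a shared schedule under identity covariance).

The default permutation count is 999 plus the observed arrangement;
every result records its seed. Before the schedule is drawn, rows are
put in sorted species order, making $p$ invariant to input ordering.

### Effect sizes and significance conventions

$Z$ standardizes the observed statistic against the permutation
distribution. By default the log of the statistic is used ($F$ and
between-mean distances are right-skewed under permutation); if any
statistic in the distribution is non-positive the raw scale is used
instead. Pairwise comparisons use the Euclidean distance between GLS
group means as their statistic and expose the one-sided standard-normal
convention $Z > 1.645$ as a significance flag.

Families of related tests (the five PC-axis tests; the twelve
per-variable tests) are corrected by Holm sequential Bonferroni:
rank-$k$ adjusted alpha $\alpha/(m-k+1)$, ties keeping input order
(several tests commonly share the resolution floor $p = 1/(B+1)$, where
rank order is otherwise arbitrary), and the step-down stopping rule.

### Calibration

Type-I error was verified by simulation at the package's study
conditions: 1000 null worlds (40-tip pure-birth trees, Brownian traits
with no group effect, microhabitat labels evolved by the asymmetric
Markov process, 499 permutations) give empirical rejection rates within
[0.03, 0.07] at $\alpha = 0.05$ for both the phylogenetic ANOVA and the
pair-type residual test (`test-acceptance.R`). One procedural caveat
discovered during this calibration is worth recording: the tree, the
trait data, the labels and the permutation schedule must draw from
*independent* seed streams; reusing one seed across generator stages
couples the label draw to the permutation schedule and distorts the
measured rate.

## 3. The maximum-entropy niche model

The package implements its own presence-background maximum-entropy
model: a Gibbs distribution over pixels,
$\pi(x) \propto \exp(w \cdot f(x))$, normalized over the background
(all valid raster pixels — the study extent). Features are per-variable
linear and quadratic terms standardized by background mean and SD, so a
Gaussian climatic niche is exactly representable (negative quadratic
weight). Weights maximize the L2-penalized mean log-probability of the
presence pixels; the objective is convex, solved by BFGS from a zero
start (no randomness, hence no seed), with convergence declared when
the gradient norm falls below `tol`. At convergence with zero penalty
the model's expected features equal the presence-sample feature means —
the defining maximum-entropy stationarity condition, asserted in tests.

Choices a user should know: the default ridge penalty is 0.01
(configurable); hinge/threshold features and clamping are out of scope;
species need at least 15 distinct presence pixels to be modeled (the
package's ENM inclusion floor, versus 3 pixels for the envelope
analysis). AUC is the rank-based presence-versus-background
probability with ties counted one half.

Suitability surfaces are normalized to sum to one over valid pixels,
which is what the overlap metrics assume: Schoener's
$D = 1 - \tfrac12\sum|p-q|$ and Warren's
$I = 1 - \tfrac12\sum(\sqrt p - \sqrt q)^2$, both in $[0, 1]$, equal to
1 for identical surfaces and 0 for disjoint support. Overlap is
computed over the full shared raster (recorded in the pair-table
metadata); restricting to per-pair union extents is a plausible
alternative the package does not implement.

## 4. The pair-type residual test

Overlap values for $n(n-1)/2$ species pairs are regressed (OLS, with
intercept) on the great-circle distance between species' mean
post-thinning occurrence points (WGS84 ellipsoid geodesic via
`geosphere`; a spherical fallback of radius 6371.0088 km is available
and flagged) and on phylogenetic distance
$d_{ij} = C_{ii} + C_{jj} - 2C_{ij}$ (the patristic distance on an
ultrametric tree). Residuals are tested across the three pair types
(AA, AT, TT) by one-way ANOVA with residual randomization, plus three
pairwise mean-difference contrasts with their own permutation
distributions.

Pairs sharing a species are not independent, and the distance
covariates only partially absorb that dependence. The default
permutation shuffles residual rows freely, which treats pairs as
exchangeable; an optional species-level mode permutes microhabitat
labels across species and rebuilds pair types, respecting the pair
structure. The row mode is the default because it matches the
residual-randomization framing of the rest of the package; the caveat
is recorded here and in the output metadata (`mode`). D and I are
always tested separately.

## 5. The synthetic world

The generator produces every input the pipeline needs, with known
effect sizes:

- **Climate raster.** Twelve Gaussian fields mixed by an eigen square
  root of a target correlation matrix (default: a two-factor
  thermal/moisture structure), smoothed with a Gaussian kernel
  (default radius 2 pixels) for spatial autocorrelation, rescaled to
  realistic per-variable locations and scales (e.g. BIO1 15 ± 5 °C,
  Elev 800 ± 600 m, truncated at 0), with a latitudinal BIO1 gradient
  (default 0.7 °C per degree of |latitude|). Grids are row-major from
  the north-west corner; pixel membership is half-open,
  $[\mathrm{west}, \mathrm{east}) \times (\mathrm{south}, \mathrm{north}]$.
- **Chronogram.** A pure-birth tree grown from the root split with
  per-lineage rate $\lambda$ until $n$ tips exist, then cut at the
  next (unrealized) speciation time, so expected depth is
  $\sum_{k=2}^{n} 1/(k\lambda)$ — checked against that closed form by
  Monte Carlo.
- **Microhabitat labels.** A two-state Markov chain along branches,
  sampled from exact transition probabilities. Defaults (gain 0.6,
  loss 1.8) keep the asymmetry direction seen in salamanders — losses
  of arboreality far outpace gains — while leaving a workable arboreal
  minority (stationary fraction 0.25). The much stronger 23:1 rate
  ratio reported for the real clade is exercised explicitly in tests;
  as a default it would leave about one arboreal species per 40-tip
  world and make every group comparison degenerate.
- **Niche centers.** Brownian motion along branches (default rate:
  half the layer SD per unit square-root time), plus a constant
  additive shift on arboreal tips (default: warmer, lower — +2 °C
  BIO1, +2 BIO5, +2.7 BIO6, +64 PET.A, −445 m Elev, magnitudes of the
  contrast sizes a strong real-world signal would show). A constant
  tip-level offset rather than a regime-dependent
  Ornstein-Uhlenbeck optimum is deliberate: the downstream tests are
  mean-difference tests, and the offset creates exactly that signal
  with one interpretable parameter.
- **Occurrences.** Pixels drawn with probability proportional to a
  product-Gaussian suitability of pixel climate around the species'
  niche center (computed in log space), points placed at pixel
  centers.

Everything is a deterministic function of the configuration seed; all
stage sub-seeds are derived from it.

What the generator does *not* emulate: coastlines and irregular study
extents, spatially biased or erroneous occurrence records,
non-Gaussian niches, climate change over the sampling period, and
regime-dependent trait evolution. Passing tests therefore demonstrate
that the statistical machinery is calibrated and powerful under a
clean, known generative model — not that any particular empirical
dataset satisfies these assumptions.

### Study conditions used by the heavy validation suites

Sizes were chosen to make the suites informative while remaining
routine to run on a laptop: calibration uses 1000 replicate 40-tip
worlds at 499 permutations; power and recovery use 100 replicates. The
power worlds have 60 tips on a unit-depth tree, BIO1 Brownian SD 2,
points per species 30–60, niche breadth at half the layer SD, and an
arboreal BIO1 shift of 3.3 °C. That shift is *derived*, not tuned: with
breadth $b = \sigma_r/2$ the occurrence sampler attenuates climate
signals by $a = \sigma_r^2/(\sigma_r^2 + b^2) = 0.8$, and adds
per-species mean noise of roughly
$\sqrt{\sigma_r^2 b^2/(\sigma_r^2+b^2)}/\sqrt{\bar m} \approx 0.36$ °C,
so the realized within-group SD of species means is about
$\sqrt{(0.8 \cdot 2)^2 + 0.36^2} \approx 1.65$ °C and the realized
shift $0.8 \times 3.3 = 2.64$ °C — two within-group standard
deviations, the condition the power claim is stated at. Worlds whose
label draw leaves fewer than two species in either microhabitat cannot
support a group test and are redrawn.

## 6. Microhabitat classification schemes

Six schemes translate primary/secondary microhabitat codes into one
category per species, differing along three axes: whether semi-aquatic
(SW) is its own category (`7-`) or remapped (`6-`), whether a
non-terrestrial secondary microhabitat overrides a terrestrial primary
(lenient `-L`) or the primary always wins (majority-rule `-M`), and
whether an alternative arboreality source forces flagged species into
A (`-Mc-`). Two choices the scheme table does not determine are made
explicit: the SW remap under 6-category schemes is a per-species
override column (default W) because the aquatic-versus-other
resolution is a natural-history fact, not a rule; and secondary codes
are consulted only when the primary is terrestrial, terrestriality
being the generalist state. `classify()` is total over the full
code-by-scheme cross product (exhaustively enumerated in tests), and
`6-M` coincides with `6-McM` whenever the alternative-source flag is
absent.

## 7. Numerical choices and degenerate inputs

- Percentiles use linear interpolation between order statistics
  (`quantile` type 7); standard deviations use the $n-1$ denominator.
- PCA is computed on the standardized matrix via `prcomp`; each
  loading vector is signed so its largest-magnitude entry is positive
  (stabilizes comparisons across runs); requesting more axes than the
  matrix rank truncates with a warning.
- Constant summary columns make standardization impossible and raise
  an error naming the column.
- A response with no variation, or a group with fewer than two
  members, is an error in the ANOVA; identical residuals in the
  pair-type test return $p = 1$ with an undefined $Z$.
- Occurrence thinning keeps the first record per (species, pixel) in
  input order; records outside the raster or on masked pixels are
  dropped with a count.
- Raster text bundles and serialized maxent models print numbers with
  17 significant digits, so round trips are bit-exact.
- The tropical subset filter keeps arboreal/terrestrial species whose
  mean occurrence latitude satisfies $|\phi| \le 23.43655°$ — a
  range-position definition; a taxonomy-based definition would be a
  reasonable alternative the package does not implement.

## 8. Known limitations

- The maxent implementation is a documented stand-in for the classic
  MAXENT application, not a reconstruction: feature classes are
  restricted to linear + quadratic and regularization is L2.
- Free row permutation in the pair-type test understates the
  dependence among pairs sharing a species (see section 4).
- The comparative route tests mean envelope differences only; it does
  not model evolutionary dynamics (no OU optima, no phylogenetic
  signal estimation, no ancestral-state reconstruction).
- Phylogenetic ANOVA conditions on the chronogram being correct up to
  the posterior sample supplied to `posterior_robustness()`.

```{r session}
sessionInfo()
```
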