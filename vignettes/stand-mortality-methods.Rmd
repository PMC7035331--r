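---
title: "Methods: spatial analysis of tree mortality in mapped stands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of tree mortality in mapped stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standspat)
```

## The problem

Desert riparian poplar (*Populus euphratica*) stands along arid-zone
rivers pass through recognisable developmental stages — dense juvenile
thickets near the channel, open mature forest farther out, and dying and
dead stands where the groundwater is out of reach.  Because standing dead
stems persist for decades in these arid conditions, a single census of a
fully mapped plot preserves both the live and the dead point pattern, and
the *spatial* arrangement of deaths carries information about the
mechanism: mortality driven by crowding (self-thinning) depresses
survival close to dead trees at small scales, while drought-driven
mortality kills trees irrespective of their neighbours and leaves the
death pattern indistinguishable from a random thinning of the stand.

`standspat` implements the full inferential chain for such data: stem-map
data structures and I/O, second-order summary statistics, Monte-Carlo
null models with rank envelopes, tree-level survival regression, exact
binomial median tests, and a synthetic-stand generator so the whole chain
can be exercised, calibrated and power-checked without field data.

## Summary statistics

All estimators work on rectangular windows with the half-open convention
`[0, Wx) x [0, Wy)` (a boundary point belongs to exactly one plot when
plots tile).

**Univariate pair correlation function.**  For a pattern of `n` points
the ring-mode estimator is

    g(r) = sum_{i != j} e_ij 1{ d_ij in (r - w/2, r + w/2] }
           -------------------------------------------------
                  lambda * n * pi[(r + w/2)^2 - (r - w/2)^2]

with `lambda = n / A` and the translation edge-correction weight
`e_ij = A / ((Wx - |dx_ij|) (Wy - |dy_ij|))`, which is exact in closed
form on rectangles.  Under complete spatial randomness (CSR) the
expectation is ~1 at every `r`; values above 1 indicate aggregation at
that scale, below 1 regularity.  A kernel mode (Epanechnikov, with a box
option that reproduces ring mode exactly) replaces the indicator for
smoother curves; it divides by `2 pi r` instead of the ring area.

**Bivariate `g12(r)`.**  The same estimator over ordered pairs with `i`
from pattern 1 and `j` from pattern 2, normalised by `lambda_2 * n_1`;
~1 under independence, above 1 positive association, below 1 negative.

**Survival probability by distance.**  For a live/dead marked pattern,
`P(r)` is the probability that a tree found at distance `r` from a
reference tree is alive: the ratio of edge-weighted live neighbours to
edge-weighted all neighbours in the ring, every tree excluded from its
own neighbourhood.  With the joined pattern as reference (the default)
this is algebraically `lambda_2 g_{a2}(r) / (lambda_a g_{aa}(r))`.  Under
random mortality it is flat at the overall live fraction; depressed
values at small `r` are the signature of density-dependent death.

### Estimator parameters

* `r` grid: default 0.5-50 m in 0.5 m steps.  Stand-scale interactions in
  these forests are read at metre resolution up to a few tens of metres,
  and `r_max` must stay below half the shorter window side (50 m in a
  1-ha plot) for ring areas and edge weights to behave.
* ring width `w`: default 1 m.  Rings are half-open `(r - w/2, r + w/2]`,
  so a distance tie at a ring boundary lands in exactly one ring and
  adjacent rings of width equal to the grid step partition distance.
* edge correction: `translation` (default) or `none`.  The `none` mode
  exists for oracle tests and for teaching; all analyses use translation.
* undefined values: where a data-dependent denominator is empty (the `P`
  statistic in sparse rings) the value is flagged undefined and
  propagated as missing, never reported as 0 — a 0 would masquerade as
  evidence of regularity in sparse plots.  `g` itself has a deterministic
  denominator and reports 0 for an empty ring, which is a genuine
  estimate.

## Null models and rank envelopes

Three Monte-Carlo null models cover the three questions:

* **CSR** (conditioned on the observed count) for the distribution of a
  single pattern;
* **independence** for the live-dead association: the default replaces
  both patterns by CSR, matching the way the reference band is usually
  drawn for these data; a toroidal-shift mode that preserves each
  pattern's internal structure is provided as the field-standard
  alternative (the choice is genuinely open — both are exposed, CSR-both
  is the default);
* **random labelling** for the random-mortality hypothesis: positions are
  fixed and exactly `n_dead` marks are reassigned uniformly without
  replacement.

Envelopes use 199 simulations with rank-5 bounds by default: at every
`r` the upper bound is the 5th-highest and the lower bound the 5th-lowest
simulated value, leaving the five extreme simulations outside on each
side — a pointwise two-sided level of `2*5/(199+1) = 0.05`.  The bounds
are exact order statistics (verified against a full sort in the tests).
Distances where a simulated statistic is undefined are dropped from the
ranking there, and a distance where more than half the simulations are
undefined is reported undefined.

Pointwise bands at many distances raise a simultaneous-inference caveat,
so `gof_rank_test()` reduces an envelope to one scalar — the summed
squared deviation from the simulation mean over a distance interval —
and ranks the observed deviation among the simulated ones; reusing the
same simulations keeps observed and simulated values exchangeable and the
p-value uniform under the null.

**A calibration subtlety.**  With small patterns the pair count in a
1 m ring has an atom at zero; when five or more of the 199 simulations
share the zero, the lower bound is pinned at the statistic's floor and
the lower-tail escape probability drops below its nominal 2.5%.
Measured coverage at `n = 50`, `r = 5` m is therefore slightly *above*
95% (about 96%), which the calibration experiment
(`envelope_coverage_experiment()`) reproduces; we run it with 1600 outer
replicates so its Monte-Carlo error (about 0.5 percentage points) is
small against the band it is read at.

**Random-labelling fast path.**  Under random labelling the locations
never change, so the edge-weighted ring degree of every tree is computed
once (`O(n^2)` in compiled code) and each relabelling reduces to a
mark-vector product, making 199 relabellings of a 7,600-stem plot a
matrix multiplication.  The fast path is tested for exact agreement with
the generic per-relabelling computation.

## Survival models and binomial median tests

Tree survival (live = 1; the `dying` vitality class counts as live — only
`dead` stems are dead) is modelled by logistic regression on height, DBH
and distance from the river.  With several plots and an identifiable
design a plot-level random intercept is added (Laplace approximation);
when a plot-constant covariate such as distance is included with four or
fewer plots, the random intercept is dropped with a note — so few groups
cannot support both a group effect and a group-level slope, and silently
fitting one would misstate the uncertainty.  Trees at or below breast
height (1.3 m) carry no DBH and are excluded from DBH models rather than
substituting basal diameter, which is a different measurement.  Complete
separation is detected and reported with ridge-penalised estimates and a
warning rather than divergent coefficients.

When one mark class is very small (tens of trees), a regression is
fragile; the binomial median test compares each live tree's size against
the *median* of the dead trees: `k` of `n` live values strictly above the
dead median, tested against Binomial(n, 1/2) with exact tail sums.  Ties
with the median are not successes and their count is reported.  The
two-sided rule doubles the smaller tail at `p0 = 0.5` (where it coincides
with the minimum-likelihood rule by symmetry) and sums all outcomes no
more likely than the observed one for `p0 != 0.5`.

## The synthetic stand generator

The generator produces the statistical structure the analyses assume,
with one preset per developmental stage.  Locations come from a Thomas
cluster process (Poisson parents, Poisson offspring, isotropic Gaussian
dispersal).  Toroidal wrapping is the default boundary treatment because
it preserves stationarity and keeps the intensity exactly `kappa * mu`,
which the tests rely on; an edge-discard mode (with parents laid in a
4-sigma buffer) is available.  Heights are drawn from a zero-truncated
normal whose *post-truncation* mean and sd equal the stated stand
moments — the parent parameters are solved numerically — because the
stand moments are what a census reports; naive truncation of a normal
with those parameters would inflate the mean of short-statured stands by
more than 10%.  DBH follows a monotone power law of height
(`1.2 h^1.5` cm at the median) with multiplicative log-normal noise,
assigned only above breast height.

The stage presets (1-ha window) are:

| stage    | live/ha | dead/ha | height (m)   | clustering           | mortality          |
|----------|---------|---------|--------------|----------------------|--------------------|
| juvenile | 5316    | 2277    | 1.1 +/- 0.8  | kappa 0.02, sigma 2  | density-dependent  |
| mature   | 186     | 30      | 9.7 +/- 4.23 | kappa 0.003, sigma 3 | random             |
| dying    | 22      | 165     | 2.4 +/- 2.2  | kappa 0.003, sigma 3 | random             |
| dead     | 0       | 194     | 1.6 +/- 1.5  | kappa 0.003, sigma 3 | random             |

Density-dependent mortality marks trees with
`logit(death) = a + 0.3 * (neighbours within 2 m)`, the intercept solved
so the expected dead share matches the preset; random mortality is a
uniform draw.  The juvenile stage is the one with crowding-driven death,
so the pipeline's detections are exercised in both directions: the
mortality test should fire at small scales on juvenile stands and stay
quiet on the others.  The height moments are treated as pooled over live
and dead stems.  In the default fixed-count mode the live/dead counts are
hit exactly (the cluster process is conditioned on its total by assigning
the fixed number of offspring to Poisson-drawn parents uniformly; deaths
are a probability-weighted sample without replacement), which makes
count-based checks sharp; a Poisson mode gives fully random counts.
Stress classes among live trees (healthy to dying) are assigned by a
height-linked latent score with stage-specific shares; they are cosmetic
for summaries and never used by inference.

One global seed expands into per-component child seeds through a fixed
affine map modulo the largest 32-bit prime (`child_seed()`), so partial
reruns reuse identical streams.

**What the generator does not emulate:** environmental heterogeneity
(gradients in groundwater within a plot — all presets are stationary),
temporal succession (each plot is a static snapshot), measurement error
in coordinates beyond the 0.1 m recording resolution, and any dependence
of mortality on unmeasured covariates.  Passing tests on synthetic
stands therefore show the chain detects the mechanisms it was built to
detect under stationarity; they cannot show robustness to inhomogeneous
intensity, which the estimators deliberately do not model (the analyses
assume homogeneous environments, and no inhomogeneous intensity
estimation is implemented).

## Numerical and design choices

* Coordinates are snapped to 0.1 m, heights to 0.01 m and diameters to
  0.1 cm at construction, so the CSV writer/reader round trip is exact
  and repeated writes are byte-stable.
* Fallen logs and stumps enter the dead pattern at their trunk-base
  coordinates; stumps carry basal diameter, not DBH.  The dead point
  pattern therefore includes all dead stems by default.
* The `P(r)` statistic's reference pattern is the joined pattern by
  default (live and dead alternatives are exposed via `reference`); the
  joined reference is the one for which the statistic reduces to the
  cross-to-joined pcf ratio.
* Envelope bounds exclude the observed statistic from the ranking (the
  bounds are order statistics of the simulations alone).
* Logistic fits use IRLS to convergence 1e-8; the ridge fallback
  penalises all non-intercept terms with `lambda = 1e-3`.
* Problem sizes in the package's own checks: envelope calibration at
  1600 outer replicates of `n = 50`; CSR unbiasedness over 500 replicates
  of `n = 200`; mortality-test power over 100 juvenile-preset stands;
  coefficient recovery over 50 stands of `n = 5000`.  These sizes put the
  Monte-Carlo error of each summary well inside the band it is read at.

## Known limitations

Rectangular windows only; no inhomogeneous, three-dimensional or
nearest-neighbour statistics; no survival-time (hazard) modelling; the
independence null's CSR-both default destroys within-pattern structure,
so its band answers "are the two patterns jointly random and unrelated"
rather than the sharper "are two structured patterns unrelated" (use the
toroidal mode for the latter); and the GoF scalar test aggregates over an
interval chosen by the analyst, which should be fixed before looking at
the envelope.
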