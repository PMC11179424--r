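---
title: "Measuring somatic CAG-repeat expansion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring somatic CAG-repeat expansion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepeatInstability)
```

## The measurement problem

Expanded CAG tracts in *HTT* are somatically unstable: in dividing and in
post-mitotic cells alike, the modal repeat length of a cell population
drifts upward over weeks. Fragment analysis measures this by PCR across
the repeat, capillary electrophoresis against a size standard, and peak
calling: each sample yields a distribution of fragment sizes whose shape
carries both the biology (the allele-length distribution) and two
instrument artifacts (PCR stutter and anomalous mobility of CAG-rich
fragments). This package turns such peak data into three quantities: the
**modal repeat**, the **modified instability index**, and per-condition
**expansion rates** with percent slowing relative to a non-targeting
control.

## From fragment size to repeat count

CAG-rich fragments migrate anomalously, so the apparent bp per repeat
unit is not 3 but an empirical constant; we model apparent size as a
linear map

$$\mathrm{size}_{bp} = \beta_0 + 2.724117\,r$$

with the slope fixed at the standard correction factor and the intercept
$\beta_0$ calibrated per run by anchoring the modal peak of a sample of
known genotype (`calibrateIntercept()`, e.g. a line carrying 125
uninterrupted CAGs). Treating the correction factor as the *slope* of a
calibrated affine map is an interpretive choice: a single constant can
only define a complete size-to-repeat transform together with an
intercept, and anchoring the intercept on a known sample absorbs any
difference between sizing algorithms (our piecewise-linear ladder
interpolation vs an instrument's Local Southern). Repeat assignment
rounds to the nearest integer; peaks rounding to the same repeat are
merged by summing heights before thresholding. A computed negative
repeat raises a calibration error rather than silently truncating.

## The modified instability index

Given retained peaks at repeats $r_i$ with proportional heights $m_i$
(normalized to $\sum_i m_i = 1$), the index relative to a reference
repeat is

$$II(\mathrm{ref}) = \sum_i m_i\,(r_i - \mathrm{ref}).$$

Two conventions matter and are fixed as follows:

* **Threshold (20% of modal height, inclusive).** Peaks with height
  $\ge 0.20 \times$ the modal height are retained; the modal peak itself
  always survives, and a peak exactly at the boundary is kept. The
  threshold suppresses stutter and baseline noise at the cost of
  compressing the tails of genuinely broad distributions.
* **Normalization after filtering.** Proportional heights are
  renormalized over the retained peaks only, so the index is invariant
  to uniform height scaling and to the discarded sub-threshold mass.
  Whether normalization precedes or follows thresholding is not
  standardized in the field; post-filter normalization is the cleaner
  reading of "proportional peak height ... for each peak in the
  distribution" once the distribution has been defined by the threshold,
  and it is the convention tested throughout.

Useful identities (both are enforced as property tests): the index is
invariant to scaling all heights, and shifting the reference by $k$
shifts the index by exactly $k$, so baseline-relative index *changes* do
not depend on the reference at all. Modal ties break toward the smaller
repeat — conservative against calling spurious expansion.

## The generative model behind the simulator

The paper-grade experiments this package is built to analyze provide no
raw data to test against, so the package carries its own ground truth: a
seeded simulator whose statistical structure matches what the analysis
assumes.

* **Expansion.** Each of `nAlleles` alleles starts at `initialRepeat`
  (default 125) and, over an interval $\Delta t$, gains
  $\mathrm{Poisson}(g\,m\,\Delta t\,(1 + c(L - L_0)))$ and loses
  $\mathrm{Poisson}(\ell\,\Delta t\,(1 + c(L - L_0)))$ repeat units
  ($g$ = `gainRate`/day, $m$ = condition `rateMultiplier`, $\ell$ =
  `lossRate`, $c$ = `lengthDependence`). With $c = \ell = 0$ the gain
  after time $t$ is exactly Poisson with mean $g\,m\,t$ — a closed form
  the tests exploit. The walk is a modelling choice made for
  tractability; it reproduces the unimodal, upward-drifting
  distributions seen in cultured HD models but is not a mechanistic MMR
  model.
* **Stutter.** PCR slippage is modelled as downward-only geometric decay:
  an allele at $L$ contributes mass $\rho^k$ at $L - k$,
  $k = 0..$`stutterOrders`, with `stutterRatio` $\rho = 0.15$ by default
  (upward stutter is negligible at long CAG tracts). Stutter conserves
  mass and never exceeds the longest true allele.
* **Traces.** Peaks become Gaussian kernels (width `traceSigmaBp`,
  default 0.7 bp) on a scan axis at 10 scans/bp, plus optional baseline
  noise and a spike ladder channel, so the peak-detection and sizing code
  can be tested by strict round trip: with zero noise and
  $\rho < 0.5$, synthesize → detect → size → repeat-call returns the true
  modal repeat exactly.
* **Study layout.** `simulateStudy()` adds the design layer: conditions
  with rate multipliers, replicate cultures, pools, timepoints, and a
  lognormal per-culture rate factor (mean 1, CV `replicateRateCv` = 0.15)
  representing biological variability between parallel cultures — without
  it, replicate slopes would be nearly identical and any replicate-based
  CI degenerate. Pool labels are recorded but carry no extra variance
  component: with only two pools per condition a pool-level effect cannot
  be estimated at this design size, and injecting one would correlate
  replicate slopes in a way the replicate-level standard error cannot
  see.

Two presets encode calibrated control behaviour: `"iPSC-control"`
(gain 0.0625 repeats/day, i.e. ~5 modal CAGs per 80 days of passaging)
and `"MSN-control"` (gain 0.2352 repeats/week, calibrated numerically so
the *fitted* index slope through the stutter + threshold chain is
~0.20 units/week). These are calibration targets for the simulator, not
reproductions of any instrument dataset.

What the simulator does **not** emulate: baseline distribution width
(real cultures start broad; simulated baselines are a single repeat
length, which makes the early index trajectory slightly convex),
interrupted repeats, contraction-biased dynamics, height-dependent
instrument saturation, and dye or crosstalk artifacts. Passing tests
therefore demonstrate correctness of the computation and calibrated
statistical behaviour under this model — not instrument fidelity.

## Rate estimation and percent slowing

Within each replicate culture, metrics are first expressed relative to
the replicate's designated baseline timepoint (baseline rows become
exactly 0), and the replicate slope is the through-origin OLS fit of the
delta against time since baseline — the regression is forced through the
baseline because the response is defined as change from it. Replicates
with fewer than three timepoints are excluded with a warning.

The primary condition-level estimator is **two-stage**: the condition
slope is the mean of its replicate slopes, with SE $= s/\sqrt{n}$ and a
$t_{n-1}$ CI. For balanced designs this coincides with the fixed-effect
slope of a random-slope linear mixed model; `method = "mixed"` fits that
model (`lme4`, per condition, random slope by replicate) and the two
agree within 2% on balanced simulated data — the pair brackets the
plausible analyses without depending on one fitting engine. Time units
(days for dividing cultures, weeks for neuronal cultures) travel with
the sample sheet and label the slopes.

**Percent slowing** of condition $j$ is
$100\,(1 - \hat\beta_j/\hat\beta_{ctrl})$, defined only when the control
slope is positive. Its CI uses **Fieller's theorem** on the slope ratio
(df $= n_j + n_{ctrl} - 2$): with only a handful of replicates the
delta-method interval for a ratio is anticonservative because it ignores
the curvature of $1/\hat\beta_{ctrl}$, so Fieller is the only interval
reported. When the control slope is not significantly nonzero
at the 5% level the Fieller set is unbounded and the CI is reported as
NA.

Pairwise condition differences use Tukey's HSD on the replicate slopes
(`stats::TukeyHSD` on a one-way layout), which controls the family-wise
error near 5% — verified by all-control null simulations. With exactly
two conditions the Tukey p equals the pooled-variance t-test p. The
degenerate all-identical-slopes case (zero residual variance) is defined
to give p = 1.

## Numerical conventions and degenerate inputs

* Peak detection reports plateau maxima at their leftmost scan; of two
  candidate maxima closer than the minimum spacing the taller wins, an
  exact height tie going to the earlier scan. Traces shorter than 3
  samples are rejected.
* Ladder sizing requires ≥2 ladder points; peaks outside the ladder span
  are excluded with a warning, never extrapolated.
* Peak tables reject non-positive heights/sizes and duplicate sizes
  within 0.1 bp; CSV round trips preserve values to 6 decimals.
* All simulation randomness flows from a single integer seed; identical
  seeds give byte-identical study outputs.

## Problem sizes used in the test suite

The package's statistical guarantees are exercised at sizes chosen to
make Monte-Carlo error small relative to the tested margins while keeping
the default suite fast: oracle equivalence on 1,000 randomized peak
tables (tolerance 1e-9); Poisson-moment checks at $10^4$ alleles;
preset calibration over 100 seeded runs; closed-loop slowing recovery
(rate ratio 0.35, 4 replicates, 5 timepoints, 2 pools) over 100
repetitions with ≥90% CI coverage of the configured 65%; and family-wise
null behaviour over 200 repetitions.

## Known limitations

The modal-repeat metric is integer-valued; at low expansion rates (an
expected gain below ~1 repeat over a study) its fitted slope is dominated
by discreteness and percent slowing computed from it saturates — the
index metric is the better-behaved readout there. The index under a
delta-function baseline under-responds early in a time course (threshold
compression), biasing fitted slope ratios a few percentage points; with
realistic replicate variability this bias is well inside the CI. The
simulator's variance structure beyond the Poisson walk (replicate-level
CV) is a modelling choice, not a measured quantity.
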