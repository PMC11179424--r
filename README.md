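# RepeatInstability

Quantification of somatic CAG-repeat expansion from capillary
fragment-analysis data, for labs measuring repeat instability in cell
models of Huntington disease (HD) and other repeat-expansion disorders.
The pathogenic *HTT* CAG tract keeps expanding in somatic cells; the speed
of that expansion — and how much a perturbation such as a mismatch-repair
(MMR) gene knockdown slows it — is the readout this package computes.

## What it computes

Starting from GeneMapper-style peak tables (fragment size in bp, peak
height) or raw electropherogram traces plus a size-standard ladder:

1. **Sizing and repeat calling.** Peaks are detected as local maxima,
   sized by piecewise-linear interpolation against the ladder, and mapped
   to integer CAG counts through a calibrated linear map
   `size_bp = intercept + 2.724117 × repeats`
   (the slope is the standard empirical correction for the anomalous
   mobility of CAG tracts; the intercept is anchored on a sample of known
   modal repeat, e.g. a 125-CAG line).
2. **Modal repeat and modified instability index.** Peaks below 20% of
   the modal peak height are discarded (inclusive threshold); retained
   heights are renormalized to proportional masses *m&#8321;…m&#8342;*, and

   &nbsp;&nbsp;&nbsp;&nbsp;II(ref) = Σᵢ mᵢ (rᵢ − ref)

   the height-weighted mean deviation of repeat lengths *rᵢ* from a
   reference repeat — "modified" because the reference is the control
   (baseline) modal repeat rather than the sample's own mode.
3. **Time-course rates.** For replicate cultures sampled over weeks, the
   per-replicate slope of the baseline-relative metric vs time
   (through-origin OLS), condition rates as the mean of replicate slopes
   with t-based CIs (a random-slope mixed model is available as an
   alternative backend), **percent slowing** of each knockdown arm,
   100 × (1 − slope/control slope) with a Fieller CI, and Tukey-adjusted
   pairwise contrasts.
4. **Simulation.** A seeded generative model — a length-dependent Poisson
   gain/loss walk per allele, downward geometric PCR stutter, Gaussian
   peak kernels plus baseline noise — so the entire pipeline can be
   validated end to end against known ground truth.

## Worked example

Simulate an 80-day dividing-culture study (4 replicate cultures per arm,
fragment analysis every 20 days) in which an MSH3 knockdown arm expands at
0.35× the control rate, then analyze it blind:

```r
library(RepeatInstability)

run <- simulateStudy(SimConfig(nAlleles = 2000),
                     conditions = c(NTC = 1, MSH3 = 0.35),
                     times = seq(0, 80, 20), seed = 42)
ans <- analyzeStudy(run$peakTables, run$sheet)
ans$rates$instability_index
#>   condition            metric n_replicates  slope      se  ci_lo  ci_hi
#> 1      MSH3 instability_index            4 0.0176 0.00138 0.0132 0.0220
#> 2       NTC instability_index            4 0.0546 0.00582 0.0360 0.0731
#>   percent_slowing slowing_ci_lo slowing_ci_hi time_unit
#> 1            67.8          54.3          76.5      days
#> 2             0.0            NA            NA      days
ans$contrasts$instability_index
#>       pair difference  ci_lo  ci_hi    p_adj significant
#> 1 NTC-MSH3      0.037 0.0223 0.0516 0.000826        TRUE
```

The control arm gains ~0.055 index units/day; the knockdown arm is slowed
by 67.8% (95% CI 54–77%, covering the configured 65%), and the Tukey
contrast is significant. `analyzeStudy` logged that the sizing intercept
was re-calibrated from the control baseline sample and that 284 of 442
peaks fell below the 20% modal-height threshold.

Single samples work too: `summarizeSample(peakTable, map, AnalysisConfig())`
returns the modal repeat, index and retained-peak count, and
`inst/scripts/repeat-instability.R` exposes `simulate`, `analyze` and
`index` subcommands for shell use.

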