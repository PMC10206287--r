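---
title: "Peak evaluation and mobile-phase scoring: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak evaluation and mobile-phase scoring: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromeval)
```

`chromeval` turns raw LC-MS runs into validated, quality-scored
chromatographic peaks. This vignette explains the models behind each stage,
the parameters that matter (with units and defaults), the choices we made
where the design was genuinely open, and what the synthetic test bed does
and does not demonstrate about real data.

## 1. EIC extraction

An extracted ion chromatogram is the per-scan sum of all intensities within
`target_mz ± tol`, where a ppm tolerance is converted to Th at the target
m/z (`io$mz_tol = 10` ppm by default, configurable globally or per
analyte). We sum — rather than take the maximum of — the in-window signal,
so profile and centroid data are treated identically and no peak picking in
the m/z dimension is attempted. Scans with no in-window ions contribute
zero instead of being dropped: downstream smoothing assumes a uniform RT
grid. Retention time is minutes everywhere; files recording seconds are
converted at read time. Reading goes through `mzR`, so both mzML and mzXML
dialects behave identically (a property the test suite checks by writing
the same synthetic run in both dialects).

## 2. Baseline correction

"IRLS baseline correction" names a family rather than a single algorithm;
we use asymmetric penalized least squares with IRLS weight updates, the
standard chromatography formulation: the baseline $z$ minimizes

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2,$$

with $w_i = p$ where $y_i > z_i$ (signal above the fit: peaks) and
$1 - p$ below, iterated to a fixed point (relative change
`< irls_tol = 1e-6`, cap `irls_max_iter = 50`). The corrected trace is
`max(y - z, 0)`: the metrics (MCQ, Std/Blk) assume non-negative signal.

Defaults are $\lambda = 10^7$, $p = 0.001$. We calibrated these on
noiseless synthetic scenes with known baselines: on a 10^4-count Gaussian
peak over a linear drift (mean 100 counts, 0.02 min sampling), the
recovered baseline's RMS error outside ±3σ of the apex is 0.8 counts with
these values, versus 19 counts with the softer
$\lambda = 10^5, p = 0.01$ often quoted for shorter traces — a soft
baseline bulges into the peak and truncates tails, biasing asymmetry and
FWHM. Stiffness is safe here because chromatographic baselines are locally
smooth (second differences near zero for linear drift, small for slow
exponential wash-off), while the asymmetry $p$ keeps peaks from pulling
the fit upward. Re-running the correction on an already-corrected trace
changes it by under 0.1% of the maximum intensity, so the operation is
idempotent for practical purposes; exact idempotence is impossible for any
$p > 0$, since the refit always assigns the peak region a small positive
baseline.

## 3. Smoothing

Savitzky–Golay with `sg_window = 11` points, `sg_order = 3` — typical for
LC peaks sampled at ≥ 1 Hz, exact on polynomials up to the filter order,
and area-conserving to within 1% on interior peaks. Edge points are handled
by the filter's startup/end transients, which refit the polynomial to the
truncated half-windows; this is deterministic and length-preserving. The
pipeline order is fixed: baseline first, then smoothing, then clipping at
zero.

## 4. Peak detection and selection

Apexes are strict local maxima at or above `min_rel_height = 0.01` of the
global maximum (plateaus count once, at their first point). Boundaries walk
outward to the nearest local minimum or to `boundary_frac = 0.01` of the
apex, whichever comes first; regions under `min_points = 5` samples are
dropped. Detection is deliberately permissive — quality control is the job
of the metric thresholds, not the detector — and is scale-invariant because
both thresholds are relative. One peak per analyte is reported (highest
apex inside the analyte's RT window, ties to the earlier RT), because a
reference library records a single retention time per metabolite.

## 5. The eight metrics

* **MCQ** follows the CODA construction: the raw (baseline-corrected,
  unsmoothed) trace scaled to unit length is compared against its 3-point
  moving average standardized to zero mean and unit variance;
  `MCQ = Σ x̂ŷ / √(m−1)`, clipped to [0, 1], and defined as 0 for constant
  traces. The 3-point window is fixed independently of the preprocessing
  smoother so MCQ measures residual raggedness, not the smoother. With this
  window, *zero-mean* white noise scores ≈ 1/√3; real noise traces are
  non-negative intensities whose mean offset drives MCQ well below 0.5.
* **Asymmetry** is measured at 10% of apex height — the chromatographic
  asymmetry-factor convention, not the 5% USP tailing factor — with
  crossings located by linear interpolation between samples. If a crossing
  falls outside the detected region (e.g. overlapping neighbours), the
  metric is undefined rather than extrapolated.
* **FWHM** uses the same crossing machinery at 50%.
* **Jaggedness** counts sign changes in the region's first differences,
  ignoring zeros; the single rise→fall change of an ideal peak is
  subtracted, and the count is normalized by the number of differences.
* **Modality** finds the deepest interior dip — the lower flanking local
  maximum minus the interior minimum — relative to apex height.
* **Std/Blk** compares the sample apex to the blank channel's *local*
  maximum within ±0.5 min (`metrics$blank_rt_halfwindow`), not the blank's
  global maximum: co-eluting background is what actually confounds
  identification. The blank level is floored at `blank_epsilon = 1` count,
  so a silent blank gives a large but finite ratio.
* **RSD of RT** is the sample statistic `100·sd/mean` over replicate apex
  RTs, undefined below two replicates.

Undefined metrics are `NA`, never zero, and every rule that references an
undefined metric fails closed — an analyte without a blank channel cannot
validate unless the user disables the Std/Blk rule explicitly.

## 6. Mobile-phase scoring (Sp + Saf)

Validation per phase uses `phase$intensity_min = 1000` counts and
`phase$mcq_min = 0.5` (inclusive comparisons). `Sp` is the ascending rank
of validated-peak counts, ties sharing the minimum rank of the block. For
`Saf`, the asymmetry factors of the *commonly* validated analytes are
compared across phases by classic equal-variance one-way ANOVA; only when
`p < alpha` (default 0.05) does `Saf` rank separation quality, operated as
distance of the mean asymmetry from 1 (an ideal symmetric peak), closest
ranking highest. Otherwise — non-significant ANOVA, an empty common set,
fewer than two common peaks, or a degenerate F statistic — every phase
receives `Saf = 1`: the asymmetry rank should never fire on insufficient
evidence. A `lowest_mean` alternative (`phase$saf_criterion`) is provided
for labs that prefer penalizing tailing only, since fronting peaks
(asymmetry < 1) are then rewarded rather than penalized.

The published scheme shows only two phases; the n-phase generalization
(ascending min-ranks, all-get-1 Saf when not significant, best = highest
total with ties broken by more validated peaks then lexicographic id) is
ours, chosen so the two-phase case reproduces the published example
exactly: 4 vs 10 validated peaks with a non-significant ANOVA scores
Sp 1/2, Saf 1/1, and the 10-peak phase wins with total 3.

## 7. Library validation (r/c/I)

Aggregation across replicates: arithmetic means for intensity, Std/Blk and
the morphology metrics (an `NA` in any replicate propagates — fail-closed),
and `rsd_rt` computed from the per-replicate apex RTs. An entry validates
iff mean Std/Blk ≥ `r` (6), RT RSD ≤ `c` (15%), mean apex intensity ≥ `I`
(1000), and a peak was found in *every* replicate; `fail_reasons`
enumerates all violated rules. Comparisons are inclusive at the boundary;
the reference dropout values (4.719 < 6, 915.368 < 1000) are strict on
either convention. Whether Std/Blk should be averaged or required
per-replicate is not settled practice; we average, which is the more
forgiving choice and keeps the rule monotone in `r`. Matching across
replicates is by analyte identity — each EIC belongs to one analyte — not
by RT clustering, consistent with a standards-mixture workflow.

## 8. The synthetic test bed

The generator emulates what the validation logic must discriminate:
Gaussian and exponentially modified Gaussian peaks (EMG tailing `tau` in
minutes; `tau = 0` recovers the Gaussian exactly), additive linear and
exponential baseline drift, additive Gaussian white noise, seeded
replicate-to-replicate RT jitter, and a blank channel carrying a chosen
fraction of the peak signal. The EMG is evaluated in a numerically stable
split form (scaled complementary error function on the leading flank, the
exponential-decay form on the trailing flank). Everything is seeded and
bit-reproducible, and the run writers emit minimal standards-conformant
mzML/mzXML that round-trips through `mzR`.

It does **not** emulate: Poisson/heteroscedastic detector noise, m/z
dimension structure (isotopes, adducts, chimeric spectra), co-eluting
interferences, column aging or drift between phases. Passing tests
therefore demonstrate the correctness of the computations and decision
rules, not instrument-level robustness.

Problem sizes in the shipped tests were chosen to exercise the code at
desk scale: EICs of 200–1000 points, a 20-analyte/3-replicate/1-blank
library study on a 0.02-min grid, 1000-case randomized checks of the
ranking and validation rules, and 200 replicates for the jitter
calibration check. Parameter-recovery tests use a 0.005-min grid because
the asymmetry factor is a ratio of interpolated crossing distances: on
coarser grids its error is dominated by apex quantization (one grid step
propagated through the quotient), not by the pipeline.

## 9. Known limitations

Overlapping peaks are not deconvolved; the detector assigns the shared
valley to whichever side the walk-down reaches first, and severely fused
peaks surface as high modality rather than as two entries. Asymmetry and
FWHM become undefined (not extrapolated) when their crossings leave the
detected region. The Std/Blk rule needs a blank run; without one it fails
closed. The CLI's `synth` scene format covers single-analyte-per-channel
studies only.
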