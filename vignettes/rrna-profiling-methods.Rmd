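---
title: "rRNA profiling for ovary staging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rRNA profiling for ovary staging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnastage)
```

## The measurement model

An on-chip capillary electrophoresis run of total RNA produces a
fluorescence-vs-migration-time trace in which each RNA species appears as a
peak. Fish oocytes in the primary growth stage stockpile 5S rRNA; as a
result the 5S peak dominates the trace in immature ovaries (up to ~99% of
total signal) and shrinks through vitellogenesis while 18S grows toward
somatic levels (~30% of total). Three indexes summarize this:

$$\mathrm{pct5S} = 100\,\frac{a_{5S}}{a_{tot}},\qquad
  \mathrm{pct18S} = 100\,\frac{a_{18S}}{a_{tot}},\qquad
  \ln\frac{a_{5S}}{a_{18S}},$$

where $a$ are *time-corrected* peak areas (raw integrated area divided by
apex migration time — later-eluting fragments move slower past the
detector, so raw areas grow with elution time; the division removes that).
Because all three indexes are area ratios, they are invariant to the
fluorescence scale and to RNA loading, which is what makes them comparable
across samples.

### Trace processing

* **Calibration.** Apparent size is close to log-linear in migration time
  in gel electrophoresis, so the ladder calibration interpolates
  $\log(\text{size})$ against time with a monotone (Hyman-filtered)
  piecewise cubic. It is exact at the anchors, strictly increasing, and
  flags queries outside the anchored range.
* **Baseline.** The baseline is estimated from off-peak points only: points
  above `median + 3·MAD-noise` (noise estimated from first differences) are
  masked as peak territory, the mask is widened by a 1 s guard so
  sub-threshold peak flanks do not leak in, and the remaining signal is
  interpolated across the gaps and smoothed (default window 5 s). A
  lower-envelope estimator (rolling minimum) was considered and rejected:
  the minimum of $n$ noise samples is biased low by roughly $2.5\sigma$,
  which inflates every integrated area by a constant offset and corrupts
  the smallest peaks worst — recovering a 0.1% 5S fraction showed ~20%
  relative error under a rolling-minimum baseline versus <2% under the
  masked estimator. The masked estimator is unbiased under pure mean-zero
  noise, exactly offset-invariant, and positively homogeneous.
* **Peaks.** Apexes are local maxima of a lightly smoothed copy (0.2 s)
  with topographic prominence above `min_prominence` (default 5
  fluorescence units, far above residual noise yet far below any real RNA
  peak in the synthetic regime); the smoothed signal is used only to locate
  features, never to integrate. Boundaries are valley-to-valley: the
  minimum between adjacent retained apexes. Integration is trapezoidal on
  the unsmoothed corrected signal. Apex times are refined to sub-grid
  precision by log-parabolic interpolation (exact for a Gaussian peak), so
  time-corrected areas do not inherit grid quantization error.
* **Detection limit.** A time-corrected area below 0.2 is below the
  instrument's detection limit. When the 5S or 18S area is below the limit
  it is replaced by half the limit (0.1) and flagged, rather than set to 0:
  the ratio and log transforms must stay defined, and the substitution is
  reported so downstream fits can inspect the affected samples. The
  substitution value itself is a convention (the half-limit rule common in
  below-detection handling); only its order of magnitude matters, and the
  flag travels with the profile.
* **Totals.** "Total RNA" is, by default, the sum of all non-marker peak
  areas (`peak_sum`), which is exactly testable against the generator's
  ground truth; a whole-region integral can be supplied instead
  (`region_integral`) for traces with appreciable inter-peak signal. The
  lower marker (earliest peak under 30 nt apparent size) is always removed
  before any total.

### Species assignment

The small RNAs are assigned by fixed apparent-size windows (tRNA 99–110 nt,
5S 131–144 nt, 5.8S 164–168 nt) — apparent sizes deviate from true lengths
but do so reproducibly. The large ribosomal RNAs drift between chips, so
among peaks above 1000 nt the two largest by area are taken as the major
subunit peaks and labeled 18S/28S in size order rather than by windows.

## Standard curves and the 10-point score

The staging regressions are fit in the direction the relationship is
established: the index is the response, maturity (GSI, or PGOO% from
histology) the regressor. Seven families are compared — linear,
logarithmic, quadratic, cubic, power, exponential, sqrt-linear — each by
ordinary least squares on its transformed design (power and exponential on
$\log y$, with fit statistics reported on that scale, as curve-estimation
tools conventionally do).

**Selection.** Raw $R^2$ is monotone under polynomial nesting, so "highest
$R^2$" would always pick the cubic. The selector therefore (i) lets the
polynomial chain be represented by the highest order whose top coefficient
is significant at the 5% level, then (ii) compares that representative with
the non-nested families by adjusted $R^2$, breaking residual ties toward
fewer coefficients. On cohorts generated from a linear model this recovers
"linear" at roughly the rate the 5% type-I error of the top-term test
allows, and a genuine quadratic (e.g. a 0.90 → 0.947 jump in $R^2$) is
promoted.

**Prediction** inverts the selected curve at a measured index value —
analytically for the monotone families, by bracketing and `uniroot` on the
observed maturity range for the quadratic/cubic. A non-monotone curve can
return several admissible maturities; all branches are reported with a
flag, since external information (sampling month) is the right
disambiguator, not the curve. The prediction interval comes from the delta
method: the standard error of the estimate $s$ divided by the local slope
of the forward curve (mapped through $f'/f$ when the fit lives on
$\log y$). Predicted maturity is also reported as a 10-point score,
$10\,(g - g_{\min})/(g_{\max} - g_{\min})$ clipped to $[0, 10]$, anchored
to the cohort's observed GSI range — the anchors are stored in the curve
artifact so scores are comparable across runs of the same cohort.

## Sex calling

Within an applicability regime the female and male distributions of a 5S
index are disjoint, so the natural classifier is a margin rule, not a
probabilistic model: the threshold is the midpoint of the gap between the
class ranges, the margin is the gap width, and confidence is distance to
the threshold in margin units (capped at 1). When the classes overlap the
best-separating cutpoint is found by exhaustive scan, the margin is 0, and
the records inside the overlap are enumerated. Applicability regimes are
configuration, not inference: they encode the empirical observations that
the 18S index separates sexes only in early development (GSI < 4) and that
in synchronous spawners the 5S indexes stop separating in the last months
before spawning (the presets gate months 5–11 for a March spawner).

## The synthetic-data generator

The generator exists so that every pipeline stage can be verified against
known ground truth; its defaults define the conditions all tests run under.

* **Traces.** Gaussian peaks (SD 0.25 s) on a 38–124 s grid sampled at
  0.02 s, a synthetic log-linear time-to-size map (25 nt at 40 s, 6000 nt
  at 120 s), a lower marker of fixed area, time-corrected areas exactly
  proportional to the requested composition (total 300 area units), and
  additive Gaussian baseline noise (SD 0.5). At these settings the smallest
  composition exercised by the tests (0.1% of total) still has peak
  amplitude ~30× the noise SD, which reflects how clean intact-RNA chip
  runs are; trapezoidal integration on this grid is exponentially accurate
  for Gaussian peaks, so integration error is dominated by baseline
  uncertainty, not discretization.
* **Cohorts.** Each index follows its stated regression model in GSI plus
  Gaussian noise on the analysis (transformed) scale — the distributional
  form is an assumption, recorded as such. Noise is truncated at 3.5 SD:
  the sex-calling claim is about *disjoint* distributions, and an unbounded
  tail crosses any finite gap eventually, so bounded supports implement the
  claimed regime honestly rather than passing tests by luck. The
  synchronous preset uses a steep log-linear 5S decline (intercept
  $\ln 5S\% = 4.55$, slope $-0.154$ per GSI unit over GSI 0.3–25) with
  quadratic $\ln(5S/18S)$ and 18S%; the asynchronous preset uses gentle
  linear declines (5S slope $-0.16$ over GSI 0.5–8) because asynchronous
  ovaries retain primary-growth oocytes at every stage — which is also why
  its sexes stay separable throughout the cycle and why its staging
  regressions are intrinsically weaker. Males sit at flat somatic-like
  levels (5S ≈ 1.7% of total). Two consequences are documented rather than
  patched: the log-linear Gaussian model can occasionally generate
  pct5S slightly above 100 at the immature extreme, and the three indexes
  are generated marginally (one model each), so the exact identity
  $\ln(\text{ratio}) = \ln(\text{pct5S}) - \ln(\text{pct18S})$ holds for
  profiles computed from traces but not for cohort tables.
* **Oocytes.** Long axes are drawn from two uniform components (0.40–0.95
  and 1.10–1.80 × the critical size), short axes at 0.6–0.9 of the long
  axis, and the component split is chosen by a deterministic monotone
  search over the drawn volumes so the achieved PGOO% lands within about
  two percentage points of the target for any seed. Tables carry 4 cuttings
  over 2 slices.

What the generator does **not** emulate: RNA degradation smears, baseline
drift or air spikes, chip-to-chip sizing drift of the large subunits,
heteroscedastic index noise near physical bounds, and sampling designs
other than uniform GSI. Tests passing on this generator therefore validate
the pipeline's arithmetic, calibration, selection and inversion logic —
not robustness to degraded field data.

## Numerical choices

* Index-consistency checks between the 5S indexes are asserted on the log
  scale the analyses use: on raw scales the 5S/18S ratio spans three
  decades and Pearson correlation is dominated by its extremes (the
  structural ceiling is ~0.87 for the synchronous preset even at zero
  noise), while the log-scale correlation sits at 0.96–0.99.
* The PGO boundary is strict (`long axis < critical size`); the critical
  size itself is counted as non-PGO.
* Oocytes are pooled across cuttings (no per-cutting averaging): pooling is
  the variance-minimizing aggregation when cuttings are exchangeable.
* Inversion tolerances: `uniroot` at `1e-10`; grid of 1024 cells for
  bracketing. Exact fits are detected at $R^2 \ge 1 - 10^{-12}$ and given
  p-value 0; a top polynomial term counts as present in an exact fit only
  if its coefficient is numerically nonzero (relative magnitude
  $> 10^{-8}$).
* Problem sizes in the test-suite and acceptance script — cohorts of
  60–100 fish, 20–100 traces per property, 200 seeds for coverage, 50
  seeds for held-out sex calling — were chosen as the smallest sizes at
  which the asserted statistical properties are stable.

## Known limitations

* The below-detection substitution (half the limit) is a convention; any
  analysis sensitive to it should consult the flags and treat affected
  samples as censored rather than measured.
* Whether tRNA and 5.8S belong in the "total RNA" denominator is exposed as
  `total_mode` rather than decided; both modes are defensible and the
  default (`peak_sum` over all non-marker peaks) is the testable one.
* The 10-point score is anchored to the *observed* cohort GSI range;
  cohorts that do not span the full reproductive cycle will compress the
  scale.
* Applicability regimes ship as presets for two species profiles;
  transferring them to other species requires re-establishing the regimes
  empirically, not just the thresholds.
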