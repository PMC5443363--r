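---
title: "BMI-for-age scoring, severe-obesity classification, and charting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BMI-for-age scoring, severe-obesity classification, and charting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(youthbmi)
```

## The scoring model

Pediatric BMI is strongly age- and sex-dependent, and its distribution is
right-skewed, so youth weight status is defined against a reference
population rather than by fixed cut-offs. `youthbmi` uses the LMS
(lambda–mu–sigma) representation of an age-varying distribution: at each
sex and age the reference supplies a Box-Cox power $L$, a median $M$
(kg/m²) and a coefficient of variation $S$, and a subject's BMI $x$ maps to

$$z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
  z = \frac{\ln(x/M)}{S} \quad (L = 0),$$

with percentile $\Phi(z)\cdot 100$. The $L = 0$ branch is the analytic
limit of the power branch; the package tests verify agreement at
$|L| = 10^{-8}$ to $10^{-6}$. The inverse transform
$M\,(1 + L S z)^{1/L}$ recovers the BMI at any percentile and underlies
both the percentile curves and the synthetic cohort generator. For
$1 + LSz \le 0$ the Box-Cox distribution is undefined; the package reports
a domain error rather than extrapolating. Z-scores are **not** truncated:
the whole point of the tool is the severe-obesity tail, and clipping would
distort exactly the region of interest. (Extremely large $|z|$ therefore
saturates the displayed percentile near 0 or 100; classification uses the
unrounded value.)

BMI as a percent of the 95th percentile,
$\mathrm{BMI}_{95} = 100\,x / P_{95}(\text{sex}, \text{age})$, is carried
alongside the percentile because percentiles compress near 100 and cannot
grade severe obesity.

## Weight-status classification

Six mutually exclusive categories are assigned: underweight
(percentile < 5), healthy weight (5 to <85), overweight (85 to <95), obese
class 1 (percentile ≥ 95 below class 2), severe obesity class 2
($120 \le \mathrm{BMI}_{95} < 140$ **or** $35.0 \le \mathrm{BMI} < 40.0$
kg/m²) and class 3 ($\mathrm{BMI}_{95} \ge 140$ **or**
$\mathrm{BMI} \ge 40.0$). Because the severe classes carry dual OR
criteria, the arms overlap; evaluating from most to least severe is the
only order under which every subject receives exactly one label (a subject
with BMI 36 but $\mathrm{BMI}_{95} = 118$ is class 2 by the absolute arm
even though the percentile arm alone would say class 1). All lower bounds
are inclusive, upper bounds exclusive. The classifier trusts its three
inputs independently and does not cross-check the percentile against the
percent-of-P95; both come from the same reference in the normal pipeline,
but users may legitimately feed externally computed values.

Exact boundary equality (a BMI of exactly 140% of P95) is honoured as
written — inclusive — but note that constructing such a subject through
floating-point multiplication and division can land an ulp either side of
the cut; the test-suite therefore probes boundaries with explicit values
and treats constructed boundary subjects with a $10^{-9}$ interior nudge.

## Reference tables and interpolation

A reference table holds per-sex rows of age in months with $L, M, S$,
validated on load: positive $M$ and $S$, ages within $[24, 240.5]$ months,
strictly increasing duplicate-free grids covering 24 through at least 240
months, both sexes present. Between grid knots the three parameters are
interpolated **linearly and independently in age**. This matches common
practice with half-month reference grids, is exact at knots, continuous,
and monotone between knots; the subject ages a cohort file carries (years,
converted as `age_months = age_y * 12` exactly) never require
extrapolation because rows outside 2 to <20 years are flagged
(`age_out_of_range`) and left unclassified instead of aborting the batch —
a batch tool must not fail on one bad row. No calendar arithmetic is done:
computing decimal age from dates of birth and assessment is the caller's
preprocessing step.

Percentile curves for charting are built by evaluating the inverse LMS
transform on a 0.5-month age grid (configurable). The severe-obesity
curves are defined — not fitted — as 1.2× and 1.4× the P95 curve, and the
tests assert those identities pointwise on the renderer's input data.

## Cohort files and the results file

The input schema is `ID`, `Sex` (F/M/female/male, case-insensitive),
`Age_y`, `Height_cm`, `Weight_kg`, optional `BMI`. Height and weight are
used preferentially; a supplied BMI is used only when either is missing,
and a supplied BMI disagreeing with the computed one by more than
0.1 kg/m² is flagged (`bmi_discrepancy`) without altering the result.
English units must be pre-converted with the exact factors
(×2.54 cm/inch, ÷2.20462 lbs/kg) exposed as converter functions.
Whole-number ages are flagged (`whole_number_age`) because self-reported
integer ages can misclassify young children; replicated IDs switch the
batch to longitudinal mode; one ID carrying two sexes is flagged
(`sex_conflict`) since a sex-specific reference makes such rows
uninterpretable. The results CSV preserves the input columns and appends
`BMI_kgm2`, `BMI_pct`, `BMI_z`, `BMI_95`, `Weight_status`, `QC_flags`.
Displayed precision is 2 decimals (4 for the z-score) — enough that
re-reading the file reproduces any classification decision boundary wider
than 0.01 — while the in-memory results keep full precision.

## Charts

Charts mimic the standard BMI-for-age layout: age 2–20 years on the x-axis
with integer ticks, BMI on the y-axis from 10 to a default ceiling of
60 kg/m² (raised from the usual ~27 so classes 2 and 3 are on-scale;
configurable per cohort). Cross-sectional charts draw one unjittered point
per subject; longitudinal charts draw one polyline with circular markers
per child, sorted by age, with a lone marker for single-visit children and
an error for duplicate ages within a child. Points above the ceiling are
clipped with a warning naming the count — never silently. Output is EPS or
PDF; both devices embed a creation timestamp, so re-runs are
content-identical rather than byte-identical. The renderer builds an
inspectable scene (points, trajectories, curve arrays) before any device
is opened, so tests assert on coordinates and curve identities rather than
parsing vector files. Longitudinal charts colour-code children by default
(`colour_by_id = FALSE` for monochrome); default file names follow the
`BMI_Graph_<sex>[_long].<ext>` family, without any tool-identifying
suffix, so a mixed-sex batch yields exactly two files per format.

## The synthetic reference and cohort generator

Nothing survey-derived is distributed. `synth_reference()` produces a
deterministic two-sex table on a 0.5-month grid whose shapes are chosen to
be physiologically plausible rather than numerically convenient: $M$ dips
to a nadir near the adiposity-rebound age (5–6 years) and rises to the
mid-20s kg/m² by age 20, $S$ grows with age within $[0.08, 0.16]$, and $L$
is negative (right skew) drifting further negative with age, within
$[-3, 1]$; the sexes differ slightly in level and rebound age.

`synth_cohort()` draws ages uniformly on $[2, 20)$ years, assigns each
subject a target category (uniform over the six by default), and inverts
the reference to place the BMI strictly interior to the target region with
margins of 0.5 percentile points, 0.5 percent-of-P95 and 0.1 kg/m² — so
the pipeline must recover the intended label for 100% of rows, and any
miss is a real defect, not boundary ambiguity. Interior sampling honours
*all* arms of a category: a percentile-band draw for
underweight/healthy/overweight is additionally capped below 35 kg/m²
(near age 20 the synthetic reference's upper bands cross that absolute
cut), class 2 falls back to its absolute-BMI arm where 1.2×P95 already
exceeds 40 kg/m², and the arm actually used is recorded in the ground
truth. Heights come from a sex-specific linear-in-age median with mild
noise and weights are back-solved from the controlled BMI, so the
height/weight columns reproduce it exactly. Longitudinal mode emits 2–5
visits per child spanning at most four years with the category held
constant. Boundary behaviour is deliberately *not* exercised by the
generator; hand-placed boundary values cover it separately.

What passing these tests shows — and does not show. The generator
guarantees schema-exact files, exact ground truth and interior placement;
it does not emulate real growth trajectories, measurement error,
digit-preference in self-reported heights, or survey sampling design. A
100% recovery rate therefore validates the scoring/classification
machinery, not robustness to real-world data quality, which is what the QC
flags are for.

## Problem sizes and numerical choices

The test-suite runs the classifier partition check on $10^5$ random points
plus a grid straddling every printed cutoff at $\pm 10^{-7}$; round-trip
identity (BMI → z → percentile → BMI) is asserted at $10^{-9}$ relative
tolerance over random LMS parameters with draws kept within the
well-conditioned body of the distribution ($|z| \lesssim 5$; nearer the
tails the normal CDF saturates in double precision and the round trip is
undefined); the normal CDF is cross-checked against adaptive quadrature of
the density at $10^{-6}$; capacity checks render a 4000-subject
cross-sectional chart and a 30-trajectory longitudinal chart to both EPS
and PDF, the scale of a large screening study. The whole suite completes
in well under a minute on a single CPU.

## Known limitations

* Ages outside 2 to <20 years are flagged, never extrapolated; WHO
  references, infant metrics, and weight-/height-for-age are out of scope.
* The percentile displayed saturates at extreme z; use `bmi_z` and
  `bmi_95` in the tails.
* Linear LMS interpolation is a modelling choice; references with coarse
  grids would be better served by the provider's own smoothed values.
* Modified/extended z-scores for very high BMI and
  biologically-implausible-value screening are not implemented; QC flags
  mark structural problems only.
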