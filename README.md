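# youthbmi

Weight status in children and adolescents (ages 2 to <20 years) is defined
relative to a sex- and age-specific reference population, not by fixed adult
BMI bands — and severe obesity, the fastest-growing and highest-risk end of
the distribution, needs cut points that ordinary growth charts do not draw.
`youthbmi` scores youth cohorts against an LMS (lambda–mu–sigma) BMI-for-age
reference, classifies each subject into one of six mutually exclusive
weight-status categories including severe obesity classes 2 and 3, and
renders cross-sectional or longitudinal BMI-for-age charts whose percentile
curves include the severe-obesity cut points. It is aimed at epidemiologists,
school- and community-screening programmes, intervention researchers, and
clinicians who need to score and visualise many children at once.

## The model

An LMS reference gives, for each sex and age, a Box-Cox power *L*, median
*M* (kg/m²) and coefficient of variation *S*. A subject's BMI
(*weight kg / (height m)²*) maps to a z-score

    z = ((BMI/M)^L − 1) / (L·S)    (L ≠ 0)
    z = ln(BMI/M) / S              (L = 0)

and to a percentile Φ(z)·100. The inverse transform
*M·(1 + L·S·z)^(1/L)* yields the BMI at any percentile; BMI as a percent of
the 95th percentile (BMI₉₅ = 100·BMI/P95) is the key severe-obesity metric.
The six categories are:

| category | criterion |
|---|---|
| underweight | percentile < 5 |
| healthy weight | 5 ≤ percentile < 85 |
| overweight | 85 ≤ percentile < 95 |
| obese class 1 | percentile ≥ 95, below class 2 |
| severe obesity class 2 | 120 ≤ BMI₉₅ < 140 **or** 35.0 ≤ BMI < 40.0 kg/m² |
| severe obesity class 3 | BMI₉₅ ≥ 140 **or** BMI ≥ 40.0 kg/m² |

The dual (OR) criteria overlap, so classification is evaluated most-severe
first; that is the only order that keeps the categories mutually exclusive.
Charts draw the P5/P50/P85/P95 curves plus the 120%-of-P95 and 140%-of-P95
severe-obesity curves, with a y-axis extending to 60 kg/m² by default.

The package ships no CDC/NCHS reference values: point `load_lms_reference()`
at your own copy of a reference file (CSV or spreadsheet with sex,
age-in-months, L, M, S columns). A clearly synthetic reference
(`synth_reference()`) with the same shape backs all examples and tests.

## Worked example

```r
library(youthbmi)
ref     <- synth_reference()   # substitute load_lms_reference("cdcref.csv")
cohort  <- read_cohort(system.file("extdata", "synthetic_cohort_example.csv",
                                   package = "youthbmi"))
results <- compute_results(cohort, ref)
results[, c("id", "sex", "age_y", "bmi_kgm2", "bmi_pct", "bmi_z", "bmi_95",
            "weight_status")]
```

```
      id    sex  age_y bmi_kgm2 bmi_pct bmi_z bmi_95          weight_status
1  S0001   male 18.273    32.43   95.91  1.74 102.61          obese class 1
2  S0002   male  3.484    28.66  100.00  4.45 151.32 severe obesity class 3
3  S0003 female 10.045    13.90    3.83 -1.77  66.60            underweight
4  S0004   male  8.986    19.31   91.68  1.38  96.25             overweight
5  S0005   male  2.132    20.07   97.99  2.05 104.48          obese class 1
...
10 S0010   male 14.191    30.74   99.39  2.51 123.77 severe obesity class 2
```

Each row carries the BMI actually used (computed from height/weight when
both are present, the supplied BMI otherwise — S0010 above came in as
BMI-only), its percentile and z-score under the reference, BMI as a percent
of the sex/age-specific 95th percentile, and the resulting category. Because
the categories are mutually exclusive, prevalences are obtained by adding
classes:

```r
prevalence_summary(results$weight_status)$aggregates
#>                          group n proportion
#> 1        obesity (classes 1-3) 5        0.5
#> 2 severe obesity (classes 2-3) 2        0.2
```

One call scores and charts a whole batch (mode is inferred: replicated IDs
mean longitudinal data):

```r
run_pipeline(cohort, ref, outdir = "out", formats = "pdf")
#> read 10 row(s); 0 flagged; mode: cross_sectional
#> wrote out/BMI_Graph_females.pdf
#> wrote out/BMI_Graph_males.pdf
```

which writes `BMI_Results.csv` plus one chart per sex
(`BMI_Graph_females.pdf`, `BMI_Graph_males.pdf`, with a `_long` suffix for
longitudinal batches). A command-line wrapper with `score`, `chart`, `run`
and `synth` subcommands is installed at
`system.file("cli", "youthbmi.R", package = "youthbmi")`.

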