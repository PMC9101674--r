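# hingefit

Biomarker threshold estimation via hinge regression, with
threshold-stratified survival analysis.

## What problem this solves

Serum 25-hydroxyvitamin D (25(OH)D) drives calcium absorption and
suppresses parathyroid hormone (PTH) — but only up to a point: both
biomarkers respond to rising 25(OH)D and then plateau. The 25(OH)D level
at which the plateau begins is an operational definition of vitamin D
*sufficiency*, and in a randomized supplementation trial it also defines
the subgroup in which treatment can plausibly improve outcomes such as
relapse-free survival (RFS).

`hingefit` estimates such thresholds from patient-level cohort data
(one row per patient: arm, 25(OH)D / calcium / PTH at baseline and year
1, survival time and event) and carries them through to survival
analysis. It is written for biostatisticians and trial analysts in the
tidyverse idiom: data frames in, tibbles out, `tidy()` / `glance()` /
`autoplot()` on every fitted object.

## The methods at its core

**MARS (multivariate adaptive regression splines), univariate.** The
biomarker is modelled as an intercept plus hinge functions
h(x − t) = max(0, x − t) and h(t − x) = max(0, t − x):

    y = β₀ + Σⱼ βⱼ · hⱼ(x; tⱼ) + ε

A greedy forward pass adds mirrored hinge pairs at the knot minimizing
the residual sum of squares; a backward pass prunes term by term, scored
by GCV = RSS / (n (1 − C/n)²); the model *size* is selected by 10-fold
cross-validation repeated (default) 100 times, choosing the size with
the smallest mean validation RSS. The fitted model is continuous and
piecewise-linear; its hinges are the candidate thresholds, the flattest
well-populated segment is the plateau, and `primary_hinge()` — the
plateau's left boundary — is the sufficiency threshold.

**Piecewise linear regression with intersection points.** For candidate
cuts c = 15, 16, …, 40 ng/mL, an OLS line is fitted on observations with
x ≤ c; the cut maximizing R² splits the data, the region above the cut
gets an independent second line, and the threshold is the intersection
x\* = (a₂ − a₁)/(b₁ − b₂) of the two lines, with a percentile-bootstrap
interval on the ordinate. Near-parallel segments are flagged rather than
trusted.

**Threshold-stratified survival.** Kaplan–Meier RFS at 5 years,
Nelson–Aalen cumulative hazards, Cox proportional-hazards fits (Efron
ties), and the three-covariate interaction model (arm, above-threshold
group, product term) testing whether the treatment effect differs across
strata.

**A calibrated synthetic cohort generator** (`cohort_spec()` /
`simulate_cohort()`) emulates a two-arm vitamin D trial — arm-specific
truncated-normal 25(OH)D, hinge-curve calcium and PTH responses with
noise calibrated to realistic model R², a 0.20 mg/dL treated-arm calcium
rise in deficient patients, and stratum-by-arm exponential relapse
hazards — so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(hingefit)

cohort <- simulate_cohort(cohort_spec(), seed = 42)   # 357 patients
m <- fit_mars(cohort, "x25ohd_y1", "pth_y1", repetitions = 20, seed = 42)
m
#> <mars_model> pth_y1 ~ hinges(x25ohd_y1)
#>   hinges (ng/mL): 27, 54.3
#>   segment slopes: -0.869, 0, 0.152
#>   R-squared 0.092 | CV-selected size 2 (k=10 folds x 20 reps)
round(c(primary_hinge(m), plateau_segment(m)$level, pre_hinge_slope(m)), 2)
#> [1] 27.00 20.80 -0.87
```

The generator's PTH response falls at −0.96 pg/mL per ng/mL up to a
hinge at 29 ng/mL and plateaus at 20.1 pg/mL; on this single simulated
cohort the fit recovers the hinge at 27 ng/mL, a plateau of 20.8 pg/mL
and a pre-hinge slope of −0.87 — threshold estimation at realistic noise
is approximately right per cohort and unbiased in the median across
cohorts (see the acceptance script below).

```r
pw <- piecewise_analysis(cohort, "x25ohd_y1", "pth_y1",
                         bootstrap_reps = 200, seed = 42)
pw
#> <piecewise_result> pth_y1 ~ x25ohd_y1
#>   segment limit (max R^2): 33; lower R^2 0.116, upper R^2 0.001
#>   lower slope -0.8049 (p=3.13e-06), upper slope 0.02833 (p=0.733)
#>   intersection at 27.8 ng/mL, 20.94 (95% CI 17.41-26.13)
#>   second threshold attempt: cut 40, intersection 39.46, reliable
```

The two independently fitted lines cross at 27.8 ng/mL — the classical
construction agrees with MARS. Stratifying survival by the thresholds
17 and 29 ng/mL:

```r
sc <- stratified_comparison(cohort, c(17, 29))
tidy(sc)[, c("label", "n", "rfs_placebo", "rfs_treatment", "hr", "hr_p")]
#> # A tibble: 3 × 6
#>   label        n rfs_placebo rfs_treatment    hr    hr_p
#> 1 <=17       101       0.710         0.765 0.823 0.620
#> 2 (17, 29)   168       0.625         0.831 0.372 0.00175
#> 3 >=29        88       0.786         0.817 0.820 0.695
```

Only the intermediate stratum — deficient but not severely so — shows a
treatment effect, exactly the structure the generator encodes (true
hazard ratio 0.49 there, 1.0 elsewhere).

Each result type has an `autoplot()` method; `run_full_analysis()`
orchestrates every stage from a single `analysis_config()` and writes a
report bundle. A thin command-line wrapper with `simulate`,
`thresholds`, `survival` and `report` subcommands ships in
`inst/scripts/hingefit-cli.R`.

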