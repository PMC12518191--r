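# stpdosim

Single-time-point (STP) dosimetry for ^131^I therapy of benign thyroid
disease: population biokinetic modelling of thyroidal radioiodine
retention with nonlinear mixed-effects (NLME) models, and estimation of a
patient's time-integrated activity (TIA) from a single uptake
measurement.

The package is aimed at medical physicists and pharmacometricians who
want to evaluate — by simulation, with known ground truth — how accurate
single-time-point thyroid dosimetry can be, which measurement time to
prefer, and how much a misspecified retention model costs.

## The model

Thyroidal retention (fraction of administered activity at time *t* after
administration, physical decay included) is described by
sum-of-exponentials functions

```
a4c(t) = λ1/(λ2+λ1−λ3) · (e^{−(λ3+λp)t} − e^{−(λ1+λ2+λp)t}) + a1·e^{−(λ1+λ2+λp)t}
a3b(t) = the same without the a1 term
```

with uptake/clearance rates λ1, λ2, λ3 ≥ 0 (h⁻¹), the physical decay
constant λp = ln2/(8.022 × 24 h), and a blood-pool background amplitude
a1 ≥ 0. The TIA, ∫₀^∞ a(t) dt, is available in closed form.

Five TIA estimators are provided per patient:

| method | data used | how |
|---|---|---|
| `rTIA` | all time points | NLME fit of `a4c`, empirical-Bayes curve integrated analytically (the reference) |
| `s1TIA` | one time point | population re-fitted with the target reduced to one observation, model `a4c` |
| `s2TIA` | one time point | same, with the 3-parameter model `a3b` |
| `hTIA` | one time point | closed-form SOP formulas (0.97·A(t)·2^{t/5.5d}·5.5d/ln2 in days 1–3; A(t)·t/0.357 in days 4–8) |
| `nTIA` | none | analytic TIA of the mean individual parameters of the population fit |

Accuracy against `rTIA` is summarised per method and time point by mean
relative deviation (RD), its SD, RMSE = √(mean² + SD²), MAPE, exceedance
counts (|RD| > 5/10/20 %), and paired Wilcoxon signed-rank comparisons
(exact distribution with midrank ties up to n = 25).

Because the clinical cohort the design emulates is not publicly
available, the package ships a synthetic-cohort generator
(`default_population()`, `generate_cohort()`) that reproduces the
sampling design — 73 patients at 2/6/24/48 h plus 96 h (n = 53) or 120 h
(n = 20), 364 records — with log-normal inter-individual variability and
a proportional-plus-floor noise model, and records the true parameters
and TIAs of every simulated patient.

## Worked example

```r
library(stpdosim)

pop <- population_truth(
  typical_params = soef_params(0.04, 0.04, 0.0015, a1 = 0.05),
  iiv_cv = 0.30,
  residual_model = list(type = "combined", prop = 0.10, add = 0.002),
  late_times = c(96, 120), late_n = c(8L, 4L), n = 12L, seed = 20260101L)
cohort <- generate_cohort(pop)

cfg <- fit_config(n_starts = 500, n_refine = 3, seed = 1L)
refs <- compute_reference_tias(cohort$records, cfg)   # rTIA per patient

s1 <- run_stp_grid(cohort$records, "a4c", time_points = 120,
                   config = cfg, ref_fit = attr(refs, "fit"))
ht <- eanm_tias(cohort$records, time_points = 120)
nt <- ntp_tia(attr(refs, "fit"))

all_est <- rbind(as.data.frame(s1), as.data.frame(ht), as.data.frame(nt))
class(all_est) <- c("tia_estimates", "data.frame")
format_accuracy_table(build_accuracy_table(all_est, refs))
```

Output:

```
  method time_point_h  n mean_rd_pct sd_rd_pct rmse_pct mape_pct n_rd5 n_rd10 n_rd20
1  s1TIA          120  4        -0.2       1.8      1.8      1.6     0      0      0
2   hTIA          120  4        -4.9       6.3      8.0      7.5     4      1      0
3   nTIA           NA 12         1.2      19.5     19.5     14.9     9      7      3
```

Reading it: for the four patients with a 120 h measurement, the NLME
single-time-point estimate (`s1TIA`) reproduces the all-time-point
reference TIA to within ~2 % (MAPE 1.6 %); the closed-form SOP estimate
(`hTIA`) is a little worse (MAPE 7.5 %, slightly negative bias); using no
measurement at all (`nTIA`, the population value assigned to all 12
patients) costs an order of magnitude in accuracy (MAPE 14.9 %, 3
patients beyond 20 %).

`run_pipeline(run_config(seed = ...))` chains the whole workflow —
simulate (or read a CSV), reference fit, STP grids for both models, SOP
and no-time-point estimates, accuracy table — and writes every artifact
with an MD5 manifest; identical seeds reproduce the outputs byte for
byte.

## Package layout

- `soef_params()`, `soef_retention()`, `soef_tia()` — retention models
  and closed-form TIAs.
- `population_truth()`, `default_population()`, `generate_cohort()`,
  `study_design_cohort()` — synthetic cohorts with ground truth.
- `fit_config()`, `random_starts()`, `fit_population()`,
  `empirical_bayes()`, `laplace_m2ll()` — NLME estimation with
  multi-start initialisation and a documented fallback ladder.
- `compute_reference_tias()`, `stp_fit()`, `run_stp_grid()`,
  `ntp_tia()`, `jackknife_validate()`, `stp_grid_counts()` — the STP
  workflow.
- `sop_constants()`, `htia()`, `eanm_tias()` — closed-form SOP
  estimators.
- `relative_deviation()`, `summarize_rd()`, `wilcoxon_paired()`,
  `build_accuracy_table()`, `format_accuracy_table()` — accuracy
  evaluation.
- `read_biokinetics()`, `write_biokinetics()`, `run_config()`,
  `run_pipeline()` — I/O and the end-to-end pipeline.

The methods vignette (`vignettes/stp-dosimetry-methods.Rmd`) documents
the estimation choices, the synthetic design and its limitations.
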