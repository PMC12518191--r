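---
title: "Single-time-point thyroid dosimetry: models, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-time-point thyroid dosimetry: models, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Individualised radioiodine therapy of benign thyroid disease requires the
time-integrated activity (TIA) of ^131^I in the thyroid: the integral of
the organ's fractional retention over all time, which multiplies the dose
factor to give the absorbed dose. Classically the TIA is obtained from a
multi-day series of uptake measurements per patient. `stpdosim`
implements the single-time-point (STP) alternative: a population
biokinetic model is estimated from a cohort by nonlinear mixed-effects
(NLME) modelling, and a new or reduced measurement — one retention value
at one time point — is turned into a patient-specific TIA through the
population distribution.

## Retention model and analytic TIA

Thyroidal retention (fraction of administered activity, blood-pool
background included) is described by sum-of-exponentials functions. The
4-parameter form is

$$a_{4c}(t) = \frac{\lambda_1}{\lambda_2+\lambda_1-\lambda_3}
  \left(e^{-(\lambda_3+\lambda_{phys})t} -
        e^{-(\lambda_1+\lambda_2+\lambda_{phys})t}\right)
  + a_1 e^{-(\lambda_1+\lambda_2+\lambda_{phys})t},$$

with uptake/clearance rate constants $\lambda_1,\lambda_2,\lambda_3 \ge 0$
(h^-1^), the physical decay constant
$\lambda_{phys} = \ln 2/(8.022\times 24)\,\mathrm{h^{-1}}$, and a
dimensionless blood-pool amplitude $a_1 \ge 0$ that absorbs residual
background counts in a neck measurement. The 3-parameter form $a_{3b}$ is
the same expression without the $a_1$ term and is represented internally
as $a_{4c}$ with $a_1$ structurally fixed at zero, so one code path serves
both.

The TIA is available in closed form,

$$TIA = \frac{\lambda_1}{\lambda_2+\lambda_1-\lambda_3}
  \left(\frac{1}{\lambda_3+\lambda_{phys}} -
        \frac{1}{\lambda_1+\lambda_2+\lambda_{phys}}\right)
  + \frac{a_1}{\lambda_1+\lambda_2+\lambda_{phys}},$$

in units of (fraction of administered activity) × hours; because the
administered activity is normalised to one, no activity-unit conversion is
applied. At the removable singularity
$\lambda_1+\lambda_2-\lambda_3 = 0$ both the curve and the integral switch
to their limit forms ($\lambda_1 t\,e^{-(\lambda_3+\lambda_{phys})t}$ and
$\lambda_1/(\lambda_3+\lambda_{phys})^2$). The switch is taken when
$|\lambda_1+\lambda_2-\lambda_3| <
10^{-10}(\lambda_1+\lambda_2+\lambda_3+\lambda_{phys})$; the
scale-relative threshold avoids catastrophic cancellation without ever
activating for physiologically distinct rates. Tests verify continuity
across the switch and agreement of the closed form with adaptive
quadrature to better than one part in 10^8^.

## Population estimation

`fit_population()` estimates the model hierarchically: individual
parameters are log-normal around population typical values, i.e. normal
random effects on $\log\lambda_1,\log\lambda_2,\log\lambda_3,\log a_1$
with a diagonal covariance. The log parameterisation enforces positivity
and is standard in population kinetics; the diagonal covariance is a
deliberate restriction — a 73-patient cohort cannot support a full 4×4
random-effect covariance robustly.

Residual error models:

* `proportional` (default) — additive normal error on log retention, the
  exponential-error form of a proportional model. `sigma` is then
  approximately the residual CV. Count-rate-derived retention fractions
  have roughly multiplicative error, which this matches. Zero retentions
  cannot enter this likelihood and are dropped (counted in the fit
  object).
* `additive` — homoscedastic error on the natural scale.
* `combined` — natural-scale error with SD proportional to
  (constant + prediction).

The marginal likelihood is maximised by the Lindstrom–Bates
alternating algorithm (`nlme::nlme`, maximum likelihood); the returned
`objective` is the resulting −2 log-likelihood. The estimation contract
is the objective, not the algorithm: `laplace_m2ll()` provides an
independent Laplace evaluation of the same marginal likelihood at
arbitrary population parameters, which the test suite uses to verify
that the returned estimate beats every refined multi-start initial
point.

**Multi-start initialisation.** Sum-of-exponentials likelihoods are
multi-modal, so 1000 starting vectors are drawn log-uniformly within
bounds ($\lambda \in [10^{-5}, 1]$ h^-1^, $a_1 \in [10^{-4}, 0.5]$ —
spanning physiologic uptake/washout scales) and ranked by a cheap pooled
fixed-effects least-squares objective; the best 5 are refined by the full
NLME fit and the best converged refinement is kept. Running the full NLME
from every start would cost three orders of magnitude more for no
benefit: the screen already separates the basins.

**Convergence.** The outer iteration stops at a relative objective change
of 10^-5^ or 60 iterations (both configurable). The alternating
algorithm's objective oscillates at the 10^-5^ level on this model class,
so pushing the tolerance lower mainly converts converged fits into
max-iteration stalls; parameter changes at that level are orders of
magnitude below the statistical uncertainty.

**Fallback ladder.** A refinement attempt can fail (step halving,
singular working matrices). The ladder is: random effects on all four
log parameters → drop the $a_1$ random effect (weakly identified when
the blood-pool share of the signal is small) → fix $a_1 = 0$ and fit the
nested 3-parameter model (the maximum-likelihood solution when the data
carry no blood-pool signal, where $\log a_1$ otherwise diverges) → a
pooled fixed-effects-only fit with all between-patient variances zero.
The engine actually used is recorded in every fit object and in the STP
audit log. Before any NLME attempt, a pooled fit is tried once: if it is
exact (residual SD at the floor of 10^-6^), the cohort is homogeneous
and noise-free, the pooled model *is* the maximum-likelihood solution,
and it is returned directly — this is what makes the degenerate
zero-variability contracts exact rather than approximate.

**Empirical Bayes.** Individual parameters are the modes of the
conditional (posterior) distribution given the patient's data and the
population estimate. For patients inside an NLME fit they come from the
fit itself; `empirical_bayes()` computes the same MAP quantity for any
patient — including one the population has never seen, which is what the
frozen-prior STP mode uses. Components with zero between-patient
variance are pinned at the typical values.

## The STP workflow

* **Reference (rTIA).** The 4-parameter model is fitted to all
  time points of all patients; each patient's empirical-Bayes curve is
  integrated analytically.
* **STP (s1TIA / s2TIA).** For a target patient and time point, the
  likelihood dataset is: all other patients' complete profiles plus the
  target's single observation. By default (`joint_refit`) the population
  is re-estimated jointly on that dataset; `frozen_prior` instead keeps a
  population fitted to the other patients and computes only the target's
  MAP estimate — a cheaper approximation whose agreement with the joint
  refit is itself tested. Fitting with $a_{4c}$ gives s1TIA, with
  $a_{3b}$ s2TIA.
* **No time point (nTIA).** The analytic TIA of the arithmetic mean of
  the per-patient parameters of the all-time-point fit, assigned to every
  patient — the value a centre would use with no measurement at all.
* **Closed-form SOP (hTIA).** One measurement mapped directly to a TIA:
  $0.97\,A(t)\,2^{t/5.5\mathrm{d}}\cdot 5.5\,\mathrm{d}/\ln 2$ for
  $t \in [1, 3]$ days, $A(t)\,t/0.357$ for $t \in [4, 8]$ days. Window
  boundaries are inclusive; the undefined gap (3, 4) days raises an error
  rather than interpolating, and no decay correction is added because the
  measured activity already contains it. For a mono-exponential retention
  with effective half-life exactly 5.5 days the early-window formula
  inverts the decay exactly, so hTIA/TIA = 0.97 to machine precision — a
  test anchors this identity, as well as the late-window ratio identity
  $\lambda_{eff}\,t\,e^{-\lambda_{eff}t}/0.357$.

Each STP grid cell is warm-started from the all-data reference estimate
and accepts the first converged candidate (reference start first, then
screened random starts). The STP dataset differs from the reference
dataset only by the removal of a handful of observations, so the
reference estimate sits in the correct basin; re-screening 1000 starts
per cell would multiply the cost of a grid by an order of magnitude
without changing the result. The full screen remains the default for
free-standing fits.

**Jackknife.** "Robustness of an STP fit" has two readable meanings, and
the report covers both: (i) the exclusion audit — the likelihood dataset
contains exactly one observation of the target, verifiable per cell in
the fit log; (ii) leave-one-out perturbation of the population — each
other patient is dropped in turn, the STP estimate is recomputed, and the
spread (SD) of the target's TIA across replicates is reported. The
target itself is structurally excluded from the leave-out set.

## Accuracy metrics

Per patient, the relative deviation $RD = (sTIA - rTIA)/rTIA$. Per
(method, time point) group: mean RD, SD of RD, $RMSE =
\sqrt{SD^2 + mean^2}$, MAPE (mean |RD|), and counts of patients with
|RD| strictly above 5 %, 10 % and 20 %. The SD is the population SD
(divide by $n$): that is the convention under which the RMSE
decomposition is exactly the root-mean-square of the RDs, and the test
suite asserts that identity; the sample SD is available for sensitivity
checks. Fractions are stored internally and converted to percent only in
the report layer.

Paired method comparisons use the Wilcoxon matched-pairs signed-rank
test. Zero differences are dropped and ties are midranked. The exact
distribution is computed (dynamic programming over doubled midranks) for
up to 25 non-zero pairs — the general-purpose implementation in base R
silently switches to a normal approximation whenever ties occur, which is
why the exact-with-ties distribution is package code; it is verified
against full 2^n^ sign enumeration in the tests. Above 25 pairs the
tie-corrected normal approximation with continuity correction is used.
The median of the paired differences is reported alongside the p-value.

## The synthetic cohort generator

The clinical dataset the design emulates is not publicly deposited, so
every stage is validated on synthetic cohorts with known ground truth.
`default_population()` fixes the emulated design: 73 patients measured at
2, 6, 24 and 48 h, plus 96 h (53 patients) or 120 h (20 patients); the
`study_design_cohort()` fixture additionally drops one patient's 6-h
measurement, giving 364 records. Individual parameters are log-normal
(median = typical) with 30 % CV on all four parameters, independently;
residual error is 10 % proportional with a 0.002 additive floor so that
late, low observations are not noise-free. Negative noisy observations
are truncated at zero and flagged.

The typical values $\lambda_1 = \lambda_2 = 0.04$ h^-1^,
$\lambda_3 = 0.0015$ h^-1^, $a_1 = 0.05$ are **invented defaults**, not
estimates of any clinical population: they are chosen so the noise-free
curve peaks near 34 h at a retention of about 0.40 with a terminal
biological half-life of roughly 2.8 weeks — qualitatively realistic for
thyroidal radioiodine uptake. What the generator does *not* emulate:
detector physics (energy windows, phantom calibration), disease-subgroup
kinetics (Graves' vs goitre), covariate structure, and any correlation
between individual parameters. Passing tests therefore demonstrate
correctness of the machinery and achievable accuracy *under the stated
population model*, not clinical performance.

A note on identifiability: under this design $\lambda_3$ (terminal
biological clearance) is the hardest parameter — it is less than half of
$\lambda_3+\lambda_{phys}$, the quantity the data actually constrain, so
relative errors in the observed terminal slope amplify by a factor of
about 3.4 in $\lambda_3$, and its estimation errors are strongly
anti-correlated with $\lambda_2$. This is a property of the measurement
design (latest sample at 120 h, 10 % noise), not of the estimator.

## Problem sizes used in validation

The test suite exercises unit behaviour on cohorts of 4–20 patients and
the full machinery on the 73-patient design: parameter recovery over 10
simulated cohorts, and the directional STP findings (later time points
beat earlier ones; the misspecified 3-parameter model is more biased than
the 4-parameter model at 120 h; the no-measurement estimate is less
accurate than informed, well-specified single-time-point estimates) over
5 simulated cohorts. The 120 h grids are evaluated in full (the 20
patients with that measurement); the 2 h grid evaluates a deterministic
subsample of 25 of the 73 possible targets — the population fit behind
every cell still uses all patients, only the number of evaluated target
cells is reduced, which changes the Monte-Carlo noise of the 2 h MAPE
and nothing else. These sizes give
stable medians while keeping a full run of the suite in the tens of
minutes; `scripts/acceptance.R` repeats the recovery study and a
one-cohort STP study from a user-supplied seed.

## Known limitations

* The Lindstrom–Bates approximation can be biased for strongly nonlinear
  models with large inter-individual variability; no stochastic-EM or
  adaptive-quadrature estimator is provided.
* Random-effect covariance is diagonal by construction.
* No covariate models (age, sex, thyroid volume, disease type).
* No standard errors of population parameters are reported.
* The closed-form SOP estimator is only defined inside its two time
  windows; measurements in the (3, 4)-day gap are refused by design.
* TIAs are reported in hours for unit administered activity; absorbed
  dose conversion is out of scope.
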