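---
title: "Population pharmacokinetics of cabozantinib: model, simulation and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of cabozantinib: model, simulation and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabopk)
```

## The problem

Cabozantinib is an oral tyrosine kinase inhibitor approved at 140 mg/day
(capsule) for medullary thyroid cancer (MTC) and at 60 mg/day (tablet) for
renal cell carcinoma (RCC). Earlier population analyses of single-population
datasets estimated apparent clearance (CL/F) around 4.4 L/h in MTC patients
but only about 2.2 L/h in RCC patients and healthy volunteers (HV) — an
approximately twofold difference that parallels the twofold difference in
approved dose. An integrated nonlinear mixed-effects (NLME) analysis pooling
healthy-volunteer and multi-tumour-type studies quantified how much of the
between-population heterogeneity is explained by demographics versus cancer
type, and found that MTC remains associated with roughly 93% higher CL/F
after adjusting for demographics, translating into roughly 40% and 50% lower
steady-state peak and trough exposures at an equal dose.

`cabopk` implements that integrated model as reusable, tested machinery:

* the closed-form structural model and steady-state exposure metrics,
* the covariate model mapping a subject's characteristics to typical
  parameters,
* between-subject and residual variability,
* a virtual-population generator reproducing the pooled nine-study design,
* marginal-likelihood estimation (Laplace) with nested-model comparison, and
* posterior-predictive-check (PPC) diagnostics with a smoothed parametric
  bootstrap.

The original concentration data are proprietary, so the published parameter
estimates are treated as ground truth for simulation, and the estimation
machinery is validated by parameter recovery on data simulated from those
values, not by re-estimating the original dataset.

## Structural model

Disposition is a two-compartment model with first-order elimination,
parameterised by apparent clearance CL/F (L/h), central volume Vc/F (L),
inter-compartmental flow Q/F (L/h) and peripheral volume Vp/F (L). Oral
input is dual: a fraction F1 of the bioavailable dose enters a lagged
first-order depot (rate constant Ka, lag ALAG1), and the remainder 1 − F1
enters the central compartment as a zero-order infusion of duration D2
starting at dose time. The plasma concentration is the sum of the standard
closed-form two-compartment solutions for a lagged first-order input and a
piecewise (during/after infusion) zero-order input; multiple dosing is
superposition, and steady state sums each exponential term as a geometric
series (`steady_state_metrics()`).

Units are fixed throughout: dose mg (free-base equivalents), volumes L,
times h, concentrations ng/mL (the mg/L solution is scaled by 1000), so the
0.5 ng/mL quantification limit can be applied directly.

Two numerical choices matter:

* **Lag placement.** The lag applies to the first-order depot only; the
  zero-order input starts at dose time. The reported model attaches the lag
  explicitly to the first-order absorption process and gives none for the
  zero-order route. Whether the zero-order route shared the lag in the
  original implementation is not determinable from the publication; this
  choice is therefore a documented assumption, not a reproduction.
* **Degenerate rate constants.** If Ka numerically coincides with a hybrid
  disposition exponent (relative difference below 1e-8), the 0/0 branch of
  the closed form is avoided by a deterministic 1e-7 relative perturbation
  of Ka rather than by separate limit formulas. The same rule resolves a
  coincident pair of hybrid exponents by perturbing Q/F.

The steady-state maximum is located on a 0.05-h grid over one dosing
interval followed by local refinement; the profile is piecewise smooth with
at most a few local maxima, so the grid cannot skip the global one. The
trough is defined as the concentration at the end of the dosing interval
(the zero-order route makes the concentration rise immediately after a
dose). AUC over a steady-state interval is exact by mass balance,
`1000 * frel * dose / cl`.

## Covariate model

Continuous covariates act as power functions of the covariate relative to a
reference value; categorical covariates act multiplicatively through
`exp(theta_x)`, where `theta_x` is the natural log of 1 plus the fractional
change from the reference level — so a reported fractional change `fc`
multiplies the typical value by exactly `1 + fc` and the parameter can
never go negative. `fractional_change_to_theta()` and its inverse implement
this convention. Age and weight act on CL/F and Vc/F; sex, race and cancer
population act on CL/F and Vc/F; dose acts on Ka through a power term;
capsule formulation scales Ka and the overall relative bioavailability. The
reference subject is a 60-year-old, 80-kg White male healthy volunteer on
the tablet.

Three reference values are not printed in the source material and are set
here, overridable on the parameter object: the age and weight references
(60 years, 80 kg — the reference subject used for the covariate-impact
figure) and the reference dose for the dose-dependent Ka power model
(60 mg, the modal tablet dose). The three published parameter columns are
available as presets: `theta_preset("FM")` (full model, the final one),
`theta_preset("FMECT")` (full model excluding cancer type) and
`theta_preset("BASE")` (no demographic or population covariates). The other
malignancies level (`OTH`) uses the "Other malignancies" coefficients.

```{r covariate-example}
th <- theta_preset("FM")
typical_disposition(reference_subject(), th)$cl          # 2.478 L/h
typical_disposition(covariate_set(population = "MTC"), th)$cl
covariate_impact_table(th)[c(1, 12), ]
```

## Variability model

Between-subject variability is log-normal on Ka, CL/F and Vc/F
(`theta_i = theta_typical * exp(eta)`) and logit-scale on F1, so the
individual depot fraction stays in (0, 1) — the published F1 is itself an
anti-logit transform, and exponential variability could push the fraction
above 1. Exactly these four effects carry reported variances
(2.063, 0.202, 0.233, 0.466); all other parameters are fixed at typical
values. Residual variability is additive on the log-concentration scale
with variance 0.118.

The single reported off-diagonal term, labelled as the CL/F–Vc/F entry with
value 2.475, exceeds the Cauchy–Schwarz bound `sqrt(0.202 * 0.233) ≈ 0.217`
and therefore cannot be a covariance of those variances as printed. An
invalid matrix must not silently enter simulation, so the default
`omega_matrix()` is the reported diagonal plus a configurable CL–Vc
*correlation* (default 0.5, a moderate positive value consistent with the
direction implied by a shared bioavailability term); the printed 2.475 is
deliberately not used. `validate_omega()` rejects any matrix violating
symmetry, the Cauchy–Schwarz bound or positive semidefiniteness.

## The virtual nine-study population

`study_suite()` encodes the pooled design: nine studies, 1534 subjects in
total, with each study's sample size, population, dose levels, formulation,
planned sampling schedule, sex and race proportions, and truncated-normal
age and weight generators (mean, SD, clipped to the reported ranges).
Several published design elements are under-determined and are encoded as
fixed, documented choices rather than left random:

* Visit rules of the sparse phase 2/3 studies ("end of week 3", "even
  weeks", cycle days) are encoded as fixed nominal pre-dose days; the
  randomized-discontinuation arm of the prostate-cancer phase 2 study is
  represented by the expansion-cohort schedule at 100 mg for all its
  subjects.
* The crossover bioequivalence study is represented as two single-dose
  periods (capsule, then tablet) separated by a 28-day washout.
* Race proportions are renormalised over the four recorded levels in
  studies that reported missing race; every generated subject has complete
  covariates.
* The first-in-human study is generated at 140 mg for all subjects (a few
  original subjects received 200 mg).
* Sampling is at nominal times only; no dropout or dose modification is
  generated.

Observations scheduled at or before the first dose contain no drug by
construction; they are emitted as missing records (`DV` empty, `MDV = 1`)
rather than below-limit measurements, mirroring how pre-dose samples enter
an analysis dataset. Simulated concentrations below 0.5 ng/mL are retained
with `BLQ = 1` and `MDV = 1`: kept in the file, excluded from estimation
(`estimation_view()`), matching the source analysis, which excluded its
small (< 1%) below-limit fraction.

```{r suite}
sum(vapply(study_suite(), `[[`, 0L, "n"))
```

## Estimation

The estimation engine is a single Laplace approximation to the marginal
likelihood with MAP inner optimisation. The original analysis names four
NONMEM algorithms (FOCEI, ITS, SAEM, importance sampling); none of them is
re-implemented as named — the Laplace family is the same conditional-
approximation family, is fully specifiable, and runs at desk scale. The
objective (OFV) is −2 log approximate marginal likelihood including all
normalising constants:

* inner step: for each subject, minimise the joint −2 log density of the
  observations and the random effects (`individual_joint_nll()`) over the
  active random effects, quasi-Newton from a warm start (zero on the first
  pass, the previous MAP afterwards), with deterministic fallback restarts;
* correction: add `log det(H_i) − d log(2*pi)` with `H_i` the
  central-difference Hessian of half the joint −2 log likelihood at the
  MAP (ridged deterministically if numerically non-positive-definite);
* outer step: `stats::nlminb()` over the transformed scale — log for
  positive structural parameters and variances, logit for F1,
  `log(1 + fc)` for fractional changes, identity for power exponents.
  A non-positive model prediction at an observation time contributes a
  large finite penalty, never a non-finite value.

Identifiability policy: configurations declare what is estimated. Sparse
late-study data cannot identify the absorption parameters, so default fits
on sparse designs keep `alag1`, `d2` and the dose exponent fixed at preset
values; rich single-dose designs may free them. Nested structures are
compared with `compare_nested()` (difference in OFV against the chi-square
upper tail). The covariance of the estimates, used by the PPC's smoothed
parametric bootstrap, is twice the inverse central-difference Hessian of
the OFV on the transformed scale (`hessian = TRUE`).

The package validates this machinery on simulated data where the truth is
known, at sizes chosen to exercise realistic designs while keeping the test
suite quick to run:

* the Laplace OFV is compared with a 21-node adaptive Gauss–Hermite oracle
  on a one-random-effect problem (8 subjects, 15-sample single-dose design,
  residual variance 0.05 — a rich, moderate-noise design in which the
  conditional posterior is near-Gaussian, which is the regime where both
  integration schemes are accurate and comparable);
* simulation–estimation recovery of (CL/F, Vc/F, Ka, F1, the CL variance,
  the residual variance) from 150 rich-sampled virtual subjects;
* a covariate-detection experiment: 150 subjects of whom 30 are MTC,
  day-1 plus day-29 sampling under once-daily dosing, with clearance
  variability only; the likelihood-ratio statistic for adding the MTC
  clearance coefficient is compared with the 10.83 chi-square cutoff
  (alpha = 0.001) over ten seeded replicates.

## Diagnostics

`gof_summary()` produces per-observation typical predictions (PRED, random
effects at zero), individual predictions (IPRED, MAP random effects),
individual weighted residuals on the log scale, and geometric means by
study and nominal time. `eta_by_covariate()` summarises MAP random effects
by covariate level — the diagnostic that exposes a population trend when
the covariate is omitted and its resolution when the covariate is modelled.

`posterior_predictive_check()` draws parameter vectors (default 500) from a
multivariate normal on the transformed scale centred at the estimates with
the estimate covariance, simulates one replicate of the fitted dataset per
draw — reusing the observed design, sample sizes and covariates — and
computes the median and 10th/90th percentiles of concentration per study
and nominal time; 90% prediction intervals are the 5th/95th percentiles of
each statistic across replicates. Draws violating parameter invariants
(non-positive-semidefinite covariance, F1 outside (0, 1)) are rejected and
redrawn with the rejection count reported; drawing on the transformed scale
makes rejections rare. Observed covariates are reused rather than resampled
because the source procedure replicates "study design, sample size, and
covariate distributions", which the observed covariates satisfy exactly.
Calibration is checked on self-consistent simulated data (40 subjects, 12
nominal times, 100 replicates): the observed median should fall inside its
90% interval at roughly 90% of nominal times.

## What the synthetic data do and do not show

The generator reproduces the design skeleton (sample sizes, doses,
formulations, schedules) and marginal demographic distributions of the
pooled studies, with observations generated exactly from the model being
fitted. Passing recovery and calibration tests therefore demonstrates that
the estimation and diagnostic machinery is internally correct — not that
the model describes real cabozantinib data, and not that the published
estimates themselves are reproduced, which would require the proprietary
concentration records. Real data features deliberately out of scope:
actual-versus-nominal sampling-time deviations (an optional jitter knob
exists but is off by default), dropout and dose reductions, missing
covariates, enterohepatic recirculation mechanisms, and inter-occasion
variability.

## Known limitations

* The Laplace approximation shares the usual small-sample biases of
  conditional-mode methods; variance parameters of weakly identified
  effects (notably the large Ka variance) are recovered less precisely
  than disposition parameters.
* The OFV Hessian used for the estimate covariance is a finite-difference
  object; for parameters near a boundary on the natural scale the
  transformed-scale normal approximation is crude.
* Time-varying clearance (the day-1 versus day-29 contrast in MTC
  patients) is represented only through the population covariate, as in
  the final published model; no time-dependent clearance term is provided.
* The steady-state trough is reported at the end of the dosing interval;
  under extreme parameter draws (lag comparable to the interval) the true
  minimum can occur elsewhere, which the multi-interval bookkeeping
  handles but the single-number summary does not flag.
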