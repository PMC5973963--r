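# cabopk

Population pharmacokinetic (popPK) modelling and simulation of the tyrosine
kinase inhibitor **cabozantinib** in healthy volunteers (HV) and patients
with renal cell carcinoma (RCC), medullary thyroid cancer (MTC),
castration-resistant prostate cancer, glioblastoma and other advanced
malignancies.

The package is aimed at pharmacometricians who want to work with the
integrated multi-study cabozantinib model — simulate exposures for typical
or virtual patients, generate virtual pooled-study datasets, fit nested
covariate structures by marginal likelihood, and run posterior predictive
checks — without access to the proprietary concentration data behind the
original analysis.

## The model

Disposition is a two-compartment model with first-order elimination
(CL/F, Vc/F, Q/F, Vp/F). Oral input is dual: a fraction F1 of the
bioavailable dose enters a lagged first-order depot (rate constant Ka, lag
ALAG1), the remainder enters the central compartment as a zero-order
infusion of duration D2. Between-subject variability is log-normal,

  θᵢ = θ_T · exp(ηᵢ),  η ~ N(0, Ω)  on (Ka, CL/F, Vc/F) and logit-scale on F1,

and residual variability is additive on the log scale,

  ln Yᵢⱼ = ln Cᵢⱼ + εᵢⱼ,  ε ~ N(0, σ²).

Continuous covariates (age, weight, dose on Ka) enter as power models
θ_TV = θ_REF (x / x_REF)^θx; categorical covariates (sex, race, cancer
population, capsule formulation) enter as θ_TV = θ_REF · exp(θx), with θx
the log of the fractional change from the reference level. Estimation uses
a Laplace approximation to the marginal likelihood (−2 log L, "OFV") with
MAP inner optimisation; nested covariate structures are compared by ΔOFV
against the chi-square tail. The three published parameter columns ship as
presets: `theta_preset("FM")` (final full model), `"FMECT"` (no cancer-type
effects) and `"BASE"` (no demographic or population covariates).

## Worked example

Typical steady-state exposure at 60 mg once daily, reference healthy
volunteer versus an otherwise-identical MTC patient:

```r
library(cabopk)
th <- theta_preset("FM")
ref <- reference_subject()
mtc <- covariate_set(population = "MTC")
ss_hv  <- steady_state_metrics(typical_absorption(ref, th),
                               typical_disposition(ref, th), dose = 60, tau = 24)
ss_mtc <- steady_state_metrics(typical_absorption(mtc, th),
                               typical_disposition(mtc, th), dose = 60, tau = 24)
round(unlist(ss_hv), 1)
#>    cmax_ss    cmin_ss auc_tau_ss    tmax_ss
#>     1136.5      924.4    24213.1        2.7
round(unlist(ss_mtc), 1)
#>    cmax_ss    cmin_ss auc_tau_ss    tmax_ss
#>      662.0      438.8    12558.6        2.7
round(100 * (1 - ss_mtc$cmax_ss / ss_hv$cmax_ss), 1)  # % lower peak
#> [1] 41.8
round(100 * (1 - ss_mtc$cmin_ss / ss_hv$cmin_ss), 1)  # % lower trough
#> [1] 52.5
```

The MTC covariate multiplies typical CL/F by 1.928 (a 92.8% increase), so
at the same dose the typical MTC patient has roughly 40% lower steady-state
peak and 50% lower trough concentrations — the package computes the peak at
1136.5 vs 662.0 ng/mL and the trough at 924.4 vs 438.8 ng/mL.

Simulating a virtual study and re-estimating parameters:

```r
spec <- study_spec("demo", 30, "HV", 60, "tablet", dose_times = 0,
                   obs_times = c(0.5, 1, 2, 4, 8, 24, 48, 96, 168, 336),
                   sex_male_p = 0.5, race_p = c(1, 0, 0, 0),
                   age = c(40, 10, 18, 60), weight = c(80, 12, 50, 120))
ds <- simulate_dataset(list(spec), th, omega_matrix(cl_vc_corr = 0),
                       residual_model(0.118), seed = 1)
fit <- poppk_fit(ds, model_config(estimate = c("cl", "vc", "omega_cl", "sigma2")),
                 start = th, omega = omega_matrix(cl_vc_corr = 0))
fit
#> Population PK model fit (Laplace approximation)
#>   structure: FM | subjects: 30 | observations: 299
#>   OFV: 450.289 | convergence code: 1
#>   estimated parameters:
#>        cl        vc  omega_cl    sigma2
#>   2.69103 157.57062   0.20986   0.12390
```

With 30 subjects the estimates scatter around the generating values
(CL/F 2.478 L/h, Vc/F 187 L, ω²_CL 0.202, σ² 0.118) within sampling error;
the recovery tests in `tests/testthat/test-acceptance.R` run the same
experiment at 150 subjects, where every estimate lands within 15% of truth.
The fitted object supports `summary()`, `coef()`, `predict()`,
`residuals()`, `simulate()`, `plot()`, `logLik()` and `vcov()`, plus
`gof_summary()`, `eta_by_covariate()`, `compare_nested()` and
`posterior_predictive_check()`.

`vignettes/cabozantinib-poppk.Rmd` documents the model equations,
parameter conventions, the virtual nine-study population (1534 subjects),
and every place where a design decision had to fill a gap in the published
description. The file `inst/extdata/example_pkdata.csv` is a small
synthetic example dataset produced by the package's own generator.

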