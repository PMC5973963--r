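# Covariate model: power relations for continuous covariates (age, weight,
# dose) and log-fractional-change exponential relations for categorical
# covariates (sex, race, cancer population, formulation).


#' One subject's covariate set
#'
#' @param age Age (years), > 0.
#' @param weight Body weight (kg), > 0.
#' @param sex `"male"` or `"female"`.
#' @param race `"White"`, `"Black"`, `"Asian"` or `"Other"`.
#' @param population Cancer population / subject type: `"HV"`, `"RCC"`,
#'   `"CRPC"`, `"MTC"`, `"GB"` or `"OTH"` (other advanced malignancies).
#' @param formulation `"tablet"` or `"capsule"`.
#' @param dose Administered dose (mg free-base equivalents), > 0.
#' @return An object of class `"covariate_set"`.
#' @export
covariate_set <- function(age = 60, weight = 80, sex = "male",
                          race = "White", population = "HV",
                          formulation = "tablet", dose = 60) {
  if (!(age > 0) || !(weight > 0) || !(dose > 0)) {
    stop("age, weight and dose must be > 0", call. = FALSE)
  }
  for (nm in c("sex", "race", "population", "formulation")) {
    val <- get(nm)
    lv <- switch(nm, sex = .sex_levels, race = .race_levels,
                 population = .pop_levels, formulation = .form_levels)
    if (!is.character(val) || length(val) != 1L || !(val %in% lv)) {
      stop(sprintf("unknown %s level '%s' (expected one of %s)",
                   nm, as.character(val), paste(lv, collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(age = age, weight = weight, sex = sex, race = race,
                 population = population, formulation = formulation,
                 dose = dose),
            class = "covariate_set")
}

#' The reference subject
#'
#' The reference against which covariate effects are expressed: a White male
#' healthy volunteer, 80 kg, 60 years, receiving the tablet formulation.
#'
#' @param dose Dose (mg); the reference dose for the dose-dependent
#'   absorption rate is carried by the parameter vector, not here.
#' @return A [covariate_set()].
#' @export
reference_subject <- function(dose = 60) {
  covariate_set(age = 60, weight = 80, sex = "male", race = "White",
                population = "HV", formulation = "tablet", dose = dose)
}

#' Convert a fractional change to its log-scale coefficient (and back)
#'
#' Categorical covariate effects are parameterised as
#' `theta_x = log(1 + fc)` so that the typical value is multiplied by
#' `exp(theta_x) = 1 + fc`, guaranteeing positivity; `fc` is the fractional
#' change from the reference level (the transformed estimate reported for
#' each categorical covariate).
#'
#' @param fc Fractional change, > -1.
#' @return `fractional_change_to_theta`: the log-scale coefficient.
#' @examples
#' fractional_change_to_theta(0.928)     # MTC on CL/F
#' theta_to_fractional_change(log(1.928))
#' @export
fractional_change_to_theta <- function(fc) {
  if (any(fc <= -1)) {
    stop("fractional change must be > -1 (parameter must remain positive)",
         call. = FALSE)
  }
  log1p(fc)
}

#' @rdname fractional_change_to_theta
#' @param theta Log-scale coefficient.
#' @return `theta_to_fractional_change`: the fractional change `exp(theta)-1`.
#' @export
theta_to_fractional_change <- function(theta) expm1(theta)

.zero_fc <- function() stats::setNames(numeric(length(.fc_levels)), .fc_levels)

.theta_new <- function(ka, d2, cl, vc, q, vp, alag1, f1, dose_ka_exp,
                       fc_capsule_ka, fc_capsule_f,
                       age_cl, wt_cl, age_vc, wt_vc,
                       fc_cl, fc_vc,
                       age_ref = 60, weight_ref = 80, dose_ref = 60) {
  structure(list(ka = ka, d2 = d2, cl = cl, vc = vc, q = q, vp = vp,
                 alag1 = alag1, f1 = f1, dose_ka_exp = dose_ka_exp,
                 fc_capsule_ka = fc_capsule_ka, fc_capsule_f = fc_capsule_f,
                 age_cl = age_cl, wt_cl = wt_cl,
                 age_vc = age_vc, wt_vc = wt_vc,
                 fc_cl = fc_cl, fc_vc = fc_vc,
                 age_ref = age_ref, weight_ref = weight_ref,
                 dose_ref = dose_ref),
            class = "theta_vector")
}

#' Fixed-effect parameter vectors of the integrated model
#'
#' Built-in presets for the three published model structures: the full model
#' (`"FM"`, demographics and cancer type on CL/F and Vc/F), the full model
#' excluding cancer type (`"FMECT"`), and the base model (`"BASE"`, no
#' demographic or population covariates). All three retain the dose-dependent
#' absorption rate and the capsule effects on absorption rate and overall
#' bioavailability. Structural values are the reported transformed estimates;
#' categorical covariate coefficients are stored as fractional changes from
#' the reference level; `f1` is the natural-scale (anti-logit) fraction.
#'
#' Reference covariate values are those of the reference subject (60 years,
#' 80 kg) and a 60-mg reference dose for the dose-dependent absorption rate;
#' all three are fields of the returned object and may be overridden.
#'
#' @param name `"FM"`, `"FMECT"` or `"BASE"`.
#' @return An object of class `"theta_vector"`: a named list with structural
#'   parameters (`ka`, `d2`, `cl`, `vc`, `q`, `vp`, `alag1`, `f1`), the power
#'   exponents (`dose_ka_exp`, `age_cl`, `wt_cl`, `age_vc`, `wt_vc`),
#'   fractional-change vectors `fc_cl`, `fc_vc` over levels
#'   female/Black/Asian/Other/RCC/CRPC/MTC/GB/OTH, the capsule effects
#'   `fc_capsule_ka`, `fc_capsule_f`, and reference values `age_ref`,
#'   `weight_ref`, `dose_ref`.
#' @examples
#' th <- theta_preset("FM")
#' th$cl
#' 1 + th$fc_cl[["MTC"]]   # multiplicative MTC effect on CL/F
#' @export
theta_preset <- function(name = c("FM", "FMECT", "BASE")) {
  name <- match.arg(name)
  fc0 <- .zero_fc()
  th <- switch(name,
    FM = {
      fc_cl <- fc0
      fc_cl[c("female", "Black", "Asian", "Other")] <-
        c(-0.230, 0.301, -0.078, -0.007)
      fc_cl[c("RCC", "CRPC", "MTC", "GB", "OTH")] <-
        c(-0.129, -0.009, 0.928, 0.216, 0.178)
      fc_vc <- fc0
      fc_vc[c("female", "Black", "Asian", "Other")] <-
        c(0.110, -0.022, 0.050, -0.059)
      fc_vc[c("RCC", "CRPC", "MTC", "GB", "OTH")] <-
        c(-0.630, -0.241, -0.070, -0.569, -0.186)
      .theta_new(ka = 0.979, d2 = 2.4, cl = 2.478, vc = 187.0, q = 31.213,
                 vp = 195.1, alag1 = 0.784, f1 = 0.854,
                 dose_ka_exp = 0.677,
                 fc_capsule_ka = -0.579, fc_capsule_f = -0.144,
                 age_cl = -0.162, wt_cl = -0.028,
                 age_vc = -0.012, wt_vc = 1.019,
                 fc_cl = fc_cl, fc_vc = fc_vc)
    },
    FMECT = {
      fc_cl <- fc0
      fc_cl[c("female", "Black", "Asian", "Other")] <-
        c(-0.233, 0.249, -0.118, -0.029)
      fc_vc <- fc0
      fc_vc[c("female", "Black", "Asian", "Other")] <-
        c(0.165, -0.065, 0.125, -0.018)
      .theta_new(ka = 0.846, d2 = 2.441, cl = 2.553, vc = 146.713,
                 q = 30.118, vp = 193.605, alag1 = 0.777, f1 = 0.840,
                 dose_ka_exp = 0.585,
                 fc_capsule_ka = -0.300, fc_capsule_f = -0.183,
                 age_cl = -0.273, wt_cl = -0.248,
                 age_vc = -0.277, wt_vc = 0.798,
                 fc_cl = fc_cl, fc_vc = fc_vc)
    },
    BASE = .theta_new(ka = 0.804, d2 = 2.435, cl = 2.457, vc = 157.178,
                      q = 30.154, vp = 188.666, alag1 = 0.789, f1 = 0.847,
                      dose_ka_exp = 0.566,
                      fc_capsule_ka = -0.211, fc_capsule_f = -0.189,
                      age_cl = 0, wt_cl = 0, age_vc = 0, wt_vc = 0,
                      fc_cl = fc0, fc_vc = fc0))
  th
}

# Multiplier applied to CL or Vc for one subject's categorical levels.
.fc_mult <- function(fc, cov) {
  m <- 1
  if (cov$sex == "female") m <- m * (1 + fc[["female"]])
  if (cov$race != "White") m <- m * (1 + fc[[cov$race]])
  if (cov$population != "HV") m <- m * (1 + fc[[cov$population]])
  m
}

#' Typical disposition parameters for a subject
#'
#' Applies the continuous power relations (age, weight) and categorical
#' fractional-change relations (sex, race, population) to the reference
#' clearance and central volume. `q` and `vp` carry no covariates.
#'
#' @param cov A [covariate_set()].
#' @param th A [theta_preset()] object.
#' @return A [disposition_params()] object.
#' @examples
#' typical_disposition(reference_subject(), theta_preset("FM"))
#' @export
typical_disposition <- function(cov, th) {
  stopifnot(inherits(cov, "covariate_set"), inherits(th, "theta_vector"))
  cl <- th$cl * (cov$age / th$age_ref)^th$age_cl *
    (cov$weight / th$weight_ref)^th$wt_cl * .fc_mult(th$fc_cl, cov)
  vc <- th$vc * (cov$age / th$age_ref)^th$age_vc *
    (cov$weight / th$weight_ref)^th$wt_vc * .fc_mult(th$fc_vc, cov)
  disposition_params(cl = cl, vc = vc, q = th$q, vp = th$vp)
}

#' Typical absorption parameters for a subject
#'
#' The absorption rate constant follows a power relation in dose and a
#' fractional-change capsule effect; the capsule formulation also lowers the
#' overall relative bioavailability. Lag time, zero-order duration and the
#' depot fraction carry no covariates.
#'
#' @inheritParams typical_disposition
#' @return An [absorption_params()] object (`frel = 1` for the tablet).
#' @examples
#' typical_absorption(reference_subject(), theta_preset("FM"))
#' @export
typical_absorption <- function(cov, th) {
  stopifnot(inherits(cov, "covariate_set"), inherits(th, "theta_vector"))
  caps <- cov$formulation == "capsule"
  ka <- th$ka * (cov$dose / th$dose_ref)^th$dose_ka_exp *
    (if (caps) 1 + th$fc_capsule_ka else 1)
  frel <- if (caps) 1 + th$fc_capsule_f else 1
  absorption_params(ka = ka, alag1 = th$alag1, d2 = th$d2, f1 = th$f1,
                    frel = frel)
}

#' Default covariate-impact scenarios
#'
#' Single-covariate perturbations of the reference subject: low/high weight
#' (56, 112 kg), low/high age (36, 79 years), female sex, the non-reference
#' race levels and the cancer populations.
#'
#' @param dose Dose (mg) carried by each scenario.
#' @return Named list of [covariate_set()] objects.
#' @export
impact_scenarios <- function(dose = 60) {
  ref <- reference_subject(dose)
  mod <- function(...) {
    args <- list(...)
    x <- unclass(ref)
    x[names(args)] <- args
    do.call(covariate_set, x)
  }
  list(REF = ref,
       LWT = mod(weight = 56), HWT = mod(weight = 112),
       LAGE = mod(age = 36), HAGE = mod(age = 79),
       Female = mod(sex = "female"),
       Black = mod(race = "Black"), Asian = mod(race = "Asian"),
       OtherRace = mod(race = "Other"),
       RCC = mod(population = "RCC"), CRPC = mod(population = "CRPC"),
       MTC = mod(population = "MTC"), GB = mod(population = "GB"),
       OTH = mod(population = "OTH"))
}

#' Covariate impact on clearance and steady-state exposure
#'
#' For each scenario, the ratio of typical CL/F, steady-state Cmax and
#' steady-state Cmin to the reference subject's values, from deterministic
#' simulation of typical parameters (no inter-individual or residual
#' variability).
#'
#' @param th A [theta_preset()] object.
#' @param scenarios Named list of [covariate_set()] objects; defaults to
#'   [impact_scenarios()].
#' @param dose Dose (mg) for the steady-state simulation.
#' @param tau Dosing interval (h).
#' @return Data frame with columns `scenario`, `cl_ratio`, `cmax_ss_ratio`,
#'   `cmin_ss_ratio`.
#' @examples
#' head(covariate_impact_table(theta_preset("FM")))
#' @export
covariate_impact_table <- function(th, scenarios = impact_scenarios(dose),
                                   dose = 60, tau = 24) {
  stopifnot(inherits(th, "theta_vector"))
  ref <- reference_subject(dose)
  ss_of <- function(cov) {
    dp <- typical_disposition(cov, th)
    ap <- typical_absorption(cov, th)
    c(cl = dp$cl, unlist(steady_state_metrics(ap, dp, dose, tau)))
  }
  base <- ss_of(ref)
  rows <- lapply(scenarios, function(cov) {
    m <- ss_of(cov)
    data.frame(cl_ratio = m[["cl"]] / base[["cl"]],
               cmax_ss_ratio = m[["cmax_ss"]] / base[["cmax_ss"]],
               cmin_ss_ratio = m[["cmin_ss"]] / base[["cmin_ss"]])
  })
  out <- do.call(rbind, rows)
  out <- cbind(scenario = names(scenarios), out)
  rownames(out) <- NULL
  out
}
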