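# Virtual pooled multi-study datasets: per-study designs (doses,
# formulations, sampling schedules) and demographic generators, simulated
# from the full population model into long-format dosing/observation records.


#' Specification of one clinical study design
#'
#' Holds everything needed to generate one study's virtual subjects: sample
#' size, population, dose/formulation assignment, dosing times, observation
#' schedule and demographic generator settings.
#'
#' @param id Study label.
#' @param n Number of subjects, > 0.
#' @param population Population level (see [covariate_set()]).
#' @param dose Dose amounts (mg); a vector is assigned cyclically across
#'   subjects (dose-ranging arms).
#' @param formulation Formulation per dose event (recycled over
#'   `dose_times`).
#' @param dose_times Dosing times (h), non-decreasing from 0.
#' @param obs_times Nominal observation times (h since first dose), >= 0.
#' @param sex_male_p Proportion of males, in \[0, 1\].
#' @param race_p Proportions over (White, Black, Asian, Other); must sum
#'   to 1.
#' @param age `c(mean, sd, min, max)` in years for the truncated-normal age
#'   generator.
#' @param weight `c(mean, sd, min, max)` in kg.
#' @return An object of class `"study_spec"`.
#' @export
study_spec <- function(id, n, population, dose, formulation, dose_times,
                       obs_times, sex_male_p, race_p, age, weight) {
  stopifnot(n > 0, length(obs_times) > 0, all(obs_times >= 0),
            length(dose_times) > 0, all(dose_times >= 0),
            !is.unsorted(dose_times))
  if (sex_male_p < 0 || sex_male_p > 1) {
    stop("sex_male_p must be in [0, 1]", call. = FALSE)
  }
  if (abs(sum(race_p) - 1) > 1e-8) {
    stop("race proportions must sum to 1", call. = FALSE)
  }
  for (v in list(age = age, weight = weight)) {
    if (length(v) != 4L || v[3] >= v[4] || v[1] < v[3] || v[1] > v[4]) {
      stop("age/weight must be c(mean, sd, min, max) with min < max and ",
           "mean inside the range", call. = FALSE)
    }
  }
  structure(list(id = as.character(id), n = as.integer(n),
                 population = population, dose = dose,
                 formulation = formulation, dose_times = dose_times,
                 obs_times = sort(obs_times), sex_male_p = sex_male_p,
                 race_p = stats::setNames(race_p, .race_levels),
                 age = age, weight = weight),
            class = "study_spec")
}

#' The nine-study design suite of the integrated analysis
#'
#' Encodes the pooled nine-study design: per-study sample sizes, doses,
#' formulations and planned PK sampling schedules, and per-study demographic
#' distributions (sex and race proportions, age and weight moments and
#' ranges). Sparse late-study visit rules are encoded as fixed nominal
#' pre-dose days; the crossover bioequivalence study is represented as two
#' single-dose periods (capsule then tablet) separated by a 28-day washout.
#' Race proportions are renormalised over the four recorded levels where a
#' study reported missing race.
#'
#' @return Named list of [study_spec()] objects totalling 1534 subjects.
#' @export
study_suite <- function() {
  rich <- c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12, 14, 24, 48, 72, 120, 168,
            240, 288, 336, 408, 504)
  d <- function(day) (day - 1) * 24
  list(
    `001` = study_spec("001", 40, "OTH", 140, "capsule",
      dose_times = seq(0, d(29), by = 24),
      obs_times = c(0, 0.5, 1, 2, 4, 8, 24, d(5), d(5) + 4, d(15),
                    d(19) + c(0, 0.5, 1, 2, 4, 8, 24), d(29)),
      sex_male_p = 0.775, race_p = c(0.875, 0.050, 0.025, 0.050),
      age = c(56.0, 11.0, 23, 71), weight = c(82.8, 15.9, 53.4, 116)),
    `010` = study_spec("010", 77, "HV", 140,
      formulation = c("capsule", "tablet"),
      dose_times = c(0, 672),
      obs_times = c(rich, 672 + rich),
      sex_male_p = 0.416, race_p = c(74, 2, 1, 0) / 77,
      age = c(39.3, 9.7, 18, 55), weight = c(71.9, 11.5, 46.1, 106)),
    `020` = study_spec("020", 63, "HV", c(20, 40, 60), "tablet",
      dose_times = 0, obs_times = rich,
      sex_male_p = 0.524, race_p = c(62, 1, 0, 0) / 63,
      age = c(36.9, 8.6, 19, 54), weight = c(76.4, 11.8, 58.1, 113.5)),
    `201` = study_spec("201", 39, "GB", 140, "capsule",
      dose_times = seq(0, d(85), by = 24),
      obs_times = c(0, 4, d(15) + c(0, 4), d(29) + c(0, 4), d(43) + c(0, 4),
                    d(57), d(85)),
      sex_male_p = 0.667, race_p = c(33, 3, 1, 1) / 38,
      age = c(48.6, 13.5, 20, 67), weight = c(81.4, 18.3, 52, 125.3)),
    `203` = study_spec("203", 284, "CRPC", 100, "capsule",
      dose_times = seq(0, d(169), by = 24),
      obs_times = d(c(1, 22, 43, 85, 127, 169)),
      sex_male_p = 1, race_p = c(246, 15, 14, 9) / 284,
      age = c(66.3, 8.8, 43, 87), weight = c(90.2, 18.6, 50.3, 182.9)),
    `301` = study_spec("301", 210, "MTC", 140, "capsule",
      dose_times = seq(0, d(29), by = 24),
      obs_times = c(0, 2, 4, 6, d(29) + c(0, 2, 4, 6)),
      sex_male_p = 0.695, race_p = c(188, 1, 9, 5) / 203,
      age = c(54.7, 13.3, 20, 86), weight = c(72.9, 18, 30.4, 137.9)),
    `306` = study_spec("306", 41, "CRPC", 60, "tablet",
      dose_times = seq(0, d(85), by = 24),
      obs_times = d(c(1, 22, 43, 85)),
      sex_male_p = 1, race_p = c(34, 4, 1, 2) / 41,
      age = c(64.8, 6.4, 48, 79), weight = c(89.3, 23.1, 57.5, 190.7)),
    `307` = study_spec("307", 498, "CRPC", 60, "tablet",
      dose_times = seq(0, d(85), by = 24),
      obs_times = d(c(22, 85)),
      sex_male_p = 1, race_p = c(380, 9, 1, 3) / 393,
      age = c(68.7, 7.6, 35, 87), weight = c(83.3, 14.0, 49.7, 140)),
    `308` = study_spec("308", 282, "RCC", 60, "tablet",
      dose_times = seq(0, d(57), by = 24),
      obs_times = c(d(29) + 14, d(57) + 14),
      sex_male_p = 0.787, race_p = c(231, 5, 19, 16) / 271,
      age = c(61.6, 9.5, 32, 86), weight = c(81.9, 17.0, 48.1, 155.7))
  )
}

# Truncated-normal sampling by inverse-CDF on the truncated uniform range.
.rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a virtual study population
#'
#' Draws `spec$n` subjects: sex and race by multinomial sampling at the
#' study proportions, age and weight from truncated normal distributions
#' (clipped to the study range), dose assigned cyclically over the study's
#' dose levels.
#'
#' @param spec A [study_spec()].
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @return Data frame, one row per subject: `ID`, `STUDY`, `AGE`, `WT`,
#'   `SEX`, `RACE`, `POP`, `DOSE`.
#' @export
build_virtual_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "study_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  data.frame(
    ID = paste0(spec$id, "-", seq_len(n)),
    STUDY = spec$id,
    AGE = .rtnorm(n, spec$age[1], spec$age[2], spec$age[3], spec$age[4]),
    WT = .rtnorm(n, spec$weight[1], spec$weight[2], spec$weight[3],
                 spec$weight[4]),
    SEX = ifelse(stats::runif(n) < spec$sex_male_p, "male", "female"),
    RACE = sample(.race_levels, n, replace = TRUE, prob = spec$race_p),
    POP = spec$population,
    DOSE = rep_len(spec$dose, n),
    stringsAsFactors = FALSE)
}

# Per-dose absorption parameters for one subject under a theta vector:
# dose-dependent ka and formulation-dependent ka/frel may differ per dose.
.subject_absorption <- function(th, cov, amts, forms) {
  caps <- forms == "capsule"
  ka <- th$ka * (amts / th$dose_ref)^th$dose_ka_exp *
    ifelse(caps, 1 + th$fc_capsule_ka, 1)
  frel <- ifelse(caps, 1 + th$fc_capsule_f, 1)
  list(ka = ka, frel = frel)
}

#' Simulate a pooled multi-study PK dataset
#'
#' For each study and subject: generate covariates, derive typical
#' parameters from the covariate model, apply inter-individual variability,
#' simulate the concentration profile at the scheduled observation times
#' under the study regimen, and add log-scale residual error. Observations
#' below the quantification limit are flagged (`BLQ = 1`) and marked
#' `MDV = 1` (retained in the dataset, excluded from estimation).
#'
#' @param specs A list of [study_spec()] objects (e.g. [study_suite()]).
#' @param th A [theta_preset()] parameter vector.
#' @param omega An [omega_matrix()].
#' @param rm A [residual_model()].
#' @param seed Integer seed.
#' @param lloq Lower limit of quantification (ng/mL).
#' @return Long-format data frame with columns `ID`, `STUDY`, `TIME`, `AMT`,
#'   `EVID`, `DV`, `MDV`, `BLQ`, `AGE`, `WT`, `SEX`, `RACE`, `POP`, `FORM`,
#'   `DOSE`. Dose records have `EVID = 1`, `AMT` set and `DV = NA`;
#'   observation records have `EVID = 0`.
#' @export
simulate_dataset <- function(specs, th, omega, rm, seed = 1L,
                             lloq = .lloq_default) {
  stopifnot(inherits(th, "theta_vector"), inherits(rm, "residual_model"))
  if (inherits(specs, "study_spec")) specs <- list(specs)
  set.seed(seed)
  sig <- sqrt(rm$sigma2)
  out <- vector("list", length(specs))
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    pop <- build_virtual_population(spec)
    etas <- draw_etas(spec$n, omega)
    forms <- rep_len(spec$formulation, length(spec$dose_times))
    rows <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      cov <- covariate_set(age = pop$AGE[i], weight = pop$WT[i],
                           sex = pop$SEX[i], race = pop$RACE[i],
                           population = pop$POP[i],
                           formulation = forms[1], dose = pop$DOSE[i])
      dp <- typical_disposition(cov, th)
      amts <- rep_len(pop$DOSE[i], length(spec$dose_times))
      ab <- .subject_absorption(th, cov, amts, forms)
      eta <- etas[i, ]
      conc <- .conc_kernel(spec$obs_times, spec$dose_times, amts,
                           ab$ka * exp(eta[1]), th$alag1, th$d2,
                           stats::plogis(stats::qlogis(th$f1) + eta[4]),
                           ab$frel,
                           dp$cl * exp(eta[2]), dp$vc * exp(eta[3]),
                           dp$q, dp$vp)
      dv <- ifelse(conc > 0,
                   conc * exp(stats::rnorm(length(conc), 0, sig)), 0)
      blq <- as.integer(dv < lloq)
      mdv <- blq
      # samples at or before the first dose carry no drug by construction;
      # they are recorded as missing (documented and excluded), not as
      # below-limit measurements
      pre <- spec$obs_times <= spec$dose_times[1]
      dv[pre] <- NA_real_
      blq[pre] <- 0L
      mdv[pre] <- 1L
      obs_form <- forms[pmax(1L,
        findInterval(spec$obs_times, spec$dose_times))]
      rec <- rbind(
        data.frame(ID = pop$ID[i], TIME = spec$dose_times, AMT = amts,
                   EVID = 1L, DV = NA_real_, MDV = 1L, BLQ = 0L,
                   FORM = forms, stringsAsFactors = FALSE),
        data.frame(ID = pop$ID[i], TIME = spec$obs_times, AMT = NA_real_,
                   EVID = 0L, DV = dv, MDV = mdv, BLQ = blq,
                   FORM = obs_form, stringsAsFactors = FALSE))
      rec <- rec[order(rec$TIME, -rec$EVID), ]
      rows[[i]] <- rec
    }
    st <- do.call(rbind, rows)
    st$STUDY <- spec$id
    covcols <- pop[match(st$ID, pop$ID),
                   c("AGE", "WT", "SEX", "RACE", "POP", "DOSE")]
    out[[si]] <- cbind(st[c("ID", "STUDY", "TIME", "AMT", "EVID", "DV",
                            "MDV", "BLQ", "FORM")], covcols)
  }
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  ds
}

.pk_columns <- c("ID", "STUDY", "TIME", "AMT", "EVID", "DV", "MDV", "BLQ",
                 "FORM", "AGE", "WT", "SEX", "RACE", "POP", "DOSE")

#' Validate a long-format PK dataset
#'
#' Checks the column contract, that every subject has at least one dose
#' record, that times are non-negative and non-decreasing within subject,
#' and that every quantifiable observation is at or above the limit of
#' quantification unless flagged `BLQ`.
#'
#' @param ds A data frame in the dialect produced by [simulate_dataset()].
#' @param lloq Lower limit of quantification (ng/mL).
#' @return Invisibly, `ds`.
#' @export
validate_dataset <- function(ds, lloq = .lloq_default) {
  missing_cols <- setdiff(.pk_columns, names(ds))
  if (length(missing_cols)) {
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sp <- split(ds, ds$ID)
  no_dose <- names(sp)[!vapply(sp, function(x) any(x$EVID == 1L), TRUE)]
  if (length(no_dose)) {
    stop("subject(s) without any dose record: ",
         paste(utils::head(no_dose, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(ds$TIME < 0)) stop("negative TIME values", call. = FALSE)
  bad <- names(sp)[vapply(sp, function(x) is.unsorted(x$TIME), TRUE)]
  if (length(bad)) {
    stop("non-monotone times within subject(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  obs <- ds[ds$EVID == 0L & !is.na(ds$DV), ]
  if (any(obs$DV < lloq & obs$BLQ != 1L)) {
    stop("observations below the quantification limit without BLQ flag",
         call. = FALSE)
  }
  invisible(ds)
}

#' Read / write a PK dataset as CSV
#'
#' Plain CSV with a header row, full numeric precision and '.' decimal
#' separator. `read_dataset()` validates the column contract on the way in.
#'
#' @param path File path.
#' @return `read_dataset()`: the validated data frame.
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(ds)
  ds
}

#' @rdname read_dataset
#' @param ds Dataset data frame.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  utils::write.csv(ds[.pk_columns], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Observations usable for estimation
#'
#' The estimation view of a dataset: observation records with `MDV = 0`
#' (quantifiable, non-missing). BLQ records are excluded.
#'
#' @param ds A validated PK dataset.
#' @return Data frame of usable observation rows.
#' @export
estimation_view <- function(ds) {
  ds[ds$EVID == 0L & ds$MDV == 0L & !is.na(ds$DV) & ds$DV > 0, ]
}

#' Read / write a model configuration
#'
#' Serialises a parameter vector, covariance matrix and residual variance to
#' a flat YAML map and back.
#'
#' @param th A [theta_preset()] object.
#' @param omega An [omega_matrix()].
#' @param rm A [residual_model()].
#' @param path File path.
#' @return `read_model_config()`: list with `theta`, `omega`, `rm`.
#' @export
write_model_config <- function(th, omega, rm, path) {
  stopifnot(inherits(th, "theta_vector"))
  x <- unclass(th)
  x$fc_cl <- as.list(th$fc_cl)
  x$fc_vc <- as.list(th$fc_vc)
  yaml::write_yaml(list(theta = x,
                        omega = apply(unclass(omega), 1L, as.list),
                        sigma2 = rm$sigma2), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  tv <- x$theta
  tv$fc_cl <- unlist(tv$fc_cl)[.fc_levels]
  tv$fc_vc <- unlist(tv$fc_vc)[.fc_levels]
  th <- do.call(.theta_new, tv)
  om <- matrix(unlist(x$omega), 4L, 4L, byrow = TRUE,
               dimnames = list(.eta_names, .eta_names))
  validate_omega(om)
  class(om) <- c("omega_matrix", class(om))
  list(theta = th, omega = om, rm = residual_model(x$sigma2))
}
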