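# Independent numerical oracles and small design builders shared by the
# test files. The ODE oracle integrates the compartmental system with a
# stiff-capable solver; the quadrature oracle evaluates the marginal
# likelihood of a one-random-effect model by adaptive Gauss-Hermite
# quadrature. Both are written against the model equations directly, not
# against the package internals they check.

library(deSolve)
library(pracma)

# depot / central / peripheral amounts; lagged depot bolus via an event,
# zero-order input as a time-switched infusion rate
ode_conc_oracle <- function(dose, ap, dp, tout) {
  k10 <- dp$cl / dp$vc; k12 <- dp$q / dp$vc; k21 <- dp$q / dp$vp
  da <- ap$f1 * ap$frel * dose
  r0 <- (1 - ap$f1) * ap$frel * dose / ap$d2
  rhs <- function(t, y, p) {
    inz <- if (t < ap$d2) r0 else 0
    list(c(-ap$ka * y[1],
           ap$ka * y[1] + inz - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  ev <- data.frame(var = "A0", time = ap$alag1, value = da, method = "add")
  tt <- sort(unique(c(0, ap$alag1, ap$d2, tout)))
  out <- lsoda(c(A0 = 0, A1 = 0, A2 = 0), tt, rhs, NULL,
               rtol = 1e-10, atol = 1e-12, events = list(data = ev))
  1000 * out[match(tout, out[, 1]), "A1"] / dp$vc
}

# -2 log marginal likelihood by adaptive 21-node Gauss-Hermite quadrature
# for a model with a single log-normal random effect on CL/F
agq_ofv_oracle <- function(ds, th, omega_cl, sigma2) {
  gh <- pracma::gaussHermite(21)
  total <- 0
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id & ds$EVID == 0 & ds$MDV == 0, ]
    dose <- ds[ds$ID == id & ds$EVID == 1, ]
    cov <- covariate_set(age = sub$AGE[1], weight = sub$WT[1],
                         sex = sub$SEX[1], race = sub$RACE[1],
                         population = sub$POP[1],
                         formulation = dose$FORM[1], dose = sub$DOSE[1])
    dp <- typical_disposition(cov, th)
    ap <- typical_absorption(cov, th)
    reg <- regimen(dose$TIME, dose$AMT, dose$FORM)
    f <- function(e) vapply(e, function(x) {
      dpx <- disposition_params(dp$cl * exp(x), dp$vc, dp$q, dp$vp)
      C <- conc_profile(reg, ap, dpx, sub$TIME)$conc
      (sum(log(2 * pi * sigma2) + (log(sub$DV) - log(C))^2 / sigma2) +
         log(2 * pi) + log(omega_cl) + x^2 / omega_cl) / 2
    }, 0)
    opt <- stats::optimize(f, c(-6, 6), tol = 1e-10)
    h <- (f(opt$minimum + 1e-4) - 2 * opt$objective +
            f(opt$minimum - 1e-4)) / 1e-8
    s <- 1 / sqrt(h)
    x <- opt$minimum + sqrt(2) * s * gh$x
    integ <- sqrt(2) * s * sum(gh$w * exp(gh$x^2 - (f(x) - opt$objective)))
    total <- total - 2 * (log(integ) - opt$objective)
  }
  total
}

fm_theta <- function() theta_preset("FM")
fm_ap <- function() absorption_params(0.979, 0.784, 2.4, 0.854)
fm_dp <- function() disposition_params(2.478, 187.0, 31.213, 195.1)

rich_times <- function() c(0.5, 1, 2, 3, 4, 5, 6, 8, 10, 12, 14, 24, 48,
                           72, 120, 168, 240, 336, 504)

hv_spec <- function(n, obs_times = rich_times(), dose = 60,
                    dose_times = 0, id = "hv") {
  study_spec(id, n, "HV", dose, "tablet", dose_times, obs_times,
             sex_male_p = 0.5, race_p = c(1, 0, 0, 0),
             age = c(40, 10, 18, 60), weight = c(80, 12, 50, 120))
}

# random but valid parameter draws around the typical values (fixed seed
# set by the caller)
draw_random_params <- function() {
  lp <- function(m) m * exp(stats::rnorm(1, 0, 0.3))
  list(ap = absorption_params(ka = lp(0.979), alag1 = stats::runif(1, 0, 1.5),
                              d2 = lp(2.4), f1 = stats::runif(1, 0.5, 0.95),
                              frel = stats::runif(1, 0.7, 1)),
       dp = disposition_params(cl = lp(2.478), vc = lp(187), q = lp(31.2),
                               vp = lp(195)))
}

# truth used by the covariate-detection and eta-trend experiments: reference
# structural values, a single MTC effect on CL/F, IIV on CL/F only
mtc_truth_theta <- function(with_effect = TRUE) {
  th <- theta_preset("FM")
  th$fc_cl[] <- 0; th$fc_vc[] <- 0
  th$age_cl <- 0; th$wt_cl <- 0; th$age_vc <- 0; th$wt_vc <- 0
  if (with_effect) th$fc_cl[["MTC"]] <- 0.928
  th
}

mtc_detection_specs <- function(n_hv = 120, n_mtc = 30) {
  obs <- c(2, 4, 6, 8, 672, 674, 676, 678, 696)
  qd <- seq(0, 672, by = 24)
  demo <- list(age = c(55, 10, 20, 80), weight = c(80, 12, 50, 120))
  list(study_spec("hv", n_hv, "HV", 60, "tablet", qd, obs, 0.5,
                  c(1, 0, 0, 0), demo$age, demo$weight),
       study_spec("mtc", n_mtc, "MTC", 60, "tablet", qd, obs, 0.5,
                  c(1, 0, 0, 0), demo$age, demo$weight))
}

# degenerate demographics: every generated subject IS the reference subject
ref_spec <- function(n, obs_times = rich_times(), dose = 60,
                     dose_times = 0, id = "ref") {
  study_spec(id, n, "HV", dose, "tablet", dose_times, obs_times,
             sex_male_p = 1, race_p = c(1, 0, 0, 0),
             age = c(60, 0, 59, 61), weight = c(80, 0, 79, 81))
}
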