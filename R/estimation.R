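# Marginal-likelihood estimation by the Laplace approximation: per-subject
# MAP optimisation of the random effects, objective function value (OFV,
# -2 log approximate marginal likelihood), outer optimisation over
# transformed fixed effects and variance components, and likelihood-ratio
# comparison of nested covariate structures.

.struct_log <- c("ka", "d2", "cl", "vc", "q", "vp", "alag1")
.exp_pars <- c("dose_ka_exp", "age_cl", "wt_cl", "age_vc", "wt_vc")
.fc_pars <- c("fc_capsule_ka", "fc_capsule_f",
              paste0("fc_cl.", .fc_levels), paste0("fc_vc.", .fc_levels))
.omega_pars <- paste0("omega_", .eta_names)
.all_pars <- c(.struct_log, "f1", .exp_pars, .fc_pars, .omega_pars, "sigma2")

# transform to the unconstrained estimation scale and back
.t_fwd <- function(name, v) {
  if (name %in% c(.struct_log, .omega_pars, "sigma2")) return(log(v))
  if (name == "f1") return(stats::qlogis(v))
  if (name %in% .fc_pars) return(log1p(v))
  v
}
.t_inv <- function(name, tv) {
  if (name %in% c(.struct_log, .omega_pars, "sigma2")) return(exp(tv))
  if (name == "f1") return(stats::plogis(tv))
  if (name %in% .fc_pars) return(expm1(tv))
  tv
}

.get_par <- function(th, omega, sigma2, name) {
  if (name %in% .omega_pars) {
    return(unclass(omega)[sub("omega_", "", name), sub("omega_", "", name)])
  }
  if (name == "sigma2") return(sigma2)
  if (startsWith(name, "fc_cl.")) return(th$fc_cl[[sub("fc_cl.", "", name)]])
  if (startsWith(name, "fc_vc.")) return(th$fc_vc[[sub("fc_vc.", "", name)]])
  th[[name]]
}

# setting an omega variance rescales its covariances to preserve correlation
.set_par <- function(state, name, value) {
  if (name %in% .omega_pars) {
    k <- sub("omega_", "", name)
    om <- unclass(state$omega)
    old <- om[k, k]
    sc <- if (old > 0) sqrt(value / old) else 0
    om[k, ] <- om[k, ] * sc
    om[, k] <- om[, k] * sc
    om[k, k] <- value
    class(om) <- c("omega_matrix", "matrix", "array")
    state$omega <- om
  } else if (name == "sigma2") {
    state$sigma2 <- value
  } else if (startsWith(name, "fc_cl.")) {
    state$theta$fc_cl[[sub("fc_cl.", "", name)]] <- value
  } else if (startsWith(name, "fc_vc.")) {
    state$theta$fc_vc[[sub("fc_vc.", "", name)]] <- value
  } else {
    state$theta[[name]] <- value
  }
  state
}

#' Model configuration for estimation
#'
#' Declares which parameters are estimated, which random effects are active,
#' and the covariate structure label. The three published structures are
#' nested: `BASE` (no demographic or population covariates) within `FMECT`
#' (demographics on CL/F and Vc/F) within `FM` (demographics and cancer
#' type). The covariate structure itself is carried by the parameter vector
#' (a zero coefficient is an absent effect); the configuration controls
#' what the optimiser may move.
#'
#' @param estimate Character vector of parameter names to estimate. Valid
#'   names: structural (`ka`, `d2`, `cl`, `vc`, `q`, `vp`, `alag1`, `f1`),
#'   exponents (`dose_ka_exp`, `age_cl`, `wt_cl`, `age_vc`, `wt_vc`),
#'   fractional changes (`fc_capsule_ka`, `fc_capsule_f`, `fc_cl.<level>`,
#'   `fc_vc.<level>` with level among female, Black, Asian, Other, RCC,
#'   CRPC, MTC, GB, OTH), variances (`omega_ka`, `omega_cl`, `omega_vc`,
#'   `omega_f1`, `sigma2`).
#' @param random Random-effect names active in the likelihood (subset of
#'   `ka`, `cl`, `vc`, `f1`); effects with zero variance are dropped
#'   automatically.
#' @param name Structure label (`"FM"`, `"FMECT"`, `"BASE"` or free text).
#' @return An object of class `"model_config"`.
#' @examples
#' model_config(estimate = c("cl", "vc", "omega_cl", "sigma2"))
#' @export
model_config <- function(estimate = c("cl", "vc"),
                         random = c("ka", "cl", "vc", "f1"),
                         name = "FM") {
  bad <- setdiff(estimate, .all_pars)
  if (length(bad)) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(random %in% .eta_names))
  structure(list(estimate = estimate, random = random, name = name),
            class = "model_config")
}

# Per-subject estimation cache: observation times/log-DV, dosing, covariates.
.prep_subjects <- function(data) {
  validate_dataset(data)
  obs <- estimation_view(data)
  sp_obs <- split(obs, obs$ID)
  sp_all <- split(data, data$ID)
  ids <- names(sp_all)
  lapply(stats::setNames(ids, ids), function(id) {
    d <- sp_all[[id]]
    dose <- d[d$EVID == 1L, ]
    o <- sp_obs[[id]]
    list(id = id,
         tobs = if (is.null(o)) numeric() else o$TIME,
         ldv = if (is.null(o)) numeric() else log(o$DV),
         dose_times = dose$TIME, amts = dose$AMT, forms = dose$FORM,
         cov = covariate_set(age = d$AGE[1], weight = d$WT[1],
                             sex = d$SEX[1], race = d$RACE[1],
                             population = d$POP[1],
                             formulation = dose$FORM[1], dose = d$DOSE[1]))
  })
}

# typical parameters under th for one prepared subject
.subject_typ <- function(th, sub) {
  dp <- typical_disposition(sub$cov, th)
  ab <- .subject_absorption(th, sub$cov, sub$amts, sub$forms)
  list(ka = ab$ka, frel = ab$frel, f1 = th$f1, lf1 = stats::qlogis(th$f1),
       alag1 = th$alag1, d2 = th$d2, cl = dp$cl, vc = dp$vc, q = dp$q,
       vp = dp$vp)
}

# -2 log joint density of (observations, eta) for one subject; eta_act are
# the active random effects, expanded to the (ka, cl, vc, f1) order.
.subject_nll2 <- function(eta_act, sub, typ, sigma2, oinv, logdet_o,
                          act_idx) {
  eta <- numeric(4L)
  eta[act_idx] <- eta_act
  conc <- .conc_kernel(sub$tobs, sub$dose_times, sub$amts,
                       typ$ka * exp(eta[1L]), typ$alag1, typ$d2,
                       stats::plogis(typ$lf1 + eta[4L]), typ$frel,
                       typ$cl * exp(eta[2L]), typ$vc * exp(eta[3L]),
                       typ$q, typ$vp)
  if (any(conc <= 0)) return(1e10 + sum(eta_act^2))
  r <- sub$ldv - log(conc)
  d <- length(eta_act)
  sum(log(2 * pi * sigma2) + r * r / sigma2) +
    d * log(2 * pi) + logdet_o +
    drop(eta_act %*% oinv %*% eta_act)
}

# central-difference Hessian
.fd_hess <- function(fn, x, f0 = fn(x)) {
  p <- length(x)
  h <- 1e-4 * (1 + abs(x))
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

.chol_logdet <- function(H) {
  ridge <- 0
  for (k in 0:6) {
    ch <- tryCatch(chol(H + diag(ridge, nrow(H))), error = function(e) NULL)
    if (!is.null(ch)) return(2 * sum(log(diag(ch))))
    ridge <- if (ridge == 0) 1e-8 * (1 + max(abs(diag(H)))) else ridge * 100
  }
  stop("inner Hessian could not be regularised", call. = FALSE)
}

#' -2 log joint likelihood of one subject's data and random effects
#'
#' The quantity minimised over `eta` in the inner (MAP) step of the Laplace
#' approximation: the sum of the -2 log Gaussian densities of the observed
#' log concentrations around the model prediction and of `eta` around zero
#' under `omega`. A non-positive model prediction at an observation time
#' yields a large finite penalty rather than a non-finite value.
#'
#' @param eta Random-effect vector, ordered (ka, cl, vc, f1).
#' @param subject Data-frame slice of one subject (dose and observation
#'   rows, PK dataset dialect).
#' @param th A [theta_preset()] parameter vector.
#' @param omega An [omega_matrix()]; a semidefinite matrix is ridged by
#'   1e-8.
#' @param rm A [residual_model()] with `sigma2 > 0`.
#' @return Scalar -2 log joint density.
#' @export
individual_joint_nll <- function(eta, subject, th, omega, rm) {
  stopifnot(inherits(rm, "residual_model"), rm$sigma2 > 0,
            length(eta) == 4L)
  sub <- .prep_subjects(subject)[[1L]]
  if (length(sub$tobs) == 0L) {
    stop("subject has no usable observation", call. = FALSE)
  }
  om <- unclass(omega)
  ch <- tryCatch(chol(om), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(om + diag(1e-8, 4L))
  oinv <- chol2inv(ch)
  .subject_nll2(eta, sub, .subject_typ(th, sub), rm$sigma2, oinv,
                2 * sum(log(diag(ch))), 1:4)
}

# MAP optimisation for one subject with deterministic jittered restarts
.inner_map <- function(sub, typ, sigma2, oinv, logdet_o, act_idx, start) {
  fn <- function(e) .subject_nll2(e, sub, typ, sigma2, oinv, logdet_o,
                                  act_idx)
  d <- length(act_idx)
  best <- NULL
  starts <- list(start, numeric(d), rep(0.5, d), rep(-0.5, d))
  for (s in starts) {
    opt <- stats::nlminb(s, fn, control = list(iter.max = 100L))
    if (is.null(best) || opt$objective < best$objective - 1e-8) best <- opt
    if (best$objective < 1e9 && opt$convergence == 0 &&
        identical(s, start)) break
  }
  H <- .fd_hess(fn, best$par, best$objective) / 2
  list(par = best$par, g2 = best$objective, logdet_h = .chol_logdet(H),
       ok = best$objective < 1e9)
}

#' Laplace objective function value
#'
#' For each subject, minimises [individual_joint_nll()] over the active
#' random effects from a warm start (zero on the first pass), then applies
#' the Laplace correction using a central-difference Hessian:
#' `OFV = sum_i [ g2_i(eta_hat) - d log(2 pi) + log det H_i ]` with `H_i`
#' the Hessian of half the joint -2 log likelihood. Deterministic given the
#' data; subject order does not affect the value.
#'
#' @param th A [theta_preset()] parameter vector.
#' @param omega An [omega_matrix()].
#' @param rm A [residual_model()].
#' @param data A validated PK dataset (or a pre-built subject cache from a
#'   previous call, via the `prep` attribute of the result).
#' @param random Active random-effect names.
#' @param warm Optional matrix of starting eta values (subjects x 4).
#' @return List: `ofv`, `etas` (subjects x 4 MAP values, zero columns for
#'   inactive effects), `flagged` (ids whose inner step hit the positivity
#'   penalty).
#' @export
laplace_ofv <- function(th, omega, rm, data, random = c("ka", "cl", "vc",
                                                        "f1"),
                        warm = NULL) {
  prep <- if (is.list(data) && !is.data.frame(data) &&
              !is.null(attr(data, "prepped"))) data else {
    p <- .prep_subjects(data)
    attr(p, "prepped") <- TRUE
    p
  }
  .laplace_core(th, unclass(omega), rm$sigma2, prep, random, warm)
}

.laplace_core <- function(th, om, sigma2, prep, random, warm = NULL) {
  act_idx <- which(.eta_names %in% random & diag(om) > 0)
  d <- length(act_idx)
  n <- length(prep)
  etas <- matrix(0, n, 4L, dimnames = list(names(prep), .eta_names))
  if (d == 0L || sigma2 <= 0) {
    # degenerate: fixed-effects -2LL only
    ofv <- 0
    for (i in seq_len(n)) {
      sub <- prep[[i]]
      if (length(sub$tobs) == 0L) next
      typ <- .subject_typ(th, sub)
      ofv <- ofv + .subject_nll2(numeric(0L), sub, typ, sigma2, matrix(0, 0, 0),
                                 0, integer(0L))
    }
    return(list(ofv = ofv, etas = etas, flagged = character()))
  }
  oa <- om[act_idx, act_idx, drop = FALSE]
  ch <- tryCatch(chol(oa), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(oa + diag(1e-8, d))
  oinv <- chol2inv(ch)
  logdet_o <- 2 * sum(log(diag(ch)))
  ofv <- 0
  flagged <- character()
  for (i in seq_len(n)) {
    sub <- prep[[i]]
    if (length(sub$tobs) == 0L) next
    typ <- .subject_typ(th, sub)
    start <- if (is.null(warm)) numeric(d) else warm[i, act_idx]
    r <- .inner_map(sub, typ, sigma2, oinv, logdet_o, act_idx, start)
    if (!r$ok) flagged <- c(flagged, sub$id)
    etas[i, act_idx] <- r$par
    ofv <- ofv + r$g2 - d * log(2 * pi) + r$logdet_h
  }
  list(ofv = ofv, etas = etas, flagged = flagged)
}

#' Fit the population model by Laplace marginal likelihood
#'
#' Outer quasi-Newton optimisation (via [stats::nlminb()]) of the Laplace
#' objective over the transformed scale of the parameters named in
#' `config$estimate` (log for positive structural parameters and variances,
#' logit for `f1`, log(1 + fc) for fractional changes, identity for power
#' exponents). Parameters not named are fixed at their `start` values. MAP
#' random effects are warm-started across outer iterations.
#'
#' @param data A PK dataset (dialect of [simulate_dataset()]).
#' @param config A [model_config()].
#' @param start A [theta_preset()] vector of starting/fixed values.
#' @param omega Starting/fixed [omega_matrix()].
#' @param sigma2 Starting/fixed residual variance.
#' @param hessian If `TRUE`, compute the covariance of the estimates as
#'   twice the inverse central-difference Hessian of the OFV on the
#'   transformed scale (needed by [posterior_predictive_check()]).
#' @param control Passed to [stats::nlminb()] (defaults:
#'   `rel.tol = 1e-7`, `iter.max = 200`, `eval.max = 600`).
#' @return An object of class `"poppk_fit"`; see [summary.poppk_fit()].
#' @examples
#' \donttest{
#' th <- theta_preset("FM")
#' suite <- list(study_spec("demo", 12, "HV", 60, "tablet", 0,
#'   c(1, 2, 4, 8, 24, 72, 168), 0.5, c(1, 0, 0, 0),
#'   c(40, 10, 18, 60), c(80, 12, 50, 120)))
#' ds <- simulate_dataset(suite, th, omega_matrix(cl_vc_corr = 0),
#'                        residual_model(0.118), seed = 7)
#' fit <- poppk_fit(ds, model_config(estimate = c("cl", "vc")), start = th)
#' coef(fit)
#' }
#' @export
poppk_fit <- function(data, config = model_config(), start = theta_preset("FM"),
                      omega = omega_matrix(cl_vc_corr = 0), sigma2 = 0.118,
                      hessian = FALSE, control = list()) {
  stopifnot(inherits(config, "model_config"),
            inherits(start, "theta_vector"))
  prep <- .prep_subjects(data)
  attr(prep, "prepped") <- TRUE
  ctl <- utils::modifyList(list(rel.tol = 1e-7, iter.max = 200L,
                                eval.max = 600L), control)
  est <- config$estimate
  state0 <- list(theta = start, omega = unclass(omega), sigma2 = sigma2)
  tpar0 <- vapply(est, function(nm)
    .t_fwd(nm, .get_par(start, omega, sigma2, nm)), 0)
  ev <- new.env(parent = emptyenv())
  ev$warm <- NULL
  build_state <- function(tpar) {
    st <- state0
    for (j in seq_along(est)) st <- .set_par(st, est[j], .t_inv(est[j],
                                                                tpar[j]))
    st
  }
  obj <- function(tpar) {
    st <- build_state(tpar)
    r <- .laplace_core(st$theta, st$omega, st$sigma2, prep, config$random,
                       warm = ev$warm)
    ev$warm <- r$etas
    r$ofv
  }
  opt <- if (length(est)) {
    stats::nlminb(tpar0, obj, control = ctl)
  } else {
    list(par = tpar0, objective = obj(tpar0), convergence = 0L,
         message = "no free parameters")
  }
  st <- build_state(opt$par)
  final <- .laplace_core(st$theta, st$omega, st$sigma2, prep, config$random,
                         warm = ev$warm)
  vc <- NULL
  if (hessian && length(est)) {
    H <- .fd_hess(obj, opt$par, opt$objective)
    vc <- tryCatch(2 * solve(H), error = function(e) {
      warning("OFV Hessian is singular; covariance unavailable",
              call. = FALSE)
      NULL
    })
    if (!is.null(vc)) dimnames(vc) <- list(est, est)
  }
  class(st$omega) <- c("omega_matrix", "matrix", "array")
  structure(list(theta = st$theta, omega = st$omega, sigma2 = st$sigma2,
                 config = config, estimate = est,
                 par = stats::setNames(opt$par, est),
                 ofv = final$ofv, map_etas = final$etas,
                 flagged = final$flagged,
                 convergence = opt$convergence,
                 message = opt$message,
                 vcov = vc, data = data,
                 n_subjects = length(prep),
                 n_obs = sum(vapply(prep, function(s) length(s$tobs), 0L))),
            class = "poppk_fit")
}

#' Construct a fit object at known parameters
#'
#' Builds a `poppk_fit` at given (typically true, simulation) parameter
#' values without optimisation: MAP random effects and the OFV are computed
#' at the supplied parameters. Useful for simulation studies and
#' self-consistency diagnostics.
#'
#' @inheritParams poppk_fit
#' @param theta A [theta_preset()] parameter vector.
#' @param vcov Covariance of the (transformed) estimates for the smoothed
#'   parametric bootstrap; defaults to a zero matrix over
#'   `config$estimate` (no parameter uncertainty).
#' @return A `"poppk_fit"` object.
#' @export
poppk_fit_known <- function(data, theta, omega = omega_matrix(cl_vc_corr = 0),
                            sigma2 = 0.118, config = model_config(),
                            vcov = NULL) {
  prep <- .prep_subjects(data)
  attr(prep, "prepped") <- TRUE
  r <- .laplace_core(theta, unclass(omega), sigma2, prep, config$random)
  est <- config$estimate
  if (is.null(vcov)) {
    vcov <- matrix(0, length(est), length(est), dimnames = list(est, est))
  }
  structure(list(theta = theta, omega = omega, sigma2 = sigma2,
                 config = config, estimate = est,
                 par = vapply(est, function(nm)
                   .t_fwd(nm, .get_par(theta, omega, sigma2, nm)), 0),
                 ofv = r$ofv, map_etas = r$etas, flagged = r$flagged,
                 convergence = 0L, message = "evaluated at given parameters",
                 vcov = vcov, data = data, n_subjects = length(prep),
                 n_obs = sum(vapply(prep, function(s) length(s$tobs), 0L))),
            class = "poppk_fit")
}

#' Likelihood-ratio comparison of nested fits
#'
#' @param fit_reduced,fit_full `"poppk_fit"` objects whose estimated
#'   parameter sets are nested (`fit_reduced$estimate` a subset of
#'   `fit_full$estimate`).
#' @return List: `delta_ofv` (reduced minus full), `df` (difference in
#'   number of estimated parameters) and `lrt_p` (upper chi-square tail).
#' @examples
#' \donttest{
#' # compare_nested(fit_base, fit_full)
#' }
#' @export
compare_nested <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "poppk_fit"), inherits(fit_full,
                                                         "poppk_fit"))
  if (!all(fit_reduced$estimate %in% fit_full$estimate)) {
    stop("models are not nested: reduced fit estimates parameters absent ",
         "from the full fit", call. = FALSE)
  }
  df <- length(fit_full$estimate) - length(fit_reduced$estimate)
  delta <- fit_reduced$ofv - fit_full$ofv
  p <- if (df == 0L) {
    if (abs(delta) <= 1e-6) 1 else NA_real_
  } else {
    stats::pchisq(max(delta, 0), df = df, lower.tail = FALSE)
  }
  list(delta_ofv = delta, df = df, lrt_p = p)
}
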