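# Closed-form two-compartment disposition with dual (lagged first-order +
# zero-order) oral absorption. All quantities use the fixed unit convention:
# dose mg, volume L, flow L/h, time h, concentration ng/mL (mg/L * 1000).

#' Disposition parameters for the two-compartment model
#'
#' Apparent (dose-normalised by bioavailability) disposition parameters of the
#' two-compartment model with first-order elimination from the central
#' compartment.
#'
#' @param cl Apparent clearance CL/F (L/h), > 0.
#' @param vc Apparent central volume Vc/F (L), > 0.
#' @param q Apparent inter-compartmental flow Q/F (L/h), > 0. `q = 0` is
#'   accepted only as the one-compartment reduction used by
#'   [terminal_half_life()].
#' @param vp Apparent peripheral volume Vp/F (L), > 0.
#' @return An object of class `"disposition_params"`.
#' @examples
#' disposition_params(cl = 2.478, vc = 187.0, q = 31.213, vp = 195.1)
#' @export
disposition_params <- function(cl, vc, q, vp) {
  stopifnot(is.numeric(cl), is.numeric(vc), is.numeric(q), is.numeric(vp))
  if (!(cl > 0) || !(vc > 0) || !(vp > 0) || q < 0 ||
      !all(is.finite(c(cl, vc, q, vp)))) {
    stop("invalid disposition parameters: cl, vc, vp must be > 0 and q >= 0",
         call. = FALSE)
  }
  structure(list(cl = cl, vc = vc, q = q, vp = vp),
            class = "disposition_params")
}

#' Absorption parameters for the dual-input oral model
#'
#' The bioavailable dose `frel * amount` is split between a lagged first-order
#' depot (fraction `f1`, rate constant `ka`, lag `alag1`) and a zero-order
#' input of duration `d2` into the central compartment starting at dose time.
#'
#' @param ka First-order absorption rate constant (1/h), > 0.
#' @param alag1 Lag time of the first-order depot (h), >= 0.
#' @param d2 Duration of the zero-order input (h), > 0.
#' @param f1 Fraction of the bioavailable dose routed to the first-order
#'   depot, in (0, 1).
#' @param frel Relative bioavailability multiplier (tablet reference 1), > 0.
#' @return An object of class `"absorption_params"`.
#' @examples
#' absorption_params(ka = 0.979, alag1 = 0.784, d2 = 2.4, f1 = 0.854)
#' @export
absorption_params <- function(ka, alag1, d2, f1, frel = 1) {
  if (!(ka > 0) || alag1 < 0 || !(d2 > 0) || !(f1 > 0 && f1 < 1) ||
      !(frel > 0) || !all(is.finite(c(ka, alag1, d2, f1, frel)))) {
    stop("invalid absorption parameters: need ka > 0, alag1 >= 0, d2 > 0, ",
         "0 < f1 < 1, frel > 0", call. = FALSE)
  }
  structure(list(ka = ka, alag1 = alag1, d2 = d2, f1 = f1, frel = frel),
            class = "absorption_params")
}

#' Dosing regimen
#'
#' An ordered set of oral dose events.
#'
#' @param time Dose times (h since first dose), non-decreasing, >= 0.
#' @param amount Dose amounts (mg free-base equivalents), > 0. Recycled.
#' @param formulation `"tablet"` or `"capsule"`. Recycled.
#' @return A data frame of class `"regimen"` with columns `time`, `amount`,
#'   `formulation`.
#' @examples
#' regimen(time = seq(0, 672, by = 24), amount = 60)
#' @export
regimen <- function(time, amount, formulation = "tablet") {
  if (length(time) == 0L) {
    return(structure(data.frame(time = numeric(), amount = numeric(),
                                formulation = character()),
                     class = c("regimen", "data.frame")))
  }
  if (any(time < 0) || is.unsorted(time)) {
    stop("dose times must be >= 0 and non-decreasing", call. = FALSE)
  }
  amount <- rep_len(amount, length(time))
  formulation <- rep_len(formulation, length(time))
  if (any(amount <= 0)) stop("dose amounts must be > 0", call. = FALSE)
  if (!all(formulation %in% c("tablet", "capsule"))) {
    stop("formulation must be 'tablet' or 'capsule'", call. = FALSE)
  }
  structure(data.frame(time = time, amount = amount,
                       formulation = formulation,
                       stringsAsFactors = FALSE),
            class = c("regimen", "data.frame"))
}

# Micro/macro constant bookkeeping. Returns k10, k12, k21, alpha, beta with
# alpha > beta > 0. A numerically coincident alpha == beta (measure-zero,
# e.g. hand-picked k10 == k21 with q ~ 0) is resolved by a deterministic
# 1e-7 relative perturbation of q so the distinct-root formulas stay valid.
.disp_constants <- function(cl, vc, q, vp) {
  for (i in 1:2) {
    k10 <- cl / vc
    k12 <- q / vc
    k21 <- q / vp
    s <- k10 + k12 + k21
    p <- k10 * k21
    disc2 <- s * s - 4 * p
    disc <- sqrt(max(disc2, 0))
    if (disc >= 1e-10 * s) break
    q <- q * (1 + 1e-7) + 1e-12
  }
  alpha <- (s + disc) / 2
  beta <- p / alpha
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

#' Hybrid (macro) disposition constants
#'
#' Converts clearance/volume parameters to the micro rate constants
#' `k10 = cl/vc`, `k12 = q/vc`, `k21 = q/vp` and the hybrid exponents
#' `alpha > beta > 0` (roots of `s^2 - (k10+k12+k21) s + k10 k21`).
#'
#' @param dp A [disposition_params()] object with `q > 0`.
#' @return Named list with `alpha`, `beta`, `k10`, `k12`, `k21` (all 1/h).
#' @examples
#' hybrid_disposition_constants(
#'   disposition_params(cl = 2.478, vc = 187.0, q = 31.213, vp = 195.1))
#' @export
hybrid_disposition_constants <- function(dp) {
  stopifnot(inherits(dp, "disposition_params"))
  if (!(dp$q > 0)) stop("q must be > 0 for the two-compartment constants",
                        call. = FALSE)
  k <- .disp_constants(dp$cl, dp$vc, dp$q, dp$vp)
  list(alpha = k$alpha, beta = k$beta, k10 = k$k10, k12 = k$k12, k21 = k$k21)
}

# Vectorised concentration kernel. tobs: observation times (h). dose_times,
# amts: one entry per dose; ka, frel may be per-dose vectors (dose- and
# formulation-dependent absorption). Returns ng/mL at tobs.
.conc_kernel <- function(tobs, dose_times, amts, ka, alag1, d2, f1, frel,
                         cl, vc, q, vp) {
  n_t <- length(tobs)
  n_d <- length(dose_times)
  if (n_d == 0L) return(numeric(n_t))
  k <- .disp_constants(cl, vc, q, vp)
  alpha <- k$alpha; beta <- k$beta; k21 <- k$k21
  ka <- rep_len(ka, n_d)
  frel <- rep_len(frel, n_d)
  # ka coinciding with a hybrid exponent hits a 0/0 branch; deterministic
  # relative perturbation keeps the distinct-rate closed form valid.
  deg <- abs(ka - alpha) < 1e-8 * alpha | abs(ka - beta) < 1e-8 * beta
  if (any(deg)) ka[deg] <- ka[deg] * (1 + 1e-7)

  da <- f1 * frel * amts          # first-order depot dose, per dose
  r0 <- (1 - f1) * frel * amts / d2  # zero-order rate, per dose

  U <- outer(-dose_times, tobs, `+`)   # n_d x n_t, time since each dose
  TP <- U - alag1                      # time since end of lag
  TPc <- pmax(TP, 0)
  Uc <- pmax(U, 0)

  A <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
  B <- (k21 - beta) / ((ka - beta) * (alpha - beta))
  CC <- (k21 - ka) / ((alpha - ka) * (beta - ka))
  oral <- (ka * da / vc) *
    (A * exp(-alpha * TPc) + B * exp(-beta * TPc) + CC * exp(-ka * TPc))
  oral[TP <= 0] <- 0

  pa <- (alpha - k21) / (alpha - beta)
  pb <- (k21 - beta) / (alpha - beta)
  T1 <- pmin(Uc, d2)
  zero <- (r0 / vc) *
    ((pa / alpha) * (exp(-alpha * (Uc - T1)) - exp(-alpha * Uc)) +
     (pb / beta) * (exp(-beta * (Uc - T1)) - exp(-beta * Uc)))
  zero[U <= 0] <- 0

  conc <- 1000 * .colSums(oral + zero, n_d, n_t)
  pmax(conc, 0)
}

#' Concentration after a single oral dose
#'
#' Closed-form plasma concentration in the central compartment at times `t`
#' after a single dose at time 0: the sum of the lagged first-order
#' two-compartment absorption solution (fraction `f1` of the bioavailable
#' dose) and the piecewise zero-order-input solution (the remainder, entering
#' over `d2` hours from dose time).
#'
#' @param dose Dose amount (mg free-base equivalents), > 0.
#' @param ap An [absorption_params()] object.
#' @param dp A [disposition_params()] object.
#' @param t Times since dose (h), >= 0. Vectorised.
#' @return Concentrations (ng/mL), same length as `t`.
#' @examples
#' ap <- absorption_params(0.979, 0.784, 2.4, 0.854)
#' dp <- disposition_params(2.478, 187.0, 31.213, 195.1)
#' conc_single_dose(60, ap, dp, c(1, 4, 24))
#' @export
conc_single_dose <- function(dose, ap, dp, t) {
  stopifnot(inherits(ap, "absorption_params"),
            inherits(dp, "disposition_params"), dose > 0)
  if (any(t < 0)) stop("times must be >= 0", call. = FALSE)
  .conc_kernel(t, 0, dose, ap$ka, ap$alag1, ap$d2, ap$f1, ap$frel,
               dp$cl, dp$vc, dp$q, dp$vp)
}

#' Concentration profile under a dosing regimen
#'
#' Superposition of single-dose solutions over the dose events of a regimen.
#' Absorption parameters may differ per dose (dose- or formulation-dependent
#' `ka`/`frel`); pass either one `absorption_params` or a list with one per
#' dose.
#'
#' @param reg A [regimen()].
#' @param ap An [absorption_params()] object, or a list of them (one per
#'   dose). Per-dose `alag1`, `d2`, `f1` must be identical; only `ka` and
#'   `frel` may vary across doses.
#' @param dp A [disposition_params()] object.
#' @param times Observation times (h), >= 0.
#' @return Data frame of class `"concentration_profile"` with columns `time`
#'   (h) and `conc` (ng/mL).
#' @export
conc_profile <- function(reg, ap, dp, times) {
  stopifnot(inherits(reg, "regimen"), inherits(dp, "disposition_params"))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (nrow(reg) == 0L) {
    conc <- numeric(length(times))
  } else {
    if (inherits(ap, "absorption_params")) ap <- list(ap)
    stopifnot(all(vapply(ap, inherits, TRUE, "absorption_params")))
    ap <- rep_len(ap, nrow(reg))
    alag1 <- unique(vapply(ap, `[[`, 0, "alag1"))
    d2 <- unique(vapply(ap, `[[`, 0, "d2"))
    f1 <- unique(vapply(ap, `[[`, 0, "f1"))
    if (length(alag1) != 1L || length(d2) != 1L || length(f1) != 1L) {
      stop("per-dose absorption may vary only in ka and frel", call. = FALSE)
    }
    conc <- .conc_kernel(times, reg$time, reg$amount,
                         vapply(ap, `[[`, 0, "ka"), alag1, d2, f1,
                         vapply(ap, `[[`, 0, "frel"),
                         dp$cl, dp$vc, dp$q, dp$vp)
  }
  structure(data.frame(time = times, conc = conc),
            class = c("concentration_profile", "data.frame"))
}

# Steady-state concentration at offsets u in [0, tau] within the dosing
# interval, for identical doses every tau hours. Doses whose age exceeds
# max(alag1, d2) contribute pure exponentials, summed analytically as a
# geometric series; the at-most-ceiling(max(alag1,d2)/tau) youngest doses are
# evaluated with the full piecewise kernel.
.ss_conc <- function(u, ap, dp, dose, tau) {
  k <- .disp_constants(dp$cl, dp$vc, dp$q, dp$vp)
  alpha <- k$alpha; beta <- k$beta; k21 <- k$k21
  ka <- ap$ka
  if (abs(ka - alpha) < 1e-8 * alpha || abs(ka - beta) < 1e-8 * beta) {
    ka <- ka * (1 + 1e-7)
  }
  da <- ap$f1 * ap$frel * dose
  r0 <- (1 - ap$f1) * ap$frel * dose / ap$d2
  vc <- dp$vc
  smax <- max(ap$alag1, ap$d2)
  K <- max(1L, ceiling(smax / tau))
  finite <- numeric(length(u))
  for (j in seq_len(K) - 1L) {
    finite <- finite + .conc_kernel(u + j * tau, 0, dose, ka, ap$alag1,
                                    ap$d2, ap$f1, ap$frel,
                                    dp$cl, vc, dp$q, dp$vp)
  }
  A <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
  B <- (k21 - beta) / ((ka - beta) * (alpha - beta))
  CC <- (k21 - ka) / ((alpha - ka) * (beta - ka))
  pa <- (alpha - k21) / (alpha - beta)
  pb <- (k21 - beta) / (alpha - beta)
  lam <- c(alpha, beta, ka)
  coef <- 1000 * c(
    (ka * da / vc) * A * exp(alpha * ap$alag1) +
      (r0 / vc) * (pa / alpha) * (exp(alpha * ap$d2) - 1),
    (ka * da / vc) * B * exp(beta * ap$alag1) +
      (r0 / vc) * (pb / beta) * (exp(beta * ap$d2) - 1),
    (ka * da / vc) * CC * exp(ka * ap$alag1))
  tail <- numeric(length(u))
  for (m in 1:3) {
    tail <- tail + coef[m] * exp(-lam[m] * (u + K * tau)) /
      (1 - exp(-lam[m] * tau))
  }
  pmax(finite + tail, 0)
}

#' Steady-state exposure metrics for once-every-tau dosing
#'
#' Analytic steady-state superposition (each exponential term summed as a
#' geometric series) for repeated identical oral doses. `cmin_ss` is the
#' trough concentration at the end of the dosing interval (`t = tau`);
#' `cmax_ss` is located by a 0.05-h grid over the interval followed by local
#' refinement; `auc_tau_ss` is exact by mass balance.
#'
#' @param ap An [absorption_params()] object.
#' @param dp A [disposition_params()] object.
#' @param dose Dose amount (mg), > 0.
#' @param tau Dosing interval (h), > 0.
#' @return Named list: `cmax_ss`, `cmin_ss` (ng/mL), `auc_tau_ss`
#'   (ng*h/mL), `tmax_ss` (h after dose).
#' @examples
#' ap <- absorption_params(0.979, 0.784, 2.4, 0.854)
#' dp <- disposition_params(2.478, 187.0, 31.213, 195.1)
#' steady_state_metrics(ap, dp, dose = 60, tau = 24)
#' @export
steady_state_metrics <- function(ap, dp, dose, tau) {
  stopifnot(inherits(ap, "absorption_params"),
            inherits(dp, "disposition_params"), dose > 0, tau > 0)
  grid <- seq(0, tau, by = min(0.05, tau / 200))
  cg <- .ss_conc(grid, ap, dp, dose, tau)
  i <- which.max(cg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(x) .ss_conc(x, ap, dp, dose, tau),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  cmax <- max(opt$objective, cg[i])
  tmax <- if (opt$objective >= cg[i]) opt$maximum else grid[i]
  cmin <- .ss_conc(tau, ap, dp, dose, tau)
  list(cmax_ss = cmax, cmin_ss = cmin,
       auc_tau_ss = 1000 * ap$frel * dose / dp$cl, tmax_ss = tmax)
}

#' Terminal half-life
#'
#' `log(2)/beta` for the two-compartment model; for the one-compartment
#' reduction (constructed with `q = 0`, `vp` ignored) the elimination
#' half-life `log(2) * vc / cl`.
#'
#' @param dp A [disposition_params()] object (`q = 0` selects the
#'   one-compartment reduction).
#' @return Half-life (h).
#' @examples
#' terminal_half_life(disposition_params(4.42, 349, 0, 1))   # ~55 h
#' terminal_half_life(disposition_params(2.478, 187.0, 31.213, 195.1))
#' @export
terminal_half_life <- function(dp) {
  stopifnot(inherits(dp, "disposition_params"))
  if (dp$q == 0) return(log(2) * dp$vc / dp$cl)
  log(2) / .disp_constants(dp$cl, dp$vc, dp$q, dp$vp)$beta
}
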