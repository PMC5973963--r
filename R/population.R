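# Between-subject variability (log-normal random effects on Ka, CL/F, Vc/F
# and logit-scale random effect on F1) and log-additive residual error.


#' Inter-individual variance-covariance matrix
#'
#' Builds the 4x4 variance-covariance matrix of the random effects on
#' (Ka, CL/F, Vc/F, F1). The default diagonal holds the reported variance
#' estimates; a CL-Vc correlation can be added (the only off-diagonal term
#' reported, whose printed value is not a valid covariance and is therefore
#' replaced by a configurable correlation).
#'
#' @param diag Variances of the eta on (ka, cl, vc, f1).
#' @param cl_vc_corr Correlation between the CL/F and Vc/F random effects,
#'   in \[-1, 1\].
#' @return A 4x4 matrix of class `"omega_matrix"` with dimnames
#'   `ka, cl, vc, f1`.
#' @examples
#' omega_matrix()                      # default, CL-Vc correlation 0.5
#' omega_matrix(cl_vc_corr = 0)        # diagonal
#' @export
omega_matrix <- function(diag = c(ka = 2.063, cl = 0.202, vc = 0.233,
                                  f1 = 0.466),
                         cl_vc_corr = 0.5) {
  stopifnot(length(diag) == 4L, is.numeric(diag))
  if (any(diag < 0)) stop("variances must be non-negative", call. = FALSE)
  if (abs(cl_vc_corr) > 1) stop("|cl_vc_corr| must be <= 1", call. = FALSE)
  om <- diag(as.numeric(diag), 4L)
  dimnames(om) <- list(.eta_names, .eta_names)
  om["cl", "vc"] <- om["vc", "cl"] <- cl_vc_corr * sqrt(om["cl", "cl"] *
                                                          om["vc", "vc"])
  validate_omega(om)
  class(om) <- c("omega_matrix", class(om))
  om
}

#' Validate an inter-individual covariance matrix
#'
#' Checks symmetry, non-negative diagonal, the Cauchy-Schwarz bound on every
#' off-diagonal element, and positive semidefiniteness.
#'
#' @param om A 4x4 numeric matrix.
#' @return Invisibly, `om`. Errors name the violated invariant.
#' @export
validate_omega <- function(om) {
  if (!is.matrix(om) || nrow(om) != 4L || ncol(om) != 4L) {
    stop("omega must be a 4x4 matrix", call. = FALSE)
  }
  if (max(abs(om - t(om))) > 1e-10 * (1 + max(abs(om)))) {
    stop("omega is not symmetric", call. = FALSE)
  }
  if (any(diag(om) < 0)) stop("omega has a negative diagonal", call. = FALSE)
  bound <- sqrt(outer(diag(om), diag(om)))
  if (any(abs(om) > bound + 1e-10 * (1 + max(bound)))) {
    stop("omega violates the Cauchy-Schwarz bound |w_ij| <= sqrt(w_ii w_jj)",
         call. = FALSE)
  }
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("omega is not positive semidefinite", call. = FALSE)
  }
  invisible(om)
}

#' Residual (within-subject) error model
#'
#' Additive error on the log-concentration scale:
#' `log(Y) = log(C) + eps`, `eps ~ N(0, sigma2)`.
#'
#' @param sigma2 Variance of `eps`, >= 0.
#' @return An object of class `"residual_model"`.
#' @export
residual_model <- function(sigma2 = 0.118) {
  if (!(is.numeric(sigma2) && length(sigma2) == 1L && sigma2 >= 0)) {
    stop("sigma2 must be a single non-negative number", call. = FALSE)
  }
  structure(list(sigma2 = sigma2), class = "residual_model")
}

#' Draw inter-individual random effects
#'
#' Multivariate-normal draws with mean zero and covariance `omega`.
#'
#' @param n Number of subjects.
#' @param omega An [omega_matrix()] (or any valid 4x4 covariance matrix).
#' @param seed Optional integer seed. When `NULL` the current RNG stream is
#'   used (so calls inside a larger seeded simulation stay reproducible).
#' @return `n` x 4 matrix of eta values, columns `ka, cl, vc, f1`.
#' @export
draw_etas <- function(n, omega, seed = NULL) {
  validate_omega(unclass(omega))
  if (!is.null(seed)) set.seed(seed)
  et <- MASS::mvrnorm(n, mu = numeric(4L), Sigma = unclass(omega))
  if (n == 1L) et <- matrix(et, nrow = 1L)
  colnames(et) <- .eta_names
  et
}

#' Apply inter-individual random effects to typical parameters
#'
#' Ka, CL/F and Vc/F are perturbed multiplicatively (`theta_i =
#' theta_typical * exp(eta)`); F1 is perturbed on the logit scale so the
#' individual fraction stays in (0, 1).
#'
#' @param ap Typical [absorption_params()].
#' @param dp Typical [disposition_params()].
#' @param eta Numeric vector of length 4, ordered (ka, cl, vc, f1).
#' @return List with elements `ap` and `dp`: the individual parameters
#'   (`q`, `vp`, `alag1`, `d2`, `frel` unchanged).
#' @examples
#' th <- theta_preset("FM"); ref <- reference_subject()
#' apply_iiv(typical_absorption(ref, th), typical_disposition(ref, th),
#'           c(0.1, -0.2, 0, 0.5))
#' @export
apply_iiv <- function(ap, dp, eta) {
  stopifnot(inherits(ap, "absorption_params"),
            inherits(dp, "disposition_params"),
            is.numeric(eta), length(eta) == 4L, all(is.finite(eta)))
  list(
    ap = absorption_params(ka = ap$ka * exp(eta[1L]), alag1 = ap$alag1,
                           d2 = ap$d2,
                           f1 = stats::plogis(stats::qlogis(ap$f1) + eta[4L]),
                           frel = ap$frel),
    dp = disposition_params(cl = dp$cl * exp(eta[2L]),
                            vc = dp$vc * exp(eta[3L]),
                            q = dp$q, vp = dp$vp))
}

#' Add residual error to predicted concentrations
#'
#' Observed concentration `Y = C * exp(eps)` with `eps ~ N(0, sigma2)`.
#' Non-positive predictions cannot carry a log-scale error; they are skipped
#' (returned as `NA`) with a warning.
#'
#' @param conc Predicted concentrations (ng/mL).
#' @param rm A [residual_model()].
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @return Observed concentrations, `NA` where `conc <= 0`.
#' @export
add_residual_error <- function(conc, rm, seed = NULL) {
  stopifnot(inherits(rm, "residual_model"))
  if (!is.null(seed)) set.seed(seed)
  ok <- conc > 0
  if (any(!ok)) {
    warning(sum(!ok), " non-positive prediction(s) skipped: log-scale ",
            "residual error is undefined at 0", call. = FALSE)
  }
  out <- rep(NA_real_, length(conc))
  out[ok] <- conc[ok] * exp(stats::rnorm(sum(ok), 0, sqrt(rm$sigma2)))
  out
}
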