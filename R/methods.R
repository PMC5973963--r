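# S3 methods for the fitted-model object.

#' @export
print.poppk_fit <- function(x, ...) {
  cat("Population PK model fit (Laplace approximation)\n")
  cat(sprintf("  structure: %s | subjects: %d | observations: %d\n",
              x$config$name, x$n_subjects, x$n_obs))
  cat(sprintf("  OFV: %.3f | convergence code: %d\n", x$ofv,
              x$convergence))
  if (length(x$estimate)) {
    cat("  estimated parameters:\n")
    print(round(coef(x), 5))
  } else {
    cat("  (no free parameters; evaluated at fixed values)\n")
  }
  if (length(x$flagged)) {
    cat("  flagged subjects (inner penalty):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Estimated parameters on the natural scale
#'
#' @param object A `"poppk_fit"`.
#' @param ... Unused.
#' @return Named numeric vector of the estimated parameters, back-
#'   transformed to their natural scale.
#' @export
coef.poppk_fit <- function(object, ...) {
  vapply(object$estimate, function(nm)
    .get_par(object$theta, object$omega, object$sigma2, nm), 0)
}

#' @export
logLik.poppk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$estimate),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.poppk_fit <- function(object, ...) object$vcov

#' Summary of a population PK fit
#'
#' @param object A `"poppk_fit"`.
#' @param ... Unused.
#' @return An object of class `"summary.poppk_fit"`: the fit plus a
#'   coefficient table (estimate, transformed estimate, and, when the fit
#'   carries a covariance matrix, an approximate standard error on the
#'   transformed scale).
#' @export
summary.poppk_fit <- function(object, ...) {
  est <- coef(object)
  tab <- data.frame(estimate = est, transformed = object$par)
  if (!is.null(object$vcov)) {
    tab$se_transformed <- sqrt(pmax(diag(object$vcov), 0))
  }
  structure(list(fit = object, coefficients = tab),
            class = "summary.poppk_fit")
}

#' @export
print.summary.poppk_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (natural scale; 'transformed' is the estimation",
      "scale):\n")
  print(round(x$coefficients, 5))
  cat(sprintf("\nsigma2 = %.4f; omega diagonal: %s\n", x$fit$sigma2,
              paste(sprintf("%s=%.3f", .eta_names,
                            diag(unclass(x$fit$omega))),
                    collapse = ", ")))
  invisible(x)
}

#' Model predictions for a PK dataset
#'
#' @param object A `"poppk_fit"`.
#' @param newdata Dataset to predict (defaults to the fitted data). For
#'   `type = "ipred"` every subject must have MAP random effects in the
#'   fit.
#' @param type `"pred"` (typical, random effects at zero) or `"ipred"`
#'   (MAP random effects).
#' @param ... Unused.
#' @return Data frame with `ID`, `TIME` and the predicted concentration
#'   (ng/mL) for every observation record.
#' @export
predict.poppk_fit <- function(object, newdata = NULL, type = c("ipred",
                                                               "pred"),
                              ...) {
  type <- match.arg(type)
  ds <- if (is.null(newdata)) object$data else newdata
  prep <- .prep_subjects(ds)
  etas <- NULL
  if (type == "ipred") {
    absent <- setdiff(names(prep), rownames(object$map_etas))
    if (length(absent)) {
      stop("subject(s) absent from fit: ",
           paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
    }
    etas <- object$map_etas
  }
  p <- .predict_prep(object$theta, prep, etas)
  do.call(rbind, lapply(names(prep), function(id) {
    if (!length(prep[[id]]$tobs)) return(NULL)
    data.frame(ID = id, TIME = prep[[id]]$tobs, pred = p[[id]])
  }))
}

#' Individual weighted residuals
#'
#' `IWRES = (log DV - log IPRED) / sigma` for every usable observation.
#'
#' @param object A `"poppk_fit"`.
#' @param ... Unused.
#' @return Numeric vector of residuals (one per usable observation, in
#'   subject/time order).
#' @export
residuals.poppk_fit <- function(object, ...) {
  gof <- gof_summary(object)
  gof$obs$IWRES
}

#' Simulate replicate datasets from a fitted model
#'
#' Re-simulates the fitted dataset's design (same subjects, covariates,
#' dosing and observation times) with freshly drawn random effects and
#' residual errors at the fitted parameter values.
#'
#' @param object A `"poppk_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of data frames in the PK dataset dialect.
#' @export
simulate.poppk_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  prep <- .prep_subjects(object$data)
  ids <- names(prep)
  sig <- sqrt(object$sigma2)
  lapply(seq_len(nsim), function(r) {
    etas <- draw_etas(length(prep), object$omega)
    rownames(etas) <- ids
    sim <- .predict_prep(object$theta, prep, etas)
    ds <- object$data
    for (id in ids) {
      rows <- which(ds$ID == id & ds$EVID == 0L)
      if (!length(rows)) next
      ci <- sim[[id]]
      y <- ifelse(ci > 0, ci * exp(stats::rnorm(length(ci), 0, sig)), 0)
      ds$DV[rows] <- y
      ds$BLQ[rows] <- as.integer(y < .lloq_default)
      ds$MDV[rows] <- ds$BLQ[rows]
    }
    ds
  })
}

#' Goodness-of-fit plot
#'
#' Observed versus typical (PRED) and individual (IPRED) predictions on
#' log-log axes, with the identity line.
#'
#' @param x A `"poppk_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [gof_summary()] table.
#' @export
plot.poppk_fit <- function(x, ...) {
  gof <- gof_summary(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (col in c("PRED", "IPRED")) {
    graphics::plot(gof$obs[[col]], gof$obs$DV, log = "xy",
                   xlab = paste(col, "(ng/mL)"), ylab = "DV (ng/mL)", ...)
    graphics::abline(0, 1, col = "grey50")
  }
  invisible(gof)
}

#' @export
print.theta_vector <- function(x, ...) {
  cat("PK fixed-effect vector\n")
  cat(sprintf(
    "  ka %.3f 1/h (dose exp %.3f), alag1 %.3f h, d2 %.3f h, f1 %.3f\n",
    x$ka, x$dose_ka_exp, x$alag1, x$d2, x$f1))
  cat(sprintf("  cl %.3f L/h, vc %.1f L, q %.3f L/h, vp %.1f L\n",
              x$cl, x$vc, x$q, x$vp))
  cat(sprintf("  capsule on ka %+.3f, on bioavailability %+.3f\n",
              x$fc_capsule_ka, x$fc_capsule_f))
  nz <- x$fc_cl[x$fc_cl != 0]
  if (length(nz)) {
    cat("  CL/F fractional changes:",
        paste(sprintf("%s %+.3f", names(nz), nz), collapse = ", "), "\n")
  }
  invisible(x)
}
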