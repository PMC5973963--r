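# Goodness-of-fit summaries, random-effect-by-covariate summaries, and the
# posterior predictive check with smoothed parametric bootstrap.

# typical and individual predictions for prepared subjects
.predict_prep <- function(th, prep, etas = NULL) {
  out <- vector("list", length(prep))
  for (i in seq_along(prep)) {
    sub <- prep[[i]]
    if (length(sub$tobs) == 0L) { out[[i]] <- numeric(); next }
    typ <- .subject_typ(th, sub)
    eta <- if (is.null(etas)) numeric(4L) else etas[sub$id, ]
    out[[i]] <- .conc_kernel(sub$tobs, sub$dose_times, sub$amts,
                             typ$ka * exp(eta[1L]), typ$alag1, typ$d2,
                             stats::plogis(typ$lf1 + eta[4L]), typ$frel,
                             typ$cl * exp(eta[2L]), typ$vc * exp(eta[3L]),
                             typ$q, typ$vp)
  }
  names(out) <- names(prep)
  out
}

.geomean <- function(x) exp(mean(log(x[x > 0])))

#' Goodness-of-fit table
#'
#' Per-observation typical predictions (PRED, random effects at zero),
#' individual predictions (IPRED, MAP random effects) and individual
#' weighted residuals `IWRES = (log DV - log IPRED) / sigma`, plus
#' geometric means of DV, PRED and IPRED by study and nominal time.
#' BLQ records carry no residual.
#'
#' @param fit A `"poppk_fit"`.
#' @param ds Dataset to evaluate (defaults to the fitted data); every
#'   subject must be present in the fit.
#' @return List of class `"gof_table"`: `obs` (per-record table) and
#'   `groups` (per study x nominal time geometric means).
#' @export
gof_summary <- function(fit, ds = fit$data) {
  stopifnot(inherits(fit, "poppk_fit"))
  prep <- .prep_subjects(ds)
  absent <- setdiff(names(prep), rownames(fit$map_etas))
  if (length(absent)) {
    stop("subject(s) absent from fit: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  pred <- .predict_prep(fit$theta, prep)
  ipred <- .predict_prep(fit$theta, prep, fit$map_etas)
  obs <- do.call(rbind, lapply(names(prep), function(id) {
    sub <- prep[[id]]
    if (length(sub$tobs) == 0L) return(NULL)
    data.frame(ID = id, STUDY = ds$STUDY[match(id, ds$ID)],
               TIME = sub$tobs, DV = exp(sub$ldv),
               PRED = pred[[id]], IPRED = ipred[[id]],
               stringsAsFactors = FALSE)
  }))
  r <- log(obs$DV) - log(obs$IPRED)
  obs$IWRES <- if (fit$sigma2 > 0) r / sqrt(fit$sigma2) else {
    ifelse(abs(r) < 1e-12, 0, NaN)  # no residual model: exact fit expected
  }
  g <- split(obs, list(obs$STUDY, obs$TIME), drop = TRUE)
  groups <- do.call(rbind, lapply(g, function(x) {
    data.frame(STUDY = x$STUDY[1], TIME = x$TIME[1], n = nrow(x),
               gm_dv = .geomean(x$DV), gm_pred = .geomean(x$PRED),
               gm_ipred = .geomean(x$IPRED))
  }))
  groups <- groups[order(groups$STUDY, groups$TIME), ]
  rownames(groups) <- NULL
  structure(list(obs = obs, groups = groups), class = "gof_table")
}

#' Random-effect summaries by covariate level
#'
#' Summaries (median, quartiles, 5th/95th percentiles) of one MAP random
#' effect per level of a categorical covariate. A continuous covariate is
#' binned at its quartiles, with the bin edges reported as an attribute.
#'
#' @param fit A `"poppk_fit"`.
#' @param ds Dataset providing the covariate (defaults to the fitted data).
#' @param covariate Column name in `ds` (e.g. `"POP"`, `"STUDY"`,
#'   `"DOSE"`, `"WT"`).
#' @param eta Which random effect (`"ka"`, `"cl"`, `"vc"`, `"f1"`).
#' @return Data frame with one row per level: `level`, `n`, `median`,
#'   `q25`, `q75`, `p5`, `p95`.
#' @export
eta_by_covariate <- function(fit, ds = fit$data, covariate = "POP",
                             eta = "cl") {
  stopifnot(inherits(fit, "poppk_fit"), eta %in% .eta_names)
  if (!covariate %in% names(ds)) {
    stop("covariate '", covariate, "' not found in the dataset",
         call. = FALSE)
  }
  first <- ds[!duplicated(ds$ID), ]
  ids <- intersect(first$ID, rownames(fit$map_etas))
  val <- first[[covariate]][match(ids, first$ID)]
  if (is.numeric(val) && length(unique(val)) > 6L) {
    edges <- stats::quantile(val, c(0, 0.25, 0.5, 0.75, 1))
    lab <- cut(val, breaks = unique(edges), include.lowest = TRUE)
    out <- .eta_level_summary(fit$map_etas[ids, eta], lab)
    attr(out, "bin_edges") <- edges
    return(out)
  }
  .eta_level_summary(fit$map_etas[ids, eta], factor(val))
}

.eta_level_summary <- function(e, f) {
  out <- do.call(rbind, lapply(split(e, f), function(x) {
    q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(n = length(x), median = q[3], q25 = q[2], q75 = q[4],
               p5 = q[1], p95 = q[5])
  }))
  cbind(level = rownames(out), out, row.names = NULL)
}

#' Posterior predictive check with smoothed parametric bootstrap
#'
#' Draws `n_rep` population parameter vectors from a multivariate normal on
#' the transformed estimation scale, centred at the estimates with the
#' estimate covariance matrix; each vector is back-transformed (draws
#' violating parameter invariants are rejected and redrawn, with the count
#' reported) and used to simulate one replicate of the fitted dataset,
#' reusing its design, sample size and observed covariates. The median and
#' 10th/90th percentiles of concentration are computed per study and
#' nominal time for the observed data and each replicate; 90% prediction
#' intervals are the 5th/95th percentiles of each statistic across
#' replicates.
#'
#' @param fit A `"poppk_fit"` carrying an estimate covariance matrix
#'   (refit with `hessian = TRUE` if missing; a zero matrix suppresses
#'   parameter uncertainty).
#' @param n_rep Number of replicates (>= 2; default 500).
#' @param seed Integer seed.
#' @param data Dataset whose design is replicated (defaults to the fitted
#'   data).
#' @return Data frame of class `"ppc_result"`, one row per study x nominal
#'   time: observed `obs_median`, `obs_p10`, `obs_p90` and simulated 5th
#'   and 95th percentiles of each statistic (`med_lo`/`med_hi`, ...), with
#'   coverage flags `covered_median`, `covered_p10`, `covered_p90`.
#'   Attributes: `n_rep`, `n_rejected`.
#' @export
posterior_predictive_check <- function(fit, n_rep = 500L, seed = 1L,
                                       data = fit$data) {
  stopifnot(inherits(fit, "poppk_fit"), n_rep >= 2L)
  if (is.null(fit$vcov)) {
    stop("fit carries no estimate covariance matrix; refit with ",
         "hessian = TRUE (a zero matrix is accepted)", call. = FALSE)
  }
  prep <- .prep_subjects(data)
  obs_rows <- data[data$EVID == 0L & !is.na(data$DV) & data$DV > 0, ]
  key <- paste(obs_rows$STUDY, obs_rows$TIME, sep = "@")
  groups <- sort(unique(key))
  q3 <- function(x) stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  obs_stat <- t(vapply(groups, function(g) q3(obs_rows$DV[key == g]),
                       numeric(3L)))
  set.seed(seed)
  est <- fit$estimate
  uncertain <- length(est) > 0L && any(fit$vcov != 0)
  sim_stats <- array(NA_real_, c(length(groups), 3L, n_rep))
  n_rejected <- 0L
  sub_ids <- vapply(prep, `[[`, "", "id")
  for (r in seq_len(n_rep)) {
    st <- list(theta = fit$theta, omega = unclass(fit$omega),
               sigma2 = fit$sigma2)
    if (uncertain) {
      for (try in 1:100) {
        tp <- MASS::mvrnorm(1L, mu = fit$par, Sigma = fit$vcov)
        cand <- st
        ok <- TRUE
        for (j in seq_along(est)) {
          cand <- .set_par(cand, est[j], .t_inv(est[j], tp[j]))
        }
        ok <- tryCatch({
          validate_omega(cand$omega)
          cand$sigma2 >= 0 && cand$theta$f1 > 0 && cand$theta$f1 < 1
        }, error = function(e) FALSE)
        if (isTRUE(ok)) { st <- cand; break }
        n_rejected <- n_rejected + 1L
        if (try == 100L) stop("parameter draws kept violating invariants",
                              call. = FALSE)
      }
    }
    etas <- draw_etas(length(prep), st$omega)
    rownames(etas) <- sub_ids
    sim <- .predict_prep(st$theta, prep, etas)
    sig <- sqrt(st$sigma2)
    dv <- numeric(0)
    kk <- character(0)
    stn <- data$STUDY[match(sub_ids, data$ID)]
    for (i in seq_along(prep)) {
      ci <- sim[[i]]
      if (!length(ci)) next
      pos <- ci > 0
      y <- ci
      y[pos] <- ci[pos] * exp(stats::rnorm(sum(pos), 0, sig))
      dv <- c(dv, y[pos])
      kk <- c(kk, paste(stn[i], prep[[i]]$tobs[pos], sep = "@"))
    }
    for (gi in seq_along(groups)) {
      x <- dv[kk == groups[gi]]
      if (length(x)) sim_stats[gi, , r] <- q3(x)
    }
  }
  lo <- apply(sim_stats, c(1, 2), stats::quantile, probs = 0.05,
              na.rm = TRUE)
  hi <- apply(sim_stats, c(1, 2), stats::quantile, probs = 0.95,
              na.rm = TRUE)
  parts <- do.call(rbind, strsplit(groups, "@", fixed = TRUE))
  out <- data.frame(STUDY = parts[, 1],
                    TIME = as.numeric(parts[, 2]),
                    obs_p10 = obs_stat[, 1], obs_median = obs_stat[, 2],
                    obs_p90 = obs_stat[, 3],
                    p10_lo = lo[, 1], p10_hi = hi[, 1],
                    med_lo = lo[, 2], med_hi = hi[, 2],
                    p90_lo = lo[, 3], p90_hi = hi[, 3])
  out$covered_p10 <- out$obs_p10 >= out$p10_lo & out$obs_p10 <= out$p10_hi
  out$covered_median <- out$obs_median >= out$med_lo &
    out$obs_median <= out$med_hi
  out$covered_p90 <- out$obs_p90 >= out$p90_lo & out$obs_p90 <= out$p90_hi
  out <- out[order(out$STUDY, out$TIME), ]
  rownames(out) <- NULL
  attr(out, "n_rep") <- n_rep
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("ppc_result", "data.frame")
  out
}
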