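# one-subject dataset with prescribed observation values
one_subject_ds <- function(tobs, dv, dose = 60) {
  n <- length(tobs)
  rbind(
    data.frame(ID = "s1", STUDY = "x", TIME = 0, AMT = dose, EVID = 1L,
               DV = NA_real_, MDV = 1L, BLQ = 0L, FORM = "tablet",
               AGE = 60, WT = 80, SEX = "male", RACE = "White", POP = "HV",
               DOSE = dose),
    data.frame(ID = "s1", STUDY = "x", TIME = tobs, AMT = NA_real_,
               EVID = 0L, DV = dv, MDV = 0L, BLQ = 0L, FORM = "tablet",
               AGE = 60, WT = 80, SEX = "male", RACE = "White", POP = "HV",
               DOSE = dose))
}

test_that("the joint -2 log likelihood matches direct density evaluation", {
  th <- fm_theta()
  ref <- reference_subject()
  ap <- typical_absorption(ref, th)
  dp <- typical_disposition(ref, th)
  # one observation exactly at the model prediction, unit variances:
  # every Gaussian kernel vanishes, leaving only normalising constants
  c4 <- conc_single_dose(60, ap, dp, 4)
  ds1 <- one_subject_ds(4, c4)
  om_i <- omega_matrix(diag = c(1, 1, 1, 1), cl_vc_corr = 0)
  val <- individual_joint_nll(rep(0, 4), ds1, th, om_i, residual_model(1))
  expect_equal(val, 5 * log(2 * pi), tolerance = 1e-8)

  # quadratic growth of the residual contribution
  base <- individual_joint_nll(rep(0, 4), one_subject_ds(4, c4), th, om_i,
                               residual_model(1))
  up1 <- individual_joint_nll(rep(0, 4), one_subject_ds(4, c4 * exp(0.3)),
                              th, om_i, residual_model(1))
  up2 <- individual_joint_nll(rep(0, 4), one_subject_ds(4, c4 * exp(0.6)),
                              th, om_i, residual_model(1))
  expect_equal(up2 - base, 4 * (up1 - base), tolerance = 1e-8)

  # three-observation fixture against term-by-term assembly with dnorm
  tobs <- c(2, 8, 48)
  dv <- conc_single_dose(60, ap, dp, tobs) * exp(c(0.2, -0.1, 0.05))
  eta <- c(0.1, -0.2, 0.15, 0.3)
  om <- omega_matrix(cl_vc_corr = 0.4)
  s2 <- 0.118
  val <- individual_joint_nll(eta, one_subject_ds(tobs, dv), th, om,
                              residual_model(s2))
  ind <- apply_iiv(ap, dp, eta)
  cpred <- conc_single_dose(60, ind$ap, ind$dp, tobs)
  oracle <- -2 * (sum(dnorm(log(dv), log(cpred), sqrt(s2), log = TRUE)) +
                    (-0.5 * (4 * log(2 * pi) +
                               determinant(unclass(om))$modulus[1] +
                               drop(eta %*% solve(unclass(om)) %*% eta))))
  expect_equal(val, oracle, tolerance = 1e-6)
})

test_that("Laplace OFV collapses to the fixed-effects -2LL as omega -> 0", {
  th <- fm_theta()
  ds <- simulate_dataset(list(ref_spec(1, obs_times = c(1, 4, 24, 96))),
                         th, omega_matrix(diag = c(0, 0, 0, 0),
                                          cl_vc_corr = 0),
                         residual_model(0.05), seed = 8)
  s2 <- 0.05
  obs <- estimation_view(ds)
  ref <- reference_subject()
  cpred <- conc_single_dose(60, typical_absorption(ref, th),
                            typical_disposition(ref, th), obs$TIME)
  direct <- sum(log(2 * pi * s2) + (log(obs$DV) - log(cpred))^2 / s2)
  tiny <- omega_matrix(diag = rep(1e-10, 4), cl_vc_corr = 0)
  lap <- laplace_ofv(th, tiny, residual_model(s2), ds)
  expect_equal(lap$ofv, direct, tolerance = 1e-3)
  # and exactly, via the degenerate zero-variance branch
  om0 <- omega_matrix(diag = c(0, 0, 0, 0), cl_vc_corr = 0)
  expect_equal(laplace_ofv(th, om0, residual_model(s2), ds)$ofv, direct,
               tolerance = 1e-10)
})

test_that("Laplace OFV is invariant to subject order and ID relabeling", {
  th <- fm_theta()
  om <- omega_matrix(cl_vc_corr = 0)
  ds <- simulate_dataset(list(hv_spec(6, obs_times = c(1, 4, 24, 96))),
                         th, om, residual_model(0.118), seed = 12)
  rm <- residual_model(0.118)
  a <- laplace_ofv(th, om, rm, ds)
  shuffled <- ds[rev(seq_len(nrow(ds))), ]
  shuffled <- shuffled[order(shuffled$TIME), ]  # arbitrary stable reorder
  shuffled <- shuffled[order(match(shuffled$ID, rev(unique(ds$ID)))), ]
  b <- laplace_ofv(th, om, rm, shuffled)
  expect_equal(a$ofv, b$ofv, tolerance = 1e-8)
  relab <- ds
  relab$ID <- paste0("z", relab$ID)
  expect_equal(laplace_ofv(th, om, rm, relab)$ofv, a$ofv, tolerance = 1e-8)
})

test_that("noise-free rich data identifies clearance and volume to < 1%", {
  th <- fm_theta()
  om0 <- omega_matrix(diag = c(0, 0, 0, 0), cl_vc_corr = 0)
  ds <- simulate_dataset(list(ref_spec(4)), th, om0, residual_model(0),
                         seed = 3)
  start <- th
  start$cl <- 3.2
  start$vc <- 150
  fit <- poppk_fit(ds, model_config(estimate = c("cl", "vc"),
                                    random = character(0)),
                   start = start, omega = om0, sigma2 = 1e-4)
  expect_equal(coef(fit)[["cl"]], 2.478, tolerance = 0.01)
  expect_equal(coef(fit)[["vc"]], 187, tolerance = 0.01)
})

test_that("nested-model comparison follows likelihood-ratio logic", {
  th <- fm_theta()
  om <- omega_matrix(diag = c(0, 0.202, 0, 0), cl_vc_corr = 0)
  ds <- simulate_dataset(list(hv_spec(8, obs_times = c(1, 4, 24, 96))),
                         th, om, residual_model(0.118), seed = 19)
  fit1 <- poppk_fit(ds, model_config(estimate = "cl", random = "cl"),
                    start = th, omega = om)
  cmp0 <- compare_nested(fit1, fit1)
  expect_equal(cmp0$delta_ofv, 0)
  expect_equal(cmp0$df, 0L)
  expect_equal(cmp0$lrt_p, 1)
  fit2 <- poppk_fit(ds, model_config(estimate = c("cl", "vc"),
                                     random = "cl"),
                    start = th, omega = om)
  cmp <- compare_nested(fit1, fit2)
  expect_equal(cmp$df, 1L)
  # growing the model cannot worsen the optimum (optimizer tolerance 0.1)
  expect_gte(cmp$delta_ofv, -0.1)
  expect_equal(cmp$lrt_p,
               pchisq(max(cmp$delta_ofv, 0), 1, lower.tail = FALSE))
  # the classic 0.001 significance cutoff
  expect_equal(pchisq(10.83, 1, lower.tail = FALSE), 0.001,
               tolerance = 1e-3)
  expect_error(compare_nested(fit2, fit1), "not nested")
})

test_that("fit methods expose the usual modelling interface", {
  th <- fm_theta()
  om <- omega_matrix(diag = c(0, 0.202, 0, 0), cl_vc_corr = 0)
  ds <- simulate_dataset(list(hv_spec(5, obs_times = c(1, 4, 24, 96))),
                         th, om, residual_model(0.118), seed = 29)
  fit <- poppk_fit(ds, model_config(estimate = c("cl", "sigma2"),
                                    random = "cl"),
                   start = th, omega = om, hessian = TRUE)
  expect_s3_class(fit, "poppk_fit")
  expect_named(coef(fit), c("cl", "sigma2"))
  expect_equal(as.numeric(logLik(fit)), -fit$ofv / 2)
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_output(print(fit), "Laplace")
  expect_output(print(summary(fit)), "Coefficients")
  pr <- predict(fit, type = "pred")
  pi <- predict(fit, type = "ipred")
  expect_equal(nrow(pr), sum(ds$EVID == 0 & ds$MDV == 0))
  expect_false(isTRUE(all.equal(pr$pred, pi$pred)))
  expect_length(residuals(fit), nrow(pr))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_silent(validate_dataset(sims[[1]]))
  expect_false(identical(sims[[1]]$DV, sims[[2]]$DV))
})
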