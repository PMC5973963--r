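test_that("hybrid constants match the eigenvalue oracle and Vieta identities", {
  dp <- fm_dp()
  k <- hybrid_disposition_constants(dp)
  # oracle: eigenvalues of the 2x2 linear rate matrix
  k10 <- dp$cl / dp$vc; k12 <- dp$q / dp$vc; k21 <- dp$q / dp$vp
  ev <- sort(-eigen(matrix(c(-(k10 + k12), k12, k21, -k21), 2, 2))$values)
  expect_equal(k$beta, ev[1], tolerance = 1e-10)
  expect_equal(k$alpha, ev[2], tolerance = 1e-10)
  expect_equal(k$beta, 0.006352, tolerance = 2e-4)
  expect_equal(k$alpha, 0.3338, tolerance = 2e-4)

  set.seed(11)
  for (i in 1:20) {
    dpr <- draw_random_params()$dp
    kr <- hybrid_disposition_constants(dpr)
    expect_gt(kr$alpha, kr$beta)
    expect_gt(kr$beta, 0)
    expect_equal(kr$alpha * kr$beta / (kr$k10 * kr$k21), 1,
                 tolerance = 1e-12)
    expect_equal(kr$alpha + kr$beta, kr$k10 + kr$k12 + kr$k21,
                 tolerance = 1e-12)
  }
  expect_error(disposition_params(-1, 187, 31, 195), "invalid")
})

test_that("single-dose profile is zero before any input and gated by the lag", {
  ap <- fm_ap(); dp <- fm_dp()
  expect_equal(conc_single_dose(60, ap, dp, 0), 0)
  # with essentially the whole dose in the lagged depot, nothing appears
  # before the lag
  ap1 <- absorption_params(0.979, 0.784, 2.4, 1 - 1e-9)
  expect_lt(conc_single_dose(60, ap1, dp, 0.5), 1e-4)
  # the zero-order route starts at dose time: concentration is positive
  # before the lag under the dual split
  expect_gt(conc_single_dose(60, ap, dp, 0.5), 0)
  expect_error(conc_single_dose(60, ap, dp, -1), "times")
})

test_that("single-dose AUC obeys mass balance dose/(CL/F)", {
  ap <- fm_ap(); dp <- fm_dp()
  auc <- integrate(function(t) conc_single_dose(60, ap, dp, t), 0, Inf,
                   rel.tol = 1e-10)$value
  expect_equal(auc, 1000 * 60 / 2.478, tolerance = 1e-7)
  set.seed(21)
  for (i in 1:3) {
    p <- draw_random_params()
    auc <- integrate(function(t) conc_single_dose(45, p$ap, p$dp, t),
                     0, 40 * terminal_half_life(p$dp),
                     rel.tol = 1e-9)$value
    expect_equal(auc, 1000 * p$ap$frel * 45 / p$dp$cl, tolerance = 1e-4)
  }
})

test_that("closed form agrees with stiff ODE integration", {
  tt <- c(0.5, 0.784, 1, 2, 3, 5, 8, 12, 24, 48, 96, 168, 336)
  set.seed(31)
  for (i in 1:5) {
    p <- draw_random_params()
    cf <- conc_single_dose(60, p$ap, p$dp, tt)
    od <- ode_conc_oracle(60, p$ap, p$dp, tt)
    keep <- od > 1e-9 * max(od)
    expect_lt(max(abs(cf[keep] - od[keep]) / od[keep]), 1e-6)
  }
})

test_that("multi-dose profiles superpose and are linear in dose", {
  ap <- fm_ap(); dp <- fm_dp()
  tt <- c(1, 5, 12, 25, 30, 47.9, 48.5, 60)
  two <- conc_profile(regimen(c(0, 24), 60), ap, dp, tt)$conc
  one0 <- conc_single_dose(60, ap, dp, tt)
  one24 <- ifelse(tt > 24, conc_single_dose(60, ap, dp, pmax(tt - 24, 0)), 0)
  expect_equal(two, one0 + one24, tolerance = 1e-10)
  dbl <- conc_profile(regimen(c(0, 24), 120), ap, dp, tt)$conc
  expect_equal(dbl, 2 * two, tolerance = 1e-12)
  expect_equal(conc_profile(regimen(numeric(), numeric()), ap, dp, tt)$conc,
               rep(0, length(tt)))
})

test_that("analytic steady state matches brute-force superposition", {
  ap <- fm_ap(); dp <- fm_dp()
  ss <- steady_state_metrics(ap, dp, dose = 60, tau = 24)
  # > 10 terminal half-lives of QD dosing (t1/2 ~ 109 h)
  nd <- 120
  reg <- regimen(seq(0, by = 24, length.out = nd), 60)
  trough <- conc_profile(reg, ap, dp, nd * 24)$conc
  expect_equal(ss$cmin_ss, trough, tolerance = 5e-3)
  expect_lt(ss$cmin_ss, ss$cmax_ss)
  expect_equal(ss$auc_tau_ss, 1000 * 60 / 2.478, tolerance = 1e-12)
  # day-29 trough of the finite regimen is within 2% of steady state
  reg29 <- regimen(seq(0, by = 24, length.out = 29), 60)
  t29 <- conc_profile(reg29, ap, dp, 696)$conc
  expect_equal(t29 / ss$cmin_ss, 1, tolerance = 0.02)
})

test_that("terminal half-life identities and scaling invariance hold", {
  expect_equal(terminal_half_life(disposition_params(4.42, 349, 0, 1)),
               55, tolerance = 0.01)
  expect_equal(terminal_half_life(disposition_params(2.23, 319, 0, 1)),
               99, tolerance = 0.01)
  expect_equal(terminal_half_life(fm_dp()), 109, tolerance = 0.005)
  # scaling all flows and volumes together leaves the rate constants, hence
  # the half-life, unchanged
  dp <- fm_dp()
  for (c in c(0.5, 3)) {
    dps <- disposition_params(dp$cl * c, dp$vc * c, dp$q * c, dp$vp * c)
    expect_equal(terminal_half_life(dps), terminal_half_life(dp),
                 tolerance = 1e-12)
  }
})

test_that("ka degenerate with a hybrid exponent is resolved, never NaN", {
  dp <- fm_dp()
  k <- hybrid_disposition_constants(dp)
  ap <- absorption_params(k$alpha, 0.5, 2.4, 0.854)
  cc <- conc_single_dose(60, ap, dp, c(1, 5, 24))
  expect_true(all(is.finite(cc)))
  expect_true(all(cc > 0))
})
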