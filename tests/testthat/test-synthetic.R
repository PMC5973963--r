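test_that("the nine-study suite matches the pooled design", {
  suite <- study_suite()
  expect_length(suite, 9L)
  expect_equal(sum(vapply(suite, `[[`, 0L, "n")), 1534L)
  expect_equal(suite[["301"]]$population, "MTC")
  expect_equal(suite[["308"]]$population, "RCC")
  expect_equal(suite[["307"]]$sex_male_p, 1)
  expect_equal(suite[["010"]]$dose, 140)
  expect_true(all(suite[["020"]]$dose == c(20, 40, 60)))
})

test_that("virtual populations follow the demographic generators", {
  suite <- study_suite()
  pop10 <- build_virtual_population(suite[["010"]], seed = 2)
  expect_equal(nrow(pop10), 77L)
  n_male <- sum(pop10$SEX == "male")
  p <- suite[["010"]]$sex_male_p
  expect_lt(abs(n_male - 77 * p), 3 * sqrt(77 * p * (1 - p)))
  # degenerate proportion: all male
  expect_true(all(build_virtual_population(suite[["307"]],
                                           seed = 3)$SEX == "male"))
  # large-sample convergence of the truncated-normal moments
  big <- suite[["308"]]
  big$n <- 4000L
  pb <- build_virtual_population(big, seed = 4)
  expect_true(all(pb$WT >= 48.1 & pb$WT <= 155.7))
  expect_equal(mean(pb$AGE), 61.6, tolerance = 0.02)
  expect_equal(mean(pb$WT), 81.9, tolerance = 0.02)
  # reproducibility
  expect_identical(build_virtual_population(suite[["010"]], seed = 2), pop10)
})

test_that("zero-variability simulation reproduces the typical profile exactly", {
  th <- fm_theta()
  om0 <- omega_matrix(diag = c(0, 0, 0, 0), cl_vc_corr = 0)
  spec <- ref_spec(1, obs_times = c(1, 2, 4, 8, 24, 72))
  ds <- simulate_dataset(list(spec), th, om0, residual_model(0), seed = 9)
  obs <- ds[ds$EVID == 0L, ]
  ref <- reference_subject()
  expected <- conc_single_dose(60, typical_absorption(ref, th),
                               typical_disposition(ref, th), obs$TIME)
  expect_equal(obs$DV, expected)
})

test_that("simulated datasets validate, flag BLQ, and are seed-reproducible", {
  th <- fm_theta()
  om <- omega_matrix(cl_vc_corr = 0)
  rm <- residual_model(0.118)
  suite <- study_suite()[c("020", "301")]
  ds <- simulate_dataset(suite, th, om, rm, seed = 17)
  expect_silent(validate_dataset(ds))
  obs <- ds[ds$EVID == 0L, ]
  # all below-limit observations are flagged and excluded from estimation
  meas <- obs[!is.na(obs$DV), ]
  expect_true(all(meas$BLQ[meas$DV < 0.5] == 1L))
  expect_true(all(meas$MDV[meas$BLQ == 1L] == 1L))
  expect_equal(nrow(estimation_view(ds)),
               sum(obs$MDV == 0L))
  # the quantifiable fraction dominates at these doses and schedules
  expect_lt(mean(meas$BLQ), 0.05)
  ds2 <- simulate_dataset(suite, th, om, rm, seed = 17)
  expect_identical(ds, ds2)
  # day-29 pre-dose concentrations: MTC runs lower than RCC at equal dose
  th_eq <- th
  sp_m <- study_suite()[["301"]]; sp_m$dose <- 60
  sp_r <- study_suite()[["308"]]; sp_r$dose <- 60
  dsx <- simulate_dataset(list(sp_m, sp_r), th_eq, om, rm, seed = 23)
  pre_m <- dsx$DV[dsx$POP == "MTC" & dsx$EVID == 0 & dsx$TIME == 672 &
                    dsx$MDV == 0]
  pre_r <- dsx$DV[dsx$POP == "RCC" & dsx$EVID == 0 & dsx$TIME == 686 &
                    dsx$MDV == 0]
  expect_lt(exp(mean(log(pre_m))), exp(mean(log(pre_r))))
})

test_that("dataset files round-trip and violations are named", {
  th <- fm_theta()
  ds <- simulate_dataset(list(hv_spec(3, obs_times = c(1, 4, 24, 168))),
                         th, omega_matrix(cl_vc_corr = 0),
                         residual_model(0.118), seed = 31)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back, ds)
  # write(read(x)) is identity at the file level
  path2 <- tempfile(fileext = ".csv")
  write_dataset(back, path2)
  expect_identical(readLines(path), readLines(path2))
  bad <- ds[setdiff(names(ds), "DV")]
  pbad <- tempfile(fileext = ".csv")
  utils::write.csv(bad, pbad, row.names = FALSE)
  expect_error(read_dataset(pbad), "DV")
  nodose <- ds[ds$EVID == 0L, ]
  expect_error(validate_dataset(nodose), "without any dose")
})

test_that("the shipped fixture parses with its BLQ record excluded", {
  path <- system.file("extdata", "example_pkdata.csv", package = "cabopk")
  ds <- read_dataset(path)
  expect_true(any(ds$BLQ == 1L))
  ev <- estimation_view(ds)
  expect_false(any(ev$BLQ == 1L))
  expect_true(all(ev$DV >= 0.5))
})

test_that("the generator's own output always passes validation", {
  th <- fm_theta()
  om <- omega_matrix(cl_vc_corr = 0.3)
  set.seed(91)
  for (id in c("001", "306", "010")) {
    sp <- study_suite()[[id]]
    sp$n <- 5L
    ds <- simulate_dataset(list(sp), th, om, residual_model(0.118),
                           seed = sample.int(1e6, 1))
    expect_silent(validate_dataset(ds))
  }
})
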