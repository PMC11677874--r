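test_that("a mono-exponential curve is summarized to its closed form", {
  t <- seq(0, 24, by = 0.5)
  conc <- 100 * exp(-0.2 * t)
  r <- run_nca(t, conc, dose = 1)
  expect_equal(r$auc_0_inf, 500, tolerance = 0.005)
  expect_equal(r$clearance, 2, tolerance = 0.005)
  expect_equal(r$lambda_z, 0.2, tolerance = 1e-6)
  expect_equal(r$cmax, 100)
  expect_equal(r$tmax, 0)
  expect_gte(r$auc_0_inf, r$auc_0_t)
  expect_true(r$extrapolated_fraction >= 0 && r$extrapolated_fraction < 1)
})

test_that("clearance is dose over AUC in the dose's own units", {
  # absolute dose
  t <- seq(0, 24, by = 1)
  conc <- 60 * exp(-0.25 * t) + 10 * exp(-0.08 * t)
  r <- run_nca(t, conc, dose = 25)
  expect_equal(r$clearance * r$auc_0_inf, 25 * 1000, tolerance = 1e-9)
  # the transcribed summary rows: 25 mg at AUC 191.45 -> 130.58 L/h
  expect_equal(round(25 * 1000 / 191.45, 2), 130.58)
  # per-kg: 0.807 mg/kg at AUC 525.04 -> 1.54 L/h/kg
  expect_equal(round(0.807 * 1000 / 525.04, 2), 1.54)
})

test_that("multi-exponential AUC is recovered within 2% against the oracle", {
  set.seed(404)
  for (i in 1:100) {
    A <- runif(2, 10, 200)
    lambda <- sort(runif(2, 0.03, 1.5), decreasing = TRUE)
    t_half <- log(2) / lambda[2]
    t <- sort(unique(c(0, exp(seq(log(0.1), log(6 * t_half), length.out = 18)))))
    conc <- multiexp_conc(t, A, lambda)
    r <- run_nca(t, conc, dose = 1)
    expect_equal(r$auc_0_inf, multiexp_auc_inf(A, lambda), tolerance = 0.02)
  }
})

test_that("degenerate inputs are rejected or flagged rather than guessed", {
  expect_error(run_nca(c(0, 1, 1, 2), c(1, 2, 3, 4), dose = 1),
               "strictly increasing")
  expect_error(run_nca(c(0, 1, 2), c(1, 2, 3), dose = 1), "4 time points")
  expect_error(run_nca(c(0, 1, 2, 3), c(1, -2, 3, 4), dose = 1),
               "nonnegative")
  # monotonically rising curve has no terminal phase
  r <- run_nca(0:9, seq(1, 10), dose = 1)
  expect_true(is.na(r$lambda_z) && is.na(r$auc_0_inf) && is.na(r$clearance))
  expect_match(r$reason, "Tmax")
  expect_equal(r$cmax, 10)
})

test_that("sparse clinical resampling feeds the same NCA machinery", {
  adult <- build_reference_individual(30, "male")
  sim <- simulate_pbpk(adult, drug_parameters(),
                       dose_regimen("po", 50, formulation = "lint80"))
  full <- nca_from_simulation(sim)
  sparse <- nca_from_simulation(sim, sampling_times_h = c(0.5, 1, 2, 3, 4, 6,
                                                          8, 12, 24))
  expect_lte(sparse$cmax, full$cmax)
  expect_equal(sparse$auc_0_inf, full$auc_0_inf, tolerance = 0.15)
})
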