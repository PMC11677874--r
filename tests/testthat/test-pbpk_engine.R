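drug <- drug_parameters()
adult <- build_reference_individual(30, "male")

test_that("linear dissolution reaches 80% at the dissolution time", {
  expect_equal(lint80_dissolved_fraction(0, 45), 0)
  expect_equal(lint80_dissolved_fraction(45, 45), 0.8)
  expect_equal(lint80_dissolved_fraction(56.25, 45), 1)
  f <- lint80_dissolved_fraction(seq(0, 120, by = 1), 45)
  expect_true(all(diff(f) >= 0) && all(f <= 1))
  expect_error(dose_regimen("iv_bolus", 50, formulation = "lint80"),
               "oral route")
})

test_that("hepatic metabolism has the Michaelis-Menten structure", {
  kin <- drug$enzyme_kinetics
  expr1 <- setNames(rep(1, 4), c("CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6"))
  expect_equal(hepatic_metabolic_rate(0, kin, 1800, 40, expr1)$total_umol_min,
               0)
  # low-concentration limit: rate/Cu equals the summed intrinsic slope
  cu <- 1e-6
  r <- hepatic_metabolic_rate(cu, kin, 1800, 40, expr1)
  slope <- sum(vapply(kin, function(k)
    k$abundance_pmol_mg * 40 * 1800 * k$vmax_pmol_min_pmol / k$km_um * 1e-6,
    numeric(1)))
  expect_equal(r$total_umol_min / cu, slope, tolerance = 1e-4)
  expect_equal(sum(r$per_enzyme_umol_min), r$total_umol_min)
  # zero expression silences every pathway at any concentration
  expr0 <- expr1 * 0
  expect_equal(hepatic_metabolic_rate(50, kin, 1800, 40, expr0)$total_umol_min,
               0)
})

test_that("renal elimination is proportional to plasma level and GFR", {
  ind <- build_reference_individual(30, "male", body_weight = 70)
  ind$gfr_fraction_of_adult <- 1
  expect_equal(renal_elimination_rate(0, ind, drug), 0)
  expect_equal(renal_elimination_rate(100, ind, drug), 70)
  ckd <- ind
  ckd$gfr_fraction_of_adult <- 0.1
  expect_equal(renal_elimination_rate(100, ckd, drug), 7)
})

test_that("mass balance closes for both routes", {
  iv <- simulate_pbpk(adult, drug, dose_regimen("iv_bolus", 50))
  expect_lt(iv$mass_balance_error, 1e-3)
  # dose starts in venous blood and total drug is conserved to < 0.05 mg
  expect_equal(unname(iv$compartment_amounts[1, "venous_blood"]), 50000)
  total <- rowSums(iv$compartment_amounts) + rowSums(iv$eliminated)
  expect_true(all(abs(total - 50000) < 50))
  expect_true(all(iv$conc_ng_ml >= 0))

  po <- simulate_pbpk(adult, drug, dose_regimen("po", 50,
                                                formulation = "lint80"))
  expect_lt(po$mass_balance_error, 1e-3)
  expect_true(all(po$conc_ng_ml >= 0))
})

test_that("the intravenous profile declines monotonically after its peak", {
  iv <- simulate_pbpk(adult, drug, dose_regimen("iv_bolus", 50))
  i_max <- which.max(iv$conc_ng_ml)
  expect_true(all(diff(iv$conc_ng_ml[i_max:length(iv$conc_ng_ml)]) <= 1e-9))
})

test_that("exposure is dose-linear at trace doses", {
  lo <- simulate_pbpk(adult, drug,
                      dose_regimen("po", 0.01, formulation = "lint80"),
                      t_end = 72, t_step = 0.25)
  hi <- simulate_pbpk(adult, drug,
                      dose_regimen("po", 0.02, formulation = "lint80"),
                      t_end = 72, t_step = 0.25)
  ratio <- nca_from_simulation(hi)$auc_0_inf / nca_from_simulation(lo)$auc_0_inf
  expect_equal(ratio, 2, tolerance = 0.01)
})

test_that("simulated clearance agrees with the well-stirred closed form", {
  # dense early grid so the venous mixing phase is integrated accurately
  tt <- c(seq(0, 1, by = 0.002), seq(1.1, 150, by = 0.1))
  sim <- simulate_pbpk(adult, drug, dose_regimen("iv_bolus", 0.1), times = tt)
  cl <- nca_from_simulation(sim)$clearance
  expect_equal(cl, closed_form_clearance(adult, drug), tolerance = 0.02)
})

test_that("losing CYP2D6 hurts clearance more than any other single CYP", {
  po <- dose_regimen("po", 50, formulation = "lint80")
  base <- nca_from_simulation(simulate_pbpk(adult, drug, po))$auc_0_inf
  aucs <- vapply(c("CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6"), function(e) {
    ko <- knockout_enzyme(adult, e)
    nca_from_simulation(simulate_pbpk(ko, drug, po))$auc_0_inf
  }, numeric(1))
  expect_true(all(aucs >= base))  # removing a pathway never lowers exposure
  expect_equal(names(which.max(aucs)), "CYP2D6")
})

test_that("zero permeability abolishes oral absorption", {
  d0 <- drug
  d0$caco2_permeability_cm_s <- 0
  sim <- simulate_pbpk(adult, d0, dose_regimen("po", 50,
                                               formulation = "lint80"))
  expect_lt(max(sim$conc_ng_ml), 1e-9)
  expect_lt(sim$mass_balance_error, 1e-3)
})
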