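drug <- drug_parameters()

test_that("packaged study designs parse into usable structures", {
  ids <- study_design_ids()
  expect_length(ids, 12)
  for (id in ids) {
    d <- study_design(id)
    expect_s3_class(d$regimen, "dose_regimen")
    expect_true(all(diff(d$sampling_times_h) > 0))
    expect_gte(d$age_range[1], 2)
  }
  ped <- study_design("po0.556_children")
  expect_true(ped$regimen$per_kg)
  expect_equal(ped$regimen$amount, 0.556)
  expect_equal(study_design("iv50_young")$regimen$route, "iv_bolus")
  expect_error(study_design("nonexistent"), "unknown study design")
})

test_that("the transcribed verification fixture loads intact", {
  pairs <- observed_pk_pairs()
  expect_equal(nrow(pairs), 36)
  expect_equal(sort(unique(pairs$parameter)),
               c("auc_0_inf", "clearance", "cmax"))
  iv_cmax <- pairs[pairs$design_id == "iv50_young" & pairs$parameter == "cmax", ]
  expect_equal(c(iv_cmax$predicted, iv_cmax$observed), c(150.54, 251.1))
  p556 <- pairs[pairs$design_id == "po0.556_children" &
                  pairs$parameter == "cmax", ]
  expect_equal(c(p556$predicted, p556$observed), c(44.32, 44.14))
})

test_that("noise-free single-subject data equals the simulation", {
  obs <- generate_observed("po50_young", drug, noise_cv = 0, n_subjects = 1,
                           seed = 17)
  subj <- obs$truth$cohort[[1]]
  sim <- simulate_pbpk(subj, drug, obs$design$regimen,
                       t_end = max(obs$design$sampling_times_h))
  expected <- approx(sim$time_h, sim$conc_ng_ml,
                     xout = obs$design$sampling_times_h)$y
  expect_equal(obs$data$conc_ng_ml, expected)
})

test_that("synthetic datasets are reproducible and correctly noised", {
  a <- generate_observed("po50_young", drug, noise_cv = 0.15, n_subjects = 4,
                         seed = 5)
  b <- generate_observed("po50_young", drug, noise_cv = 0.15, n_subjects = 4,
                         seed = 5)
  expect_identical(a$data, b$data)

  # identical subjects, so cross-subject spread at the peak is pure noise
  design <- study_design("po50_young")
  design$age_range <- c(30, 30)
  design$weight_range <- c(73, 73)
  design$female_fraction <- 0
  obs <- generate_observed(design, drug, noise_cv = 0.2, n_subjects = 40,
                           seed = 12)
  peak_t <- with(aggregate(conc_ng_ml ~ time_h, obs$data, mean),
                 time_h[which.max(conc_ng_ml)])
  at_peak <- obs$data$conc_ng_ml[obs$data$time_h == peak_t]
  cv <- sd(at_peak) / mean(at_peak)
  expect_gte(cv, 0.15)
  expect_lte(cv, 0.25)
})

test_that("observed CSV schema round-trips", {
  obs <- generate_observed("po25_young_men", drug, noise_cv = 0.1,
                           n_subjects = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observed_csv(obs, path)
  back <- read_observed_csv(path)
  expect_equal(back$conc_ng_ml, obs$data$conc_ng_ml, tolerance = 1e-12)
  expect_error(read_observed_csv(withr::local_tempfile(lines = "a,b\n1,2",
                                                       fileext = ".csv")),
               "columns")
})
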