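drug <- drug_parameters()

test_that("cohort sampling is seed-reproducible with exact sex counts", {
  spec <- population_spec("adults", n = 60, age_range = c(21.1, 31.8),
                          female_fraction = 0.5)
  a <- sample_population(spec, seed = 42)
  b <- sample_population(spec, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(vapply(a, `[[`, character(1), "sex") == "female"), 30)
  ages <- vapply(a, `[[`, numeric(1), "age")
  expect_true(all(ages >= 21.1 & ages <= 31.8))

  # a 1000-individual cohort at 50% females has exactly 500
  big <- population_spec("adults", n = 1000, age_range = c(21.1, 31.8))
  sexes <- vapply(sample_population(big, seed = 1), `[[`, character(1), "sex")
  expect_equal(sum(sexes == "female"), 500)
})

test_that("lognormal variability reproduces the requested CV", {
  spec <- population_spec("adults", n = 3000, age_range = c(25, 35),
                          variability = list(cyp_abundance = 0.30,
                                             volume_scale = 0,
                                             weight = 0))
  cohort <- sample_population(spec, seed = 5)
  mult <- vapply(cohort, function(x) x$enzyme_expression[["CYP2D6"]],
                 numeric(1))
  cv <- sd(mult) / mean(mult)
  expect_gte(cv, 0.27)
  expect_lte(cv, 0.33)
  expect_equal(mean(mult), 1, tolerance = 0.03)
})

test_that("population summaries respect percentile ordering", {
  spec <- population_spec("adults", n = 30, age_range = c(21, 41),
                          female_fraction = 0.5)
  cohort <- sample_population(spec, seed = 9)
  summ <- simulate_population(cohort, drug,
                              dose_regimen("po", 50, formulation = "lint80"),
                              t_step = 0.25)
  expect_equal(length(summ$time_h), length(summ$mean))
  expect_true(all(summ$min <= summ$p5 + 1e-12))
  expect_true(all(summ$p5 <= summ$p95))
  expect_true(all(summ$p95 <= summ$max + 1e-12))
  expect_true(all(summ$mean >= summ$min - 1e-12 &
                    summ$mean <= summ$max + 1e-12))
  expect_equal(nrow(summ$nca), 30)
  expect_length(summ$failures, 0)
})

test_that("degenerate cohorts collapse the percentile band", {
  # a single individual is its own summary
  one <- sample_population(population_spec("x", n = 1, age_range = c(30, 30)),
                           seed = 3)
  s1 <- simulate_population(one, drug, dose_regimen("iv_bolus", 50),
                            t_step = 0.5)
  expect_equal(s1$mean, s1$p5)
  expect_equal(s1$p5, s1$p95)

  # zero variability and point demographics give identical individuals
  spec0 <- population_spec("clone", n = 3, age_range = c(30, 30),
                           female_fraction = 0, weight_range = c(73, 73),
                           variability = list(cyp_abundance = 0,
                                              volume_scale = 0, weight = 0))
  cohort0 <- sample_population(spec0, seed = 8)
  s3 <- simulate_population(cohort0, drug, dose_regimen("iv_bolus", 50),
                            t_step = 0.5)
  expect_equal(s3$p5, s3$p95)
})
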