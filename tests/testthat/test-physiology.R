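test_that("reference individuals satisfy the anatomical invariants", {
  adult <- build_reference_individual(30, "male", body_weight = 73)
  expect_length(adult$organ_volumes, 16)
  expect_true(all(adult$organ_volumes > 0))
  expect_true(all(adult$organ_blood_flows > 0))
  rel <- abs(sum(adult$organ_blood_flows) - adult$cardiac_output) /
    adult$cardiac_output
  expect_lt(rel, 0.01)

  # flow partition holds across ages and sexes
  for (age in c(2, 4.3, 9, 15.5, 33, 71)) {
    for (sex in c("male", "female")) {
      ind <- build_reference_individual(age, sex)
      expect_lt(abs(sum(ind$organ_blood_flows) - ind$cardiac_output) /
                  ind$cardiac_output, 0.01)
      expect_true(all(ind$organ_volumes > 0))
    }
  }
})

test_that("ages below the supported pediatric range are rejected", {
  expect_error(build_reference_individual(1, "male"), "neonate")
  expect_error(build_reference_individual(30, "male", body_weight = -1),
               "positive")
})

test_that("children are anatomically smaller than adults of the same sex", {
  child <- build_reference_individual(8, "female")
  adult <- build_reference_individual(30, "female")
  expect_lt(sum(child$organ_volumes), sum(adult$organ_volumes))
  expect_lt(child$body_weight, adult$body_weight)
})

test_that("individual construction is deterministic", {
  a <- build_reference_individual(7.5, "male")
  b <- build_reference_individual(7.5, "male")
  expect_identical(a, b)
})

test_that("ontogeny curves behave as saturating maturation functions", {
  half <- ontogeny_curve(list(birth_fraction = 0, tm50_y = 3, hill = 1.4))
  expect_equal(ontogeny_fraction(half, 3), 0.5)

  grid <- seq(0, 30, by = 0.1)
  for (enz in c("CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6", "GFR")) {
    f <- ontogeny_fraction(ontogeny_curve(enz), grid)
    expect_true(all(diff(f) >= 0), info = enz)
    expect_true(all(f > 0 & f <= 1), info = enz)
    expect_gte(ontogeny_fraction(ontogeny_curve(enz), 30), 0.95)
    # every packaged curve matures: age 6 at least as mature as age 2
    expect_gte(ontogeny_fraction(ontogeny_curve(enz), 6),
               ontogeny_fraction(ontogeny_curve(enz), 2))
  }
  expect_error(ontogeny_fraction(ontogeny_curve("CYP2D6"), -1), "nonnegative")
})

test_that("unbound fraction scales with albumin as the binding model states", {
  expect_equal(scale_fraction_unbound(0.18, 1), 0.18)
  # direct evaluation of 1 / (1 + r (1 - fu) / fu)
  expect_equal(scale_fraction_unbound(0.18, 0.8),
               1 / (1 + 0.8 * 0.82 / 0.18), tolerance = 1e-12)
  expect_equal(round(scale_fraction_unbound(0.18, 0.8), 3), 0.215)
  # vanishing binding protein frees the drug entirely
  expect_gt(scale_fraction_unbound(0.18, 1e-9), 0.999)
  expect_error(scale_fraction_unbound(1.2, 1), "\\(0, 1\\]")
  expect_error(scale_fraction_unbound(0.18, -1), "nonnegative")
})
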