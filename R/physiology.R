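#' Enzyme and GFR maturation curves
#'
#' Age-dependent maturation is described by a saturating Hill function,
#' \deqn{f(a) = f_0 + (1 - f_0)\,a^h / (a^h + T_{50}^h),}
#' where \eqn{f_0} is the fraction of adult activity at birth, \eqn{T_{50}}
#' the half-maturation age in years and \eqn{h} the Hill coefficient.  The
#' packaged defaults (one per CYP plus glomerular filtration) live in
#' `reference_table("ontogeny")`.
#'
#' @param process Name of a packaged curve (`"CYP1A2"`, `"CYP2C9"`,
#'   `"CYP2C19"`, `"CYP2D6"`, `"GFR"`), or a list with elements
#'   `birth_fraction`, `tm50_y`, `hill`.
#' @return An object of class `ontogeny_curve`.
#' @examples
#' ontogeny_fraction(ontogeny_curve("CYP1A2"), c(2, 6, 30))
#' @export
ontogeny_curve <- function(process) {
  if (is.list(process)) {
    curve <- process
    stopifnot(all(c("birth_fraction", "tm50_y", "hill") %in% names(curve)))
  } else {
    tab <- reference_table("ontogeny")
    row <- tab[tab$process == process, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("no packaged ontogeny curve for process: ", process)
    }
    curve <- list(process = process, birth_fraction = row$birth_fraction,
                  tm50_y = row$tm50_y, hill = row$hill)
  }
  if (curve$birth_fraction < 0 || curve$birth_fraction >= 1) {
    stop("birth_fraction must lie in [0, 1)")
  }
  if (curve$tm50_y <= 0 || curve$hill <= 0) {
    stop("tm50_y and hill must be positive")
  }
  structure(curve, class = "ontogeny_curve")
}

#' Fraction of adult activity at a given age
#'
#' @param curve An [ontogeny_curve()].
#' @param age Age in years (vectorized, must be >= 0).
#' @return Fraction of adult activity in `(0, 1]`; tends to 1 as age grows.
#' @export
ontogeny_fraction <- function(curve, age) {
  if (!inherits(curve, "ontogeny_curve")) curve <- ontogeny_curve(curve)
  if (any(age < 0)) stop("age must be nonnegative")
  f0 <- curve$birth_fraction
  a <- age^curve$hill
  f0 + (1 - f0) * a / (a + curve$tm50_y^curve$hill)
}

#' Scale the unbound plasma fraction with albumin
#'
#' Binding-protein scaling: assuming the bound/unbound equilibrium is
#' proportional to the albumin concentration,
#' \deqn{fu = 1 / (1 + r \,(1 - fu_{adult}) / fu_{adult}),}
#' with \eqn{r} the albumin ratio to the healthy adult.  \eqn{r = 1} returns
#' the adult value; \eqn{r \to 0} frees the drug completely.
#'
#' @param fu_adult Adult unbound fraction in `(0, 1]`.
#' @param albumin_ratio Albumin relative to adult, `> 0` (0 allowed as limit).
#' @return Scaled unbound fraction in `(0, 1]`.
#' @examples
#' scale_fraction_unbound(0.18, 0.8)
#' @export
scale_fraction_unbound <- function(fu_adult, albumin_ratio) {
  if (any(fu_adult <= 0) || any(fu_adult > 1)) {
    stop("fu_adult must lie in (0, 1]")
  }
  if (any(albumin_ratio < 0)) stop("albumin_ratio must be nonnegative")
  1 / (1 + albumin_ratio * (1 - fu_adult) / fu_adult)
}

# Microsomal protein per gram of liver (mg/g) as a function of age: a
# log10-cubic maturation curve on the lower-central band of published
# pediatric values (~25 mg/g at 2-3 y, ~41 in young adults, declining again
# in old age), part of the pediatric clearance scaling.
mppgl_for_age <- function(age) {
  young <- 10^(1.35 + 0.0205 * age - 0.00047 * age^2 + 0.0000028 * age^3)
  # modest senescent decline past the young-adult plateau
  old <- 41.45 - 0.19 * (age - 30)
  ifelse(age <= 30, young, old)
}

# Hematocrit by age/sex (package default, linear in age on a coarse grid).
hematocrit_for_age <- function(age, sex) {
  if (sex == "male") {
    stats::approx(c(2, 12, 18, 100), c(0.37, 0.40, 0.45, 0.45),
                  xout = age, rule = 2)$y
  } else {
    stats::approx(c(2, 12, 18, 100), c(0.37, 0.39, 0.40, 0.40),
                  xout = age, rule = 2)$y
  }
}

#' Construct a reference virtual individual
#'
#' Builds a fully parameterized physiology state for a given age and sex from
#' the packaged reference tables: organ volumes scale with body weight via
#' age-interpolated organ fractions, regional flows partition an allometric
#' cardiac output (exponent 0.75 on weight, with a mild decline after age 40),
#' and enzyme expression multipliers come from the packaged ontogeny curves
#' normalized to the 30-year-old adult.
#'
#' Supported ages are 2 to 100 years; the underlying data exclude pre-term
#' and neonate physiology.
#'
#' @param age Age in years, `2 <= age <= 100`.
#' @param sex `"male"` or `"female"`.
#' @param body_weight Body weight in kg; default interpolated from the growth
#'   table for `(age, sex)`.
#' @param height Height in cm; default from the growth table.
#' @return An object of class `physiology_state`: a list with fields `age`,
#'   `sex`, `body_weight`, `height`, `organ_volumes` (L, 16 compartments),
#'   `organ_blood_flows` (L/h; the liver entry is the hepatic arterial supply,
#'   portal inflow arrives via gut/spleen/stomach), `cardiac_output` (L/h),
#'   `hematocrit`, `gfr_fraction_of_adult`, `albumin_ratio_to_adult`,
#'   `enzyme_expression` (multiplier per CYP, adult = 1), `mppgl` (mg/g),
#'   `shunt_fraction` (portosystemic, 0 in health).
#' @examples
#' adult <- build_reference_individual(30, "male")
#' sum(adult$organ_blood_flows)  # equals cardiac output
#' @export
build_reference_individual <- function(age, sex = c("male", "female"),
                                       body_weight = NULL, height = NULL) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1L || is.na(age)) {
    stop("age must be a single number")
  }
  if (age < 2) {
    stop("age ", age, " y is below the supported range: pre-term, neonate ",
         "and infant (< 2 y) physiology is excluded from this model")
  }
  if (age > 100) stop("age must be <= 100 years")

  growth <- reference_table("growth")
  if (is.null(body_weight)) {
    body_weight <- interp_age(growth, age, "weight_kg", sex)[["weight_kg"]]
  }
  if (is.null(height)) {
    height <- interp_age(growth, age, "height_cm", sex)[["height_cm"]]
  }
  if (body_weight <= 0) stop("body_weight must be positive")
  if (height <= 0) stop("height must be positive")

  ofrac <- reference_table("organ_fractions")
  ocols <- setdiff(names(ofrac), c("sex", "age_y"))
  fr <- interp_age(ofrac, age, ocols, sex)
  volumes <- fr * body_weight            # density ~1 kg/L
  rest_v <- body_weight * max(1 - sum(fr), 0.01)
  organ_volumes <- c(volumes, rest = rest_v)[.dph_organs]

  # Cardiac output: allometric in weight, sex-specific reference, mild
  # senescent decline after 40 y.
  ref <- if (sex == "male") c(co = 390, bw = 73) else c(co = 350, bw = 60)
  co <- ref[["co"]] * (body_weight / ref[["bw"]])^0.75 *
    max(0.7, 1 - 0.003 * max(0, age - 40))

  ffrac <- reference_table("flow_fractions")
  fcols <- setdiff(names(ffrac), c("sex", "age_y"))
  ff <- interp_age(ffrac, age, fcols, sex)
  ff <- ff / sum(ff)                     # exact partition of cardiac output
  flows <- ff * co
  names(flows)[names(flows) == "liver_artery"] <- "liver"
  organ_blood_flows <- flows[.dph_tissues]

  gfr_curve <- ontogeny_curve("GFR")
  gfr <- ontogeny_fraction(gfr_curve, age) *
    max(0.5, 1 - 0.005 * max(0, age - 40))

  alb <- interp_age(reference_table("albumin"), age,
                    "albumin_ratio")[["albumin_ratio"]]

  expr <- vapply(.dph_enzymes, function(enz) {
    curve <- ontogeny_curve(enz)
    ontogeny_fraction(curve, age) / ontogeny_fraction(curve, 30)
  }, numeric(1))

  state <- structure(list(
    age = age, sex = sex, body_weight = body_weight, height = height,
    organ_volumes = organ_volumes,
    organ_blood_flows = organ_blood_flows,
    cardiac_output = co,
    hematocrit = hematocrit_for_age(age, sex),
    gfr_fraction_of_adult = gfr,
    albumin_ratio_to_adult = alb,
    enzyme_expression = expr,
    mppgl = mppgl_for_age(age),
    shunt_fraction = 0
  ), class = "physiology_state")
  validate_physiology(state)
  state
}

#' Validate a physiology state
#'
#' Checks the structural invariants: all volumes and flows strictly positive,
#' the organ flows (excluding lung, which is in series) partition cardiac
#' output within 1%, and enzyme expression multipliers are nonnegative.
#'
#' @param state A `physiology_state`.
#' @return `state`, invisibly; errors on violation.
#' @export
validate_physiology <- function(state) {
  stopifnot(inherits(state, "physiology_state"))
  if (any(state$organ_volumes <= 0)) stop("all organ volumes must be positive")
  if (any(state$organ_blood_flows <= 0)) stop("all organ flows must be positive")
  rel <- abs(sum(state$organ_blood_flows) - state$cardiac_output) /
    state$cardiac_output
  if (rel > 0.01) stop("organ flows do not partition cardiac output (",
                       signif(rel * 100, 3), "% off)")
  if (any(state$enzyme_expression < 0)) {
    stop("enzyme expression multipliers must be nonnegative")
  }
  if (state$hematocrit <= 0 || state$hematocrit >= 1) {
    stop("hematocrit must lie in (0, 1)")
  }
  invisible(state)
}

#' @export
print.physiology_state <- function(x, ...) {
  cat(sprintf("<physiology_state> %s, %.3g y, %.3g kg, %.0f cm\n",
              x$sex, x$age, x$body_weight, x$height))
  cat(sprintf("  cardiac output %.1f L/h, hematocrit %.2f, GFR fraction %.2f\n",
              x$cardiac_output, x$hematocrit, x$gfr_fraction_of_adult))
  cat("  enzyme expression:",
      paste(sprintf("%s %.2f", names(x$enzyme_expression),
                    x$enzyme_expression), collapse = ", "), "\n")
  invisible(x)
}
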