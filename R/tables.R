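#' @keywords internal
"_PACKAGE"

# Cache for packaged reference tables so repeated cohort construction does not
# re-read CSVs from disk.
.dph_cache <- new.env(parent = emptyenv())

#' Path to a packaged data file
#'
#' @param file File name under `inst/extdata`.
#' @return Absolute path to the installed file.
#' @keywords internal
dph_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dphpbpk")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

read_packaged_csv <- function(file) {
  key <- paste0("csv:", file)
  if (!is.null(.dph_cache[[key]])) return(.dph_cache[[key]])
  x <- utils::read.csv(dph_extdata(file), comment.char = "#",
                       stringsAsFactors = FALSE)
  .dph_cache[[key]] <- x
  x
}

#' Packaged reference physiology and drug tables
#'
#' Accessors for the literature-informed tables shipped with the package:
#' growth reference (weight/height by age and sex), organ-volume fractions,
#' regional blood-flow fractions, enzyme/GFR maturation parameters, albumin
#' ratio by age, Rodgers-Rowland tissue composition, impairment scenario
#' modifiers, clinical study designs, and transcribed observed PK summaries.
#' These are package defaults standing in for a proprietary physiology
#' database; they are not values printed in any single source.
#'
#' @param name One of `"growth"`, `"organ_fractions"`, `"flow_fractions"`,
#'   `"ontogeny"`, `"albumin"`, `"tissue_composition"`,
#'   `"scenario_modifiers"`, `"study_designs"`, `"observed_pk"`.
#' @return A `data.frame` with the documented column schema of that table.
#' @examples
#' head(reference_table("growth"))
#' @export
reference_table <- function(name = c("growth", "organ_fractions",
                                     "flow_fractions", "ontogeny", "albumin",
                                     "tissue_composition",
                                     "scenario_modifiers", "study_designs",
                                     "observed_pk")) {
  name <- match.arg(name)
  file <- switch(name,
    growth             = "growth_table.csv",
    organ_fractions    = "organ_fractions.csv",
    flow_fractions     = "flow_fractions.csv",
    ontogeny           = "ontogeny_parameters.csv",
    albumin            = "albumin_ratio.csv",
    tissue_composition = "tissue_composition.csv",
    scenario_modifiers = "scenario_modifiers.csv",
    study_designs      = "study_designs.csv",
    observed_pk        = "observed_pk_summaries.csv")
  read_packaged_csv(file)
}

# Linear interpolation in age within one sex stratum of an age-indexed table;
# ages beyond the grid are clamped to the boundary rows.
interp_age <- function(tab, age, cols, sex = NULL) {
  if (!is.null(sex)) tab <- tab[tab$sex == sex, , drop = FALSE]
  tab <- tab[order(tab$age_y), , drop = FALSE]
  vapply(cols, function(col) {
    stats::approx(tab$age_y, tab[[col]], xout = age, rule = 2)$y
  }, numeric(1))
}

# Names of the 14 perfused tissue compartments (blood and lung handled apart).
.dph_tissues <- c("brain", "heart", "kidney", "liver", "gut", "spleen",
                  "stomach", "muscle", "skin", "adipose", "bone", "gonads",
                  "rest")

.dph_organs <- c("lung", .dph_tissues, "arterial_blood", "venous_blood")

.dph_enzymes <- c("CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6")
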