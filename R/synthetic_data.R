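# Integrity checksum of the transcribed observed-PK fixture; guards against
# silent edits of the packaged file.
.observed_pk_md5 <- "0750d3df07dab20cd6baa316c7e6dbd7"

#' Packaged clinical study designs
#'
#' Returns one packaged study design (cohort demographics, dose, route,
#' formulation, sampling schedule) as a structured list, parsed from
#' `reference_table("study_designs")`.
#'
#' @param design_id One of the packaged design identifiers (see
#'   `reference_table("study_designs")$design_id`).
#' @return An object of class `study_design` with elements `design_id`,
#'   `population`, `cohort`, `age_range`, `female_fraction`, `weight_range`
#'   (or `NULL`), `regimen` (a [dose_regimen()]) and `sampling_times_h`.
#' @examples
#' study_design("po50_young")$sampling_times_h
#' @export
study_design <- function(design_id) {
  tab <- reference_table("study_designs")
  row <- tab[tab$design_id == design_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown study design: ", design_id)
  wr <- c(row$weight_min_kg, row$weight_max_kg)
  structure(list(
    design_id = row$design_id,
    population = row$population,
    cohort = row$cohort,
    age_range = c(row$age_min_y, row$age_max_y),
    female_fraction = row$female_pct / 100,
    weight_range = if (anyNA(wr)) NULL else wr,
    regimen = dose_regimen(route = row$route, amount = row$dose,
                           per_kg = row$dose_unit == "mg_kg",
                           formulation = row$formulation),
    sampling_times_h = as.numeric(strsplit(row$sampling_times_h, ";")[[1]])
  ), class = "study_design")
}

#' All packaged design identifiers
#' @return Character vector of design ids in table order.
#' @export
study_design_ids <- function() {
  reference_table("study_designs")$design_id
}

#' Generate a synthetic observed dataset
#'
#' Emulates a clinical concentration-time dataset for a study design: samples
#' `n_subjects` virtual subjects from the design demographics, simulates each
#' with the engine, resamples onto the design's sampling schedule and applies
#' independent multiplicative lognormal residual noise (arithmetic mean 1,
#' the stated CV).  The generating truth (individual states, seed, noise CV)
#' is retained for recovery tests.
#'
#' @param design A [study_design()] (or a design id).
#' @param truth_drug The [drug_parameters()] used as ground truth.
#' @param noise_cv Residual coefficient of variation (>= 0).
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param variability Inter-individual variability passed to
#'   [population_spec()]; defaults to none so that `noise_cv = 0, n = 1`
#'   reproduces the deterministic simulation exactly.
#' @return An object of class `synthetic_observation`: `data` (data.frame
#'   `subject_id, time_h, conc_ng_ml`), `design`, `truth` (cohort, noise_cv,
#'   seed).
#' @export
generate_observed <- function(design, truth_drug, noise_cv = 0.15,
                              n_subjects = 12, seed = 1,
                              variability = list(cyp_abundance = 0,
                                                 volume_scale = 0,
                                                 weight = 0)) {
  if (is.character(design)) design <- study_design(design)
  stopifnot(inherits(design, "study_design"))
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  spec <- population_spec(label = design$design_id, n = n_subjects,
                          age_range = design$age_range,
                          female_fraction = design$female_fraction,
                          weight_range = design$weight_range,
                          variability = variability)
  cohort <- sample_population(spec, seed)
  ts <- design$sampling_times_h
  rows <- lapply(seq_len(n_subjects), function(i) {
    sim <- simulate_pbpk(cohort[[i]], truth_drug, design$regimen,
                         t_end = max(ts))
    conc <- stats::approx(sim$time_h, sim$conc_ng_ml, xout = ts, rule = 2)$y
    noisy <- pmax(0, conc * lognormal_multiplier(length(ts), noise_cv))
    data.frame(subject_id = i, time_h = ts, conc_ng_ml = noisy)
  })
  structure(list(
    data = do.call(rbind, rows),
    design = design,
    truth = list(cohort = cohort, noise_cv = noise_cv, seed = seed)
  ), class = "synthetic_observation")
}

#' Write/read the observed-data CSV schema
#'
#' Synthetic or real observed datasets use the schema
#' `subject_id, time_h, conc_ng_ml`.
#'
#' @param obs A `synthetic_observation` (or a data.frame in the schema).
#' @param path CSV path.
#' @return `path` (write) / the data.frame (read).
#' @export
write_observed_csv <- function(obs, path) {
  df <- if (inherits(obs, "synthetic_observation")) obs$data else obs
  stopifnot(all(c("subject_id", "time_h", "conc_ng_ml") %in% names(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observed_csv
#' @export
read_observed_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_h", "conc_ng_ml")
  if (!all(need %in% names(df))) {
    stop("observed CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Transcribed predicted/observed PK summary pairs
#'
#' Loads the packaged fixture of source-study NCA summaries for the twelve
#' verification profiles and returns all 36 predicted/observed pairs (Cmax,
#' AUC0-inf, clearance per profile) in [pred_obs_pairs()] layout, with a
#' `population` grouping column and `design_id`.  The file's checksum is
#' verified on load.
#'
#' @return A `pred_obs_pairs` data.frame with 36 rows.
#' @examples
#' pairs <- observed_pk_pairs()
#' nrow(pairs)  # 36
#' @export
observed_pk_pairs <- function() {
  path <- dph_extdata("observed_pk_summaries.csv")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .observed_pk_md5)) {
    stop("packaged observed-PK fixture failed its checksum; the file has ",
         "been modified")
  }
  wide <- reference_table("observed_pk")
  long <- do.call(rbind, lapply(c("cmax", "auc", "cl"), function(par) {
    data.frame(parameter = switch(par, cmax = "cmax", auc = "auc_0_inf",
                                  cl = "clearance"),
               predicted = wide[[paste0(par, "_pre")]],
               observed = wide[[paste0(par, "_obs")]],
               cohort = wide$dose_label,
               dose_label = wide$dose_label,
               population = wide$population,
               design_id = wide$design_id,
               per_kg = wide$per_kg,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  structure(long, class = c("pred_obs_pairs", "data.frame"))
}
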