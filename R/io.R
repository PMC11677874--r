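#' Write a simulation result to CSV
#'
#' Fixed CSV dialect (comma separator, period decimal, UTF-8, header row):
#' columns `time_h, conc_ng_ml`, plus per-compartment amount columns when
#' `compartments = TRUE`.  A sidecar YAML manifest records the regimen,
#' individual demographics, calibration factor and any seed so the artifact
#' can be regenerated.
#'
#' @param sim A [simulate_pbpk()] result.
#' @param path Output CSV path.
#' @param compartments Include per-compartment amount columns?
#' @param manifest_path Optional sidecar YAML path.
#' @param drug Optional [drug_parameters()] recorded in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return Invisibly, `path`.
#' @export
write_simulation_csv <- function(sim, path, compartments = FALSE,
                                 manifest_path = NULL, drug = NULL,
                                 seed = NULL) {
  stopifnot(inherits(sim, "simulation_result"))
  df <- data.frame(time_h = sim$time_h, conc_ng_ml = sim$conc_ng_ml)
  if (compartments) df <- cbind(df, as.data.frame(sim$compartment_amounts))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(manifest_path)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("dphpbpk")),
      regimen = unclass(sim$regimen),
      individual = list(age = sim$individual$age, sex = sim$individual$sex,
                        body_weight = sim$individual$body_weight),
      dose_mg = sim$dose_mg,
      mass_balance_error = sim$mass_balance_error,
      calibration_factor = if (!is.null(drug)) drug$calibration_factor,
      seed = seed)
    yaml::write_yaml(manifest, manifest_path)
  }
  invisible(path)
}

#' Read a simulation CSV
#' @param path CSV written by [write_simulation_csv()].
#' @return A data.frame with at least `time_h` and `conc_ng_ml`.
#' @export
read_simulation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "conc_ng_ml") %in% names(df))) {
    stop("simulation CSV must have columns time_h, conc_ng_ml")
  }
  df
}

#' Batch NCA over a directory of simulation CSVs
#'
#' @param dir Directory containing `*.csv` files in the simulation schema.
#' @param dose,per_kg Dose metadata applied to every curve.
#' @return A data.frame, one NCA row per file.
#' @export
batch_nca <- function(dir, dose, per_kg = FALSE) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no CSV files in ", dir)
  do.call(rbind, lapply(files, function(f) {
    df <- read_simulation_csv(f)
    r <- run_nca(df$time_h, df$conc_ng_ml, dose = dose, per_kg = per_kg)
    data.frame(file = basename(f), cmax = r$cmax, tmax = r$tmax,
               auc_0_t = r$auc_0_t, auc_0_inf = r$auc_0_inf,
               lambda_z = r$lambda_z, clearance = r$clearance,
               stringsAsFactors = FALSE)
  }))
}

#' Plot a population summary
#'
#' Mean curve with 5th-95th centile band and min-max envelope; observed
#' points overlaid when supplied (a visual predictive check).
#'
#' @param summary A [simulate_population()] result.
#' @param observed Optional data.frame `time_h, conc_ng_ml`.
#' @param log_y Log-scale concentration axis?
#' @return A ggplot object.
#' @export
plot_population_summary <- function(summary, observed = NULL, log_y = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- data.frame(time_h = summary$time_h, mean = summary$mean,
                   p5 = summary$p5, p95 = summary$p95,
                   min = summary$min, max = summary$max)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.8) +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)")
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = observed,
                                 ggplot2::aes(x = .data$time_h,
                                              y = .data$conc_ng_ml),
                                 colour = "red")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot exposure distributions as box-whisker summaries
#'
#' @param distributions Named list of `exposure_distribution` objects.
#' @return A ggplot object (boxes at quartiles, whiskers at 5th/95th).
#' @export
plot_exposure_boxes <- function(distributions) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- do.call(rbind, lapply(distributions, function(d) {
    data.frame(group = d$label, p5 = d$p5, q1 = d$q1, median = d$median,
               q3 = d$q3, p95 = d$p95)
  }))
  df$group <- factor(df$group, levels = df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$p5, lower = .data$q1,
                                       middle = .data$median,
                                       upper = .data$q3, ymax = .data$p95),
                          stat = "identity") +
    ggplot2::labs(x = NULL, y = "AUC0-inf (ng*h/mL)")
}
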