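#' Predicted/observed pairs
#'
#' Builds the tidy pair table consumed by the evaluation statistics.
#'
#' @param parameter Character vector: `"cmax"`, `"auc_0_inf"` or
#'   `"clearance"` per pair.
#' @param predicted,observed Positive values in matching units.
#' @param cohort,dose_label Optional annotation columns.
#' @return A `data.frame` of class `pred_obs_pairs`.
#' @export
pred_obs_pairs <- function(parameter, predicted, observed,
                           cohort = NA_character_, dose_label = NA_character_) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("predicted and observed values must be positive")
  }
  structure(data.frame(parameter = parameter, predicted = predicted,
                       observed = observed, cohort = cohort,
                       dose_label = dose_label, stringsAsFactors = FALSE),
            class = c("pred_obs_pairs", "data.frame"))
}

#' Predicted/observed ratio
#'
#' `R = predicted / observed`, the per-parameter fold deviation.
#'
#' @param predicted,observed Positive values in the same units (vectorized).
#' @return The ratio(s).
#' @examples
#' r_ratio(150.54, 251.1)  # 0.60 for the IV peak
#' @export
r_ratio <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("predicted and observed values must be positive")
  }
  predicted / observed
}

#' Average fold error
#'
#' `AFE = 10^(mean(log10(predicted/observed)))`, the geometric mean of the
#' predicted/observed ratios.  Signed logs are used, so systematic under- and
#' over-prediction cancel; see [absolute_average_fold_error()] for the
#' unsigned variant.
#'
#' @param ratios Positive ratios, or a `pred_obs_pairs` table.
#' @return The AFE (scalar).
#' @examples
#' average_fold_error(c(2, 0.5))  # 1: reciprocal cancellation
#' @export
average_fold_error <- function(ratios) {
  if (inherits(ratios, "pred_obs_pairs") || is.data.frame(ratios)) {
    ratios <- r_ratio(ratios$predicted, ratios$observed)
  }
  if (length(ratios) == 0) stop("need at least one ratio")
  if (any(ratios <= 0)) stop("ratios must be positive")
  10^(sum(log10(ratios)) / length(ratios))
}

#' Absolute average fold error
#'
#' `AAFE = 10^(mean(|log10(predicted/observed)|))`, always >= 1; a spread
#' measure that does not let errors of opposite sign cancel.
#'
#' @inheritParams average_fold_error
#' @return The AAFE (scalar).
#' @export
absolute_average_fold_error <- function(ratios) {
  if (inherits(ratios, "pred_obs_pairs") || is.data.frame(ratios)) {
    ratios <- r_ratio(ratios$predicted, ratios$observed)
  }
  if (length(ratios) == 0) stop("need at least one ratio")
  if (any(ratios <= 0)) stop("ratios must be positive")
  10^(sum(abs(log10(ratios))) / length(ratios))
}

#' Two-fold acceptance screen
#'
#' Flags each predicted/observed ratio as acceptable when it falls within
#' `[1/fold, fold]` (default the conventional 0.5-2-fold band).
#'
#' @param ratios Positive ratios, or a `pred_obs_pairs` table.
#' @param fold Acceptance fold, `> 1` (default 2).
#' @return List with `flags` (logical per ratio), `verdict` (all pass?),
#'   `worst` (ratio farthest from 1 on the log scale).
#' @examples
#' two_fold_screen(c(0.6, 1.99, 1.0))$verdict
#' @export
two_fold_screen <- function(ratios, fold = 2) {
  if (inherits(ratios, "pred_obs_pairs") || is.data.frame(ratios)) {
    ratios <- r_ratio(ratios$predicted, ratios$observed)
  }
  if (fold <= 1) stop("fold must exceed 1")
  flags <- ratios >= 1 / fold & ratios <= fold
  list(flags = flags, verdict = all(flags),
       worst = ratios[which.max(abs(log(ratios)))])
}

#' Model-verification report
#'
#' Computes per-pair predicted/observed ratios, per-population per-parameter
#' AFE (and AAFE), and 2-fold flags from a pair table, mirroring the layout
#' of published PBPK verification tables.  When reference (printed) AFE
#' values are supplied, a deviation column shows recomputed minus reference
#' rather than forcing agreement.
#'
#' @param pairs A [pred_obs_pairs()] table (column `population` optional; if
#'   absent, `cohort` is used for grouping).
#' @param reference_afe Optional data.frame with columns `population`,
#'   `parameter`, `afe_printed`.
#' @param fold Acceptance fold (default 2).
#' @return List of class `evaluation_report` with `pairs` (ratios + flags),
#'   `afe` (grouped summary) and `verdict`.
#' @export
evaluation_report <- function(pairs, reference_afe = NULL, fold = 2) {
  stopifnot(is.data.frame(pairs))
  pairs <- as.data.frame(pairs)
  pairs$ratio <- r_ratio(pairs$predicted, pairs$observed)
  pairs$within_fold <- pairs$ratio >= 1 / fold & pairs$ratio <= fold
  grp <- if ("population" %in% names(pairs)) pairs$population else pairs$cohort
  key <- interaction(grp, pairs$parameter, drop = TRUE)
  afe <- do.call(rbind, lapply(split(pairs, key), function(d) {
    data.frame(population = if ("population" %in% names(d)) d$population[1] else d$cohort[1],
               parameter = d$parameter[1],
               n = nrow(d),
               afe = average_fold_error(d$ratio),
               aafe = absolute_average_fold_error(d$ratio),
               stringsAsFactors = FALSE)
  }))
  rownames(afe) <- NULL
  if (!is.null(reference_afe)) {
    afe <- merge(afe, reference_afe, by = c("population", "parameter"),
                 all.x = TRUE, sort = FALSE)
    afe$deviation <- round(afe$afe, 2) - afe$afe_printed
  }
  structure(list(pairs = pairs, afe = afe,
                 verdict = all(pairs$within_fold), fold = fold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d pairs, %d-fold screen: %s\n",
              nrow(x$pairs), x$fold,
              if (x$verdict) "all within bounds" else "violations present"))
  print(x$afe, digits = 3)
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' @param report An `evaluation_report`.
#' @param pairs_path,afe_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_evaluation_report <- function(report, pairs_path = NULL,
                                    afe_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(pairs_path)) {
    utils::write.csv(report$pairs, pairs_path, row.names = FALSE)
  }
  if (!is.null(afe_path)) {
    utils::write.csv(report$afe, afe_path, row.names = FALSE)
  }
  invisible(report)
}
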