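#' Non-compartmental analysis of a concentration-time curve
#'
#' Computes Cmax, Tmax, AUC0-t by the linear-up/log-down trapezoid rule,
#' terminal slope `lambda_z` by log-linear regression (best adjusted R^2 over
#' the last 3-6 points after Tmax), AUC0-inf by `Clast/lambda_z`
#' extrapolation, and clearance `CL = dose / AUC0-inf`.
#'
#' @param times Sampling times, h, strictly increasing, length >= 4.
#' @param concentrations Concentrations, ng/mL, nonnegative.
#' @param dose Dose in mg (or mg/kg when `per_kg = TRUE`).
#' @param per_kg If `TRUE`, clearance is reported in L/h/kg; otherwise L/h.
#' @return An object of class `nca_result`: `cmax`, `tmax`, `auc_0_t`,
#'   `auc_0_inf` (ng*h/mL), `lambda_z` (1/h), `half_life` (h), `clearance`
#'   (L/h or L/h/kg), `extrapolated_fraction`, `lambda_z_points`,
#'   `lambda_z_adj_r2`.  When no positive terminal phase can be fit,
#'   `lambda_z`, `auc_0_inf` and `clearance` are `NA` with a `reason`.
#' @examples
#' t <- seq(0, 24, by = 0.5)
#' run_nca(t, 100 * exp(-0.2 * t), dose = 1)
#' @export
run_nca <- function(times, concentrations, dose, per_kg = FALSE) {
  if (length(times) < 4) stop("need at least 4 time points")
  if (length(times) != length(concentrations)) {
    stop("times and concentrations must have equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  if (dose <= 0) stop("dose must be positive")

  cmax <- max(concentrations)
  tmax <- times[which.max(concentrations)]

  auc_0_t <- auc_linuplogdown(times, concentrations)

  term <- fit_lambda_z(times, concentrations, tmax)
  if (is.na(term$lambda_z)) {
    res <- list(cmax = cmax, tmax = tmax, auc_0_t = auc_0_t,
                auc_0_inf = NA_real_, lambda_z = NA_real_,
                half_life = NA_real_, clearance = NA_real_,
                extrapolated_fraction = NA_real_,
                lambda_z_points = 0L, lambda_z_adj_r2 = NA_real_,
                dose = dose, per_kg = per_kg, reason = term$reason)
    return(structure(res, class = "nca_result"))
  }
  clast <- concentrations[max(which(concentrations > 0))]
  auc_inf <- auc_0_t + clast / term$lambda_z
  structure(list(
    cmax = cmax, tmax = tmax, auc_0_t = auc_0_t, auc_0_inf = auc_inf,
    lambda_z = term$lambda_z, half_life = log(2) / term$lambda_z,
    clearance = dose * 1000 / auc_inf,  # mg -> ug; ug / (ug*h/L) = L/h
    extrapolated_fraction = (auc_inf - auc_0_t) / auc_inf,
    lambda_z_points = term$n, lambda_z_adj_r2 = term$adj_r2,
    dose = dose, per_kg = per_kg, reason = NA_character_
  ), class = "nca_result")
}

# Linear-up/log-down trapezoid; log interval requires both ends positive and
# strictly decreasing, otherwise linear.
auc_linuplogdown <- function(t, c) {
  dt <- diff(t)
  c1 <- c[-length(c)]
  c2 <- c[-1]
  seg <- ifelse(c2 < c1 & c2 > 0 & c1 > 0,
                dt * (c1 - c2) / (log(c1) - log(c2)),
                dt * (c1 + c2) / 2)
  sum(seg)
}

# lambda_z: log-linear fit over the last k points strictly after Tmax,
# k = 3..6, choosing the best adjusted R^2 (standard practice; the fit
# requires a negative slope).
fit_lambda_z <- function(times, conc, tmax) {
  ok <- which(times > tmax & conc > 0)
  if (length(ok) < 3) {
    return(list(lambda_z = NA_real_, n = 0L, adj_r2 = NA_real_,
                reason = "fewer than 3 positive points after Tmax"))
  }
  best <- list(lambda_z = NA_real_, n = 0L, adj_r2 = -Inf,
               reason = "no decreasing terminal phase found")
  for (k in 3:min(6, length(ok))) {
    idx <- utils::tail(ok, k)
    fit <- stats::lm(log(conc[idx]) ~ times[idx])
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) next
    adj <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.finite(adj) && adj > best$adj_r2) {
      best <- list(lambda_z = -slope, n = k, adj_r2 = adj, reason = NA_character_)
    }
  }
  if (!is.finite(best$adj_r2)) best$adj_r2 <- NA_real_
  best
}

#' @export
print.nca_result <- function(x, ...) {
  cl_unit <- if (isTRUE(x$per_kg)) "L/h/kg" else "L/h"
  cat(sprintf("<nca_result> Cmax %.4g ng/mL at %.3g h\n", x$cmax, x$tmax))
  cat(sprintf("  AUC0-t %.4g, AUC0-inf %.4g ng*h/mL (%.1f%% extrapolated)\n",
              x$auc_0_t, x$auc_0_inf, 100 * x$extrapolated_fraction))
  cat(sprintf("  lambda_z %.4g 1/h (n=%d, adjR2=%.3f), CL %.4g %s\n",
              x$lambda_z, x$lambda_z_points, x$lambda_z_adj_r2,
              x$clearance, cl_unit))
  invisible(x)
}

#' NCA for a simulation result
#'
#' Convenience wrapper running [run_nca()] on a [simulate_pbpk()] output,
#' optionally resampled to a sparse clinical sampling schedule first.
#'
#' @param sim A `simulation_result`.
#' @param sampling_times_h Optional sampling schedule; concentrations are
#'   linearly interpolated onto it.
#' @return An `nca_result`; the dose and per-kg flag are taken from the
#'   simulation's regimen.
#' @export
nca_from_simulation <- function(sim, sampling_times_h = NULL) {
  stopifnot(inherits(sim, "simulation_result"))
  t <- sim$time_h
  c <- sim$conc_ng_ml
  if (!is.null(sampling_times_h)) {
    c <- stats::approx(t, c, xout = sampling_times_h, rule = 2)$y
    t <- sampling_times_h
  }
  run_nca(t, c, dose = sim$regimen$amount, per_kg = sim$regimen$per_kg)
}
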