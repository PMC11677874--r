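#' Load drug parameters from a config file
#'
#' Reads a structured YAML drug-parameter configuration (the packaged default
#' is the diphenhydramine set: MW 255.36 g/mol, log P 3.27, pKa 8.98
#' monoprotic base, fu 0.18 bound to albumin, Caco-2 permeability
#' 5.43e-4 cm/s, renal clearance 0.01 L/h/kg, and Michaelis-Menten kinetics
#' for CYP1A2/2C9/2C19/2D6).
#'
#' @param path Path to a YAML config; default the packaged diphenhydramine
#'   file.
#' @return An object of class `drug_parameters`.
#' @examples
#' drug <- drug_parameters()
#' drug$pka
#' @export
drug_parameters <- function(path = dph_extdata("diphenhydramine.yaml")) {
  cfg <- yaml::read_yaml(path)
  validate_drug(structure(cfg, class = "drug_parameters"))
}

#' Write drug parameters to a config file
#'
#' @param drug A `drug_parameters` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_drug_config <- function(drug, path) {
  stopifnot(inherits(drug, "drug_parameters"))
  x <- unclass(drug)
  yaml::write_yaml(x, path)
  invisible(path)
}

validate_drug <- function(drug) {
  with(drug, {
    if (molecular_weight <= 0) stop("molecular_weight must be positive")
    if (fu_plasma_adult <= 0 || fu_plasma_adult > 1) {
      stop("fu_plasma_adult must lie in (0, 1]")
    }
    if (pka <= 0 || pka >= 14) stop("pka must lie in (0, 14)")
    if (renal_clearance_l_h_kg < 0) stop("renal clearance must be nonnegative")
    if (blood_to_plasma_ratio <= 0) {
      stop("blood_to_plasma_ratio must be positive")
    }
    if (caco2_permeability_cm_s < 0) stop("caco2 permeability must be >= 0")
  })
  for (ek in drug$enzyme_kinetics) {
    if (ek$vmax_pmol_min_pmol <= 0 || ek$km_um <= 0 ||
        ek$abundance_pmol_mg < 0) {
      stop("enzyme kinetics must have positive vmax/km, nonnegative abundance")
    }
  }
  drug
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters> %s: MW %.2f, logP %.2f, pKa %.2f, fu %.2f\n",
              x$name, x$molecular_weight, x$log_p, x$pka, x$fu_plasma_adult))
  cat(sprintf("  B:P %.2f, CLr %.3g L/h/kg, calibration factor %.4g\n",
              x$blood_to_plasma_ratio, x$renal_clearance_l_h_kg,
              x$calibration_factor))
  invisible(x)
}

#' Ionized fraction of a monoprotic base
#'
#' Henderson-Hasselbalch: `1 / (1 + 10^(pH - pKa))`.
#'
#' @param pka Dissociation constant.
#' @param ph Ambient pH (vectorized).
#' @return Fraction ionized in `(0, 1)`.
#' @examples
#' ionized_fraction(8.98, 7.4)
#' @export
ionized_fraction <- function(pka, ph) {
  1 / (1 + 10^(ph - pka))
}

#' Rodgers-Rowland tissue-to-plasma partition coefficients
#'
#' Mechanistic tissue-composition prediction of total tissue:plasma partition
#' coefficients for a moderate-to-strong monoprotic base (pKa > 7), in which
#' ionized drug associates with acidic phospholipids.  The association
#' constant is calibrated from the blood-to-plasma ratio via blood-cell
#' partitioning, then applied to every tissue with its packaged composition:
#' \deqn{Kp_u = f_{EW} + \frac{1 + 10^{pKa - pH_{IW}}}{1 + 10^{pKa - pH_p}}
#'   f_{IW} + \frac{K_{a,AP}\,[AP]\,10^{pKa - pH_{IW}}}{1 + 10^{pKa - pH_p}}
#'   + \frac{P f_{NL} + (0.3 P + 0.7) f_{NP}}{1 + 10^{pKa - pH_p}}}
#' and \eqn{Kp = fu \cdot Kp_u}.  Adipose uses the olive-oil partition
#' convention, \eqn{\log P_{vow} = 1.115 \log P - 1.35}.
#'
#' @param drug A [drug_parameters()] object (must be a base with pKa > 7).
#' @param compositions Tissue-composition table; default the packaged one.
#' @param fu Unbound plasma fraction; defaults to the adult value in `drug`.
#' @param plasma_ph Plasma pH (default 7.4).
#' @return Named numeric vector of Kp (tissue:plasma, total) for the 14 model
#'   tissues.
#' @examples
#' kp <- partition_coefficients(drug_parameters())
#' kp["adipose"] < kp["muscle"]  # acidic phospholipids dominate lean tissue
#' @export
partition_coefficients <- function(drug,
                                   compositions = reference_table("tissue_composition"),
                                   fu = drug$fu_plasma_adult,
                                   plasma_ph = 7.4) {
  if (drug$pka <= 7) {
    stop("this implementation covers moderate-to-strong bases (pKa > 7)")
  }
  missing <- setdiff(c("lung", .dph_tissues), compositions$tissue)
  if (length(missing)) {
    stop("missing tissue composition rows: ", paste(missing, collapse = ", "))
  }
  if (!"blood_cells" %in% compositions$tissue) {
    stop("missing tissue composition rows: blood_cells")
  }

  pka <- drug$pka
  P <- 10^drug$log_p
  hct <- 0.45
  bp <- drug$blood_to_plasma_ratio
  ion_p <- 10^(pka - plasma_ph)          # ionized:neutral in plasma

  bc <- compositions[compositions$tissue == "blood_cells", ]
  ion_bc <- 10^(pka - bc$ph_iw)
  kpu_bc <- (bp - (1 - hct)) / (hct * fu)
  if (kpu_bc <= 0) {
    stop("blood-to-plasma ratio and hematocrit imply nonpositive blood-cell ",
         "partitioning; check blood_to_plasma_ratio")
  }
  nl_bc <- (P * bc$f_nl + (0.3 * P + 0.7) * bc$f_np) / (1 + ion_p)
  iw_bc <- bc$f_iw * (1 + ion_bc) / (1 + ion_p)
  ka_ap <- (kpu_bc - iw_bc - nl_bc) * (1 + ion_p) / (bc$ap_mg_g * ion_bc)
  if (ka_ap <= 0) {
    stop("calibrated acidic-phospholipid association constant is nonpositive")
  }

  rows <- compositions[match(.dph_tissues, compositions$tissue), ]
  kp <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    Pt <- if (r$tissue == "adipose") 10^(1.115 * drug$log_p - 1.35) else P
    ion_iw <- 10^(pka - r$ph_iw)
    kpu <- r$f_ew +
      r$f_iw * (1 + ion_iw) / (1 + ion_p) +
      ka_ap * r$ap_mg_g * ion_iw / (1 + ion_p) +
      (Pt * r$f_nl + (0.3 * Pt + 0.7) * r$f_np) / (1 + ion_p)
    kpu * fu
  }, numeric(1))
  names(kp) <- rows$tissue
  # Lung tissue for the series compartment uses its own composition row.
  lung_row <- compositions[compositions$tissue == "lung", ]
  ion_iw <- 10^(pka - lung_row$ph_iw)
  kp_lung <- fu * (lung_row$f_ew +
    lung_row$f_iw * (1 + ion_iw) / (1 + ion_p) +
    ka_ap * lung_row$ap_mg_g * ion_iw / (1 + ion_p) +
    (P * lung_row$f_nl + (0.3 * P + 0.7) * lung_row$f_np) / (1 + ion_p))
  c(lung = kp_lung, kp)
}

#' First-order absorption rate constant from Caco-2 permeability
#'
#' Transforms in vitro monolayer permeability into a lumen-to-portal
#' absorption rate constant with a cylindrical small-intestine geometry:
#' `ka = Papp (cm/h) * 2 / r`, where `r` is the packaged effective lumen
#' radius (1.25 cm), i.e. the surface-to-volume ratio of the absorbing
#' segment.  The transform is linear in permeability.
#'
#' @param drug A [drug_parameters()] object.
#' @param lumen_radius_cm Effective lumen radius (default 1.25 cm).
#' @return Absorption rate constant in 1/h.
#' @examples
#' absorption_rate_constant(drug_parameters())
#' @export
absorption_rate_constant <- function(drug, lumen_radius_cm = 1.25) {
  papp_cm_h <- drug$caco2_permeability_cm_s * 3600
  papp_cm_h * 2 / lumen_radius_cm
}
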