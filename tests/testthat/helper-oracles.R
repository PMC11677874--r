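# Independent oracles used across the test files.

# Brute-force transcription of the tissue-composition partition equations for
# a moderate-to-strong monoprotic base, written directly from the published
# scheme and kept independent of the package implementation (scalar loop,
# explicit intermediate quantities).
rr_base_kpu_oracle <- function(log_p, pka, fu, bp, comp_row, bc_row,
                               ph_plasma = 7.4, hct = 0.45) {
  P <- 10^log_p
  Y <- 1 + 10^(pka - ph_plasma)                # plasma ionization term
  X_bc <- 1 + 10^(pka - bc_row$ph_iw)
  kpu_bc <- (bp - (1 - hct)) / (hct * fu)
  nlnp_bc <- (P * bc_row$f_nl + (0.3 * P + 0.7) * bc_row$f_np) / Y
  ka_ap <- (kpu_bc - bc_row$f_iw * X_bc / Y - nlnp_bc) * Y /
    (bc_row$ap_mg_g * (X_bc - 1))
  X <- 1 + 10^(pka - comp_row$ph_iw)
  P_t <- if (comp_row$tissue == "adipose") 10^(1.115 * log_p - 1.35) else P
  comp_row$f_ew +
    comp_row$f_iw * X / Y +
    ka_ap * comp_row$ap_mg_g * (X - 1) / Y +
    (P_t * comp_row$f_nl + (0.3 * P_t + 0.7) * comp_row$f_np) / Y
}

# Analytic multi-exponential concentration model and its exact AUC0-inf.
multiexp_conc <- function(t, A, lambda) {
  rowSums(vapply(seq_along(A),
                 function(i) A[i] * exp(-lambda[i] * t),
                 numeric(length(t))))
}

multiexp_auc_inf <- function(A, lambda) sum(A / lambda)
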