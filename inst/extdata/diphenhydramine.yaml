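# Diphenhydramine drug-parameter configuration (package default fixture).
# Physicochemistry, binding, permeability and enzyme kinetics as compiled for
# the whole-body model; enzyme abundances, MPPGL handling and the calibration
# factor are package defaults, not compound measurements.
name: diphenhydramine
molecular_weight: 255.36        # g/mol
log_p: 3.27
pka: 8.98                       # monoprotic base
compound_type: monoprotic_base
water_solubility_mg_ml: 3.06    # at pH 7.00
solubility_ph: 7.00
fu_plasma_adult: 0.18
binding_protein: albumin
blood_to_plasma_ratio: 0.8      # package default, editable; see vignette
caco2_permeability_cm_s: 5.43e-4
specific_organ_permeability_cm_min: 0.19   # stored for reference; the model is perfusion-limited
renal_clearance_l_h_kg: 0.01
# Single global scalar applied to the summed hepatic intrinsic clearance,
# fitted once by bisection on the adult model-building profiles and then
# reused unchanged for every population, dose and scenario.
calibration_factor: 5.66335
enzyme_kinetics:
  - enzyme: CYP1A2
    vmax_pmol_min_pmol: 14
    km_um: 295
    abundance_pmol_mg: 52      # pmol per mg microsomal protein, package default
  - enzyme: CYP2C9
    vmax_pmol_min_pmol: 4.43
    km_um: 134
    abundance_pmol_mg: 73
  - enzyme: CYP2C19
    vmax_pmol_min_pmol: 11
    km_um: 55.7
    abundance_pmol_mg: 14
  - enzyme: CYP2D6
    vmax_pmol_min_pmol: 2.38
    km_um: 1.12
    abundance_pmol_mg: 8
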