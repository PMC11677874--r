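# Hill-type maturation curves, fraction of adult activity:
#   fraction(age) = birth_fraction + (1 - birth_fraction) * age^hill / (age^hill + tm50_y^hill)
# Package defaults: CYP2D6 and CYP2C9 near-adult by 1 y, CYP2C19 intermediate,
# CYP1A2 the slowest of the four; GFR essentially mature by age 2 (kept so
# renal-impairment scenarios can reuse the same field).
process,birth_fraction,tm50_y,hill
CYP1A2,0.05,3.5,1.8
CYP2C9,0.15,0.20,1.2
CYP2C19,0.12,2.5,1.2
CYP2D6,0.05,0.25,1.5
GFR,0.30,0.40,2.0
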