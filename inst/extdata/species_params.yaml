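# Default vital-rate parameters for the two-species larch stand simulator.
# Calibrated set: sibirica = fast, warmth-demanding, crowding-sensitive;
# gmelinii = slow, cold- and competition-tolerant.
version: 1
sibirica:
  height_growth_max: 0.30   # m/yr
  gdd_min: 260              # degC day, base 5
  gdd_halfsat: 300
  comp_sens_growth: 0.25    # per unit NCI
  comp_sens_estab: 8.00     # per unit NCI
  comp_mort_coeff: 0.012    # 1/yr per unit NCI
  fecundity: 15             # seeds per m above maturity per yr
  maturity_height: 2.0      # m
  dispersal_mean: 22        # m
  estab_prob: 0.08
  background_mort: 0.015    # 1/yr
  seed_mort: 0.5            # 1/yr
  max_seed_age: 5           # yr
  max_age: 300              # yr
  max_height: 30            # m
gmelinii:
  height_growth_max: 0.18
  gdd_min: 250
  gdd_halfsat: 300
  comp_sens_growth: 0.10
  comp_sens_estab: 0.12
  comp_mort_coeff: 0.004
  fecundity: 16
  maturity_height: 1.8
  dispersal_mean: 18
  estab_prob: 0.04
  background_mort: 0.012
  seed_mort: 0.45
  max_seed_age: 6
  max_age: 400
  max_height: 25
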