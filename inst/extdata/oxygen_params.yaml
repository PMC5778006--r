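# Oxygen transport parameter set.
# Units: D cm^2/s; solubilities umol cm^-3 mmHg^-1; M0 umol cm^-3 min^-1;
# pressures mmHg; C0 umol per cm^3 of red cells; K_iv mmHg per (umol cm^-1 min^-1).
# D and alpha follow the Green's-function oxygen-transport literature
# (3.89e-5 cm3 O2 cm^-3 mmHg^-1 = 1.736e-3 umol cm^-3 mmHg^-1 at 22,414 cm3/mol).
D_cm2_s: 2.41e-5
alpha_umol_cm3_mmHg: 1.736e-3
# maximal (demand) consumption; the exerted demand is M0 * demand_scale,
# demand_scale being the midpoint of the 80-85% operating range of CMRO2.
M0_umol_cm3_min: 1.71
demand_scale: 0.825
P0_mmHg: 1.0
# haemoglobin-bound O2 in a fully saturated red cell (0.5 cm3 O2 / cm3 RBC)
C0_umol_cm3: 22.3
hill_n: 3.0
P50_mmHg: 38.0
# effective solubility of oxygen in blood, approximated by a constant
alpha_eff_umol_cm3_mmHg: 1.53e-3
alpha_plasma_umol_cm3_mmHg: 1.53e-3
alpha_rbc_umol_cm3_mmHg: 1.50e-3
# intravascular resistance to radial O2 transport, diameter-indexed lookup
# (linear interpolation, constant beyond the ends); magnitudes chosen to give
# intravascular drops of a few mmHg at physiological efflux rates
K_iv:
  diameter_um: [4, 6, 10, 20, 40]
  K_mmHg_per_umol_cm_min: [6.0e4, 5.0e4, 3.0e4, 1.5e4, 1.0e4]
K_iv_constant_fallback: 3.0e4
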