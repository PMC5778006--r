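# Unit conversion constants. The user-facing unit system is
# micrometre / mmHg / nl/min / mm/s / cP / dyn/cm^2; conversions below are the
# exact factors that make Poiseuille conductance in those units come out right.

# 1 mmHg in Pa
.MMHG_PA <- 133.322387415

# Conductance prefactor: with d, l in um and mu in cP,
#   G [nl/min per mmHg] = COND_UM_CP_NLMIN * pi * d^4 / (128 * mu * l)
# derived from SI: (1e-6)^4 / (1e-3 * 1e-6) [m^3/s per Pa] * MMHG_PA * 1e12 * 60
.COND_UM_CP_NLMIN <- .MMHG_PA * 1e-24 / (1e-3 * 1e-6) * 1e12 * 60

# Velocity: v [mm/s] = Q [nl/min] * VEL_FACTOR / d^2 [um^2]
# v = (Q*1e-12/60) / (pi d^2/4 * 1e-12) * 1e3
.VEL_FACTOR <- 4e3 / 60 / pi

# Wall shear stress: tau [dyn/cm^2] = SHEAR_FACTOR * 32 * mu [cP] * Q [nl/min] / (pi d^3 [um^3])
# from 1 cP = 1e-2 dyn s/cm^2, 1 nl/min = 1e-6/60 cm^3/s, 1 um = 1e-4 cm
.SHEAR_FACTOR <- 1e-2 * (1e-6 / 60) / (1e-4)^3

# um -> cm
.UM_CM <- 1e-4
# nl/min -> cm^3/min
.NLMIN_CM3MIN <- 1e-6
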