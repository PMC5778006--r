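# Blood rheology parameter set.
# viscosity_law:
#   pries_invivo_2005  - in-vivo apparent viscosity law including the
#                        endothelial surface layer (default)
#   pries_invitro_1992 - in-vitro (glass tube) law; exhibits the classical
#                        Fahraeus-Lindqvist minimum near 7 um
# phase_separation_law:
#   pries_2005 - empirical red-cell partition law at diverging bifurcations
plasma_viscosity_cP: 1.0
viscosity_law: pries_invivo_2005
viscosity_coefficients:
  pries_invivo_2005:
    # mu*_45(D) = a1*exp(a2*D) + a3 + a4*exp(a5*D^a6)
    a1: 6.0
    a2: -0.085
    a3: 3.2
    a4: -2.44
    a5: -0.06
    a6: 0.645
    # shape exponent C(D)
    c1: 0.8
    c2: -0.075
    c3: 1.0e-11
    c4: 12.0
    # effective lumen shrinkage (D/(D - delta))^2, twice applied
    delta_um: 1.1
    reference_hd: 0.45
  pries_invitro_1992:
    a1: 220.0
    a2: -1.3
    a3: 3.2
    a4: -2.44
    a5: -0.06
    a6: 0.645
    c1: 0.8
    c2: -0.075
    c3: 1.0e-11
    c4: 12.0
    delta_um: 0.0
    reference_hd: 0.45
phase_separation_law: pries_2005
phase_separation_coefficients:
  pries_2005:
    a: -13.29
    b: 6.98
    x0: 0.964
hd_max: 1.0
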