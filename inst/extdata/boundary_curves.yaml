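# Boundary-value curves for pial pressure assignment and capillary inflow PO2.
# Pressure-diameter curves are logistic in diameter (mmHg):
#   arteriole: p(d) = p_cap + a_span / (1 + exp(-(d - a_mid)/a_scale))
#   venule:    p(d) = p_cap - v_span / (1 + exp(-(d - v_mid)/v_scale))
# The arteriolar side rises towards ~75 mmHg at the largest pial arterioles,
# the venular side falls towards ~15 mmHg, and both pivot around the mean
# capillary pressure of 31 mmHg.
pressure:
  p_cap_mmHg: 31
  a_span_mmHg: 44
  a_mid_um: 10
  a_scale_um: 3
  v_span_mmHg: 16
  v_mid_um: 8
  v_scale_um: 2.5
# Capillary inflow PO2 versus cortical depth (mmHg, depth in um):
#   po2(z) = base + amp * exp(-z / decay)
# smooth, positive, decreasing from the surface value base+amp.
po2_depth:
  base_mmHg: 38
  amp_mmHg: 22
  decay_um: 150
  depth_max_um: 400
  # analytic mean over [0, depth_max]: base + amp*decay/depth_max*(1-exp(-depth_max/decay))
  declared_mean_mmHg: 45.67676152
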