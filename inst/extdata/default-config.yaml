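# Canonical model configuration; every value here equals the package default
# and can be overridden. Used by the CLI via --config.
geometry:
  ioa_end: 10          # mm
  canal_end: 14        # mm
  total_length: 30     # mm
  radius: {ioa: 0.7, canal: 0.7, eoa: 0.7}        # mm
  compliance: {ioa: 3.0e-4, canal: 0.0, eoa: 3.0e-4}  # fractional area / mmHg
  probe_ioa: 5         # mm
  probe_eoa: 22        # mm
  probe_halfwidth: 1   # mm
load:
  icp: 20              # mmHg
  pio: 4               # mmHg
  pe: 0                # mmHg (0 = monitoring mode)
  inlet_mean: 60       # mmHg
  inlet_amplitude: 20  # mmHg peak-to-peak
  period: 1.0          # s
  waveform: rect_sine
  outlet_resistance: 223.5   # mmHg.s/mL
sim:
  dt: 0.004            # s
  samples_per_cycle: 250
  n_cycles: 3
  ramp_cycles: 1
  n_nodes: 61
  density: 1050        # kg/m^3
  viscosity: 3.5e-3    # Pa.s
  tol: 1.0e-4
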