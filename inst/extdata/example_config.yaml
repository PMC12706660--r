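# Example lvadflow study configuration (all keys optional; clinical units at
# this boundary: L/min, mmHg, mm).
cardiac_output_lpm: 5
pressure:
  systolic_mmhg: 120
  diastolic_mmhg: 80
waveform:
  period: 0.8
  systolic_fraction: 0.375
  notch_fraction: 0.05
  notch_depth: 0.1
solver:
  dt: 0.001
  n_cycles: 3
# per-segment geometry overrides
geometry:
  desc_thoracic: {radius_mm: 10, length_mm: 200}
# scenario set (omit to use the default five)
scenarios:
  baseline: {heart_lpm: 5}
  FA40: {heart_lpm: 3, site: right_femoral, lvad_lpm: 2}
  FA60: {heart_lpm: 2, site: right_femoral, lvad_lpm: 3}
  AA40: {heart_lpm: 3, site: right_axillary, lvad_lpm: 2}
  AA60: {heart_lpm: 2, site: right_axillary, lvad_lpm: 3}
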