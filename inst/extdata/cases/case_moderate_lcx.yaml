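# Synthetic case: moderate LCX stenosis with a marginal branch upstream.
case_id: moderate_lcx
target: lcx
lengths:
  l_lad: 105
  l_lcx: 95
  l_rca_rv: 60
  l_rca_lv: 110
  cutoff_diameter_mm: 1
branching:
  r_p: 1.6
  r_d: [0.9]
  k: 2
hemo:
  sbp: 140
  dbp: 81
  hr: 67
  stroke_volume: 65
  hct: 0.402
  p_ra: 5
geometry:
  nominal_radius: 1.4
  length: 18
  pitch: 0.2
  ellipticity: 1.15
  noise_amplitude: 0.015
  seed: 23
  stenoses:
    - {center_s: 9, width: 5, area_reduction: 0.6}
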