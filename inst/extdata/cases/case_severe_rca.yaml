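# Synthetic case: severe focal RCA stenosis; two side branches upstream.
case_id: severe_rca
target: rca
lengths:
  l_lad: 100
  l_lcx: 100
  l_rca_rv: 70
  l_rca_lv: 100
  cutoff_diameter_mm: 1
branching:
  r_p: 1.9
  r_d: [1.0, 0.7]
  k: 2
hemo:
  sbp: 140
  dbp: 81
  hr: 67
  stroke_volume: 65
  hct: 0.402
  p_ra: 5
geometry:
  nominal_radius: 1.5
  length: 22
  pitch: 0.2
  ellipticity: 1.1
  noise_amplitude: 0.015
  seed: 37
  stenoses:
    - {center_s: 11, width: 4, area_reduction: 0.9}
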