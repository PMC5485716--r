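# Synthetic case: mild focal LAD stenosis, reference-cohort hemodynamics.
case_id: mild_lad
target: lad
lengths:
  l_lad: 110
  l_lcx: 100
  l_rca_rv: 70
  l_rca_lv: 100
  cutoff_diameter_mm: 1
branching:
  r_p: 1.75          # proximal LAD radius, mm
  r_d: [1.0]         # one diagonal leaves before the imaged segment
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
  length: 20
  pitch: 0.2
  ellipticity: 1.1
  noise_amplitude: 0.015
  seed: 11
  stenoses:
    - {center_s: 10, width: 4, area_reduction: 0.3}
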