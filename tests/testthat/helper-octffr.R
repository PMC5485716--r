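# Shared fixture builders. Everything is generated in code; seeds fixed.

ref_hemo <- function(...) patient_hemo(...)

# noise-free uniform tube profile (analytic limit)
uniform_profile <- function(radius = 1.5, length = 20, pitch = 0.2) {
  lumen_profile(generate_pullback(
    stenosis_spec(radius, length, pitch, noise_amplitude = 0)))
}

# lumen profile built directly from exact areas, bypassing polygons
exact_profile <- function(s, area) {
  structure(list(s = s, area = area, r_eff = sqrt(area / pi),
                 length = s[length(s)]),
            class = "lumen_profile")
}

# loss model with prescribed coefficients (for algebraic solver tests);
# the generous cross-section keeps the laminar-range check quiet
fake_loss <- function(a_v, a_t, n = 6, area = 12) {
  s <- seq(0, 10, length.out = n)
  structure(list(a_v = a_v, a_t = a_t,
                 a_v_cum = a_v * s / max(s), i_min = ceiling(n / 2),
                 k_t = 1.52, reference = "proximal",
                 blood = blood_props(0.4),
                 profile = exact_profile(s, rep(area, n))),
            class = "roi_loss_model")
}

# steady (pulseless) driving pressures at a given level
steady_waveforms <- function(p = 100, hr = 60) {
  hemo <- patient_hemo(sbp = p, dbp = p, hr = hr)
  list(ao = aortic_waveform(hemo), lv = lv_waveform(hemo))
}

# capacitance-free, compression-free, collateral-free network
algebraic_network <- function(r_total, p_ra = 5) {
  build_network(r_total, caps = rep(1e-12, 3), gamma = 0, p_ra = p_ra,
                p_coll_threshold = -Inf)
}
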