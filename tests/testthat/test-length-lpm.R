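test_that("RCA effective length matches hand-evaluated values in both variants", {
  # harmonic ("as printed") form: 1/(3.46/50 + 1/60)
  expect_equal(rca_effective_length(50, 60, 3.46, "as_printed"),
               1 / (3.46 / 50 + 1 / 60), tolerance = 1e-12)
  # additive form: l_rv/alpha + l_lv
  expect_equal(rca_effective_length(70, 100, 3.46, "additive"),
               70 / 3.46 + 100, tolerance = 1e-12)
  # no RV-feeding vessels contribute
  expect_equal(rca_effective_length(0, 100, 3.46, "additive"), 100)
})

test_that("degenerate RCA inputs raise classed errors", {
  expect_error(rca_effective_length(0, 0, 3.46), class = "octffr_invalid_input")
  expect_error(rca_effective_length(0, 100, 3.46, "as_printed"),
               class = "octffr_degenerate_formula")
  expect_error(rca_effective_length(100, 0, 3.46, "as_printed"),
               class = "octffr_degenerate_formula")
  expect_error(rca_effective_length(50, 60, alpha = 0),
               class = "octffr_invalid_input")
})

test_that("flow fractions are the normalized effective lengths", {
  f <- flow_fractions(branch_lengths(110, 100, 70, 100), 3.46, "additive")
  expect_equal(round(c(f$f_lad, f$f_lcx, f$f_rca), 3), c(0.333, 0.303, 0.364))
  # symmetry: equal effective lengths split in thirds
  f3 <- flow_fractions(branch_lengths(80, 80, 0, 80))
  expect_equal(c(f3$f_lad, f3$f_lcx, f3$f_rca), rep(1 / 3, 3),
               tolerance = 1e-12)
  # fully degenerate tree (every effective length zero)
  degenerate <- branch_lengths(100, 0, 0, 0)
  degenerate$l_lad <- 0
  expect_error(flow_fractions(degenerate), class = "octffr_invalid_input")
})

test_that("flow fractions are a unit simplex and monotone in branch length", {
  set.seed(42)
  for (i in 1:200) {
    l <- branch_lengths(runif(1, 1, 200), runif(1, 1, 200),
                        runif(1, 0, 150), runif(1, 1, 200))
    f <- flow_fractions(l, alpha = runif(1, 2.42, 4.5))
    v <- c(f$f_lad, f$f_lcx, f$f_rca)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
  # longer LAD -> larger LAD fraction, smaller LAD resistance
  hemo <- ref_hemo()
  l1 <- branch_lengths(100, 100, 70, 100)
  l2 <- branch_lengths(140, 100, 70, 100)
  f1 <- flow_fractions(l1); f2 <- flow_fractions(l2)
  expect_gt(f2$f_lad, f1$f_lad)
  expect_lt(branch_resistances(f2, hemo)$r_lad,
            branch_resistances(f1, hemo)$r_lad)
})

test_that("branch resistances follow the coronary-fraction rule and conserve flow", {
  # CO = 5000 mL/min, 4% rule, MAP 95, P_ra 5 -> R_LAD = 90/(0.33*3.333)
  f <- flow_fractions(branch_lengths(33, 30, 0, 37))
  hemo <- patient_hemo(sbp = 125, dbp = 80, hr = 100, stroke_volume = 50,
                       hct = 0.4, p_ra = 5)
  r <- branch_resistances(f, hemo, coronary_fraction = 0.04,
                          map_estimate = 95)
  expect_equal(r$q_cor, 200 / 60, tolerance = 1e-12)
  expect_equal(r$delta_p, 90)
  expect_equal(r$r_lad, 90 / (0.33 * (200 / 60)), tolerance = 1e-9)
  # flow conservation at the aortic root
  q_back <- r$delta_p / r$r_lad + r$delta_p / r$r_lcx + r$delta_p / r$r_rca
  expect_equal(q_back, r$q_cor, tolerance = 1e-9)
})

test_that("a zero-fraction branch is reported as infinite resistance", {
  l <- branch_lengths(100, 0, 0, 100)
  expect_error(branch_resistances(flow_fractions(l), ref_hemo()),
               class = "octffr_infinite_resistance")
  expect_error(branch_resistances(flow_fractions(l), ref_hemo(),
                                  coronary_fraction = 0.5),
               class = "octffr_invalid_input")
})

test_that("amplification factor matches hand evaluation and flags non-physical trees", {
  expect_equal(amp_factor(branching_spec(2, numeric())), 1.0)
  expect_equal(amp_factor(branching_spec(2, 1)), 0.75)
  expect_equal(amp_factor(branching_spec(3, c(1, 2))), 4 / 9,
               tolerance = 1e-12)
  expect_error(amp_factor(branching_spec(2, 2)),
               class = "octffr_non_physical_branching")
  expect_error(amp_factor(branching_spec(2, c(1.5, 1.5))),
               class = "octffr_non_physical_branching")
})

test_that("amplification factor stays in (0, 1] over randomized valid trees", {
  set.seed(7)
  for (k in c(2, 2.5, 3)) {
    n_ok <- 0
    while (n_ok < 300) {
      r_p <- runif(1, 1, 3)
      r_d <- runif(sample(0:4, 1), 0.05, r_p * 0.999)
      if (length(r_d) && sum((r_d / r_p)^k) >= 1) next
      a <- amp_factor(branching_spec(r_p, r_d, k))
      expect_true(a > 0 && a <= 1)
      n_ok <- n_ok + 1
    }
  }
})

test_that("distal segment resistance is parent resistance divided by AMP_R", {
  expect_equal(roi_total_resistance(100, 1.0)$r_roi, 100)
  expect_equal(roi_total_resistance(100, 0.5)$r_roi, 200)
  expect_equal(roi_total_resistance(81.8, 0.75)$r_roi, 81.8 / 0.75,
               tolerance = 1e-12)
  expect_error(roi_total_resistance(100, 0),
               class = "octffr_non_physical_branching")
  # monotone non-increasing in amp_r; never below the parent value
  amps <- seq(0.05, 1, by = 0.05)
  rr <- vapply(amps, function(a) roi_total_resistance(55, a)$r_roi,
               numeric(1))
  expect_true(all(diff(rr) < 0))
  expect_true(all(rr >= 55))
})

test_that("branch lengths round-trip through JSON", {
  l <- branch_lengths(110.5, 98.25, 70, 101.125, cutoff_diameter = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_branch_lengths(l, p)
  expect_equal(read_branch_lengths(p), l)
})
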