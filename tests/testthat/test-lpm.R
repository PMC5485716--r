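test_that("aortic waveform is periodic with the prescribed extremes", {
  wf <- aortic_waveform(patient_hemo(sbp = 140, dbp = 81, hr = 67))
  expect_equal(wf$period, 60 / 67)
  tg <- seq(0, wf$period, length.out = 5000)
  expect_equal(max(wf$value(tg)), 140, tolerance = 1e-6)
  expect_equal(min(wf$value(tg)), 81, tolerance = 1e-6)
  expect_gt(wf$mean, 81); expect_lt(wf$mean, 140)
  expect_equal(wf$value(tg), wf$value(tg + 3 * wf$period), tolerance = 1e-12)
  # pulseless limit
  flat <- aortic_waveform(patient_hemo(sbp = 100, dbp = 100))
  expect_true(all(flat$value(tg) == 100))
})

test_that("LV waveform peaks at systolic pressure and transmits via gamma", {
  hemo <- patient_hemo(sbp = 140, dbp = 81, hr = 67)
  wf <- lv_waveform(hemo)
  t_sys <- 0.35 * wf$period
  expect_equal(wf$value(t_sys / 2), 140)
  expect_equal(wf$value(0.9 * wf$period), 8)
  expect_equal(0.75 * max(wf$value(seq(0, wf$period, length.out = 5000))),
               105, tolerance = 1e-6)
})

test_that("network construction distributes R_ROI and rejects bad splits", {
  net <- build_network(200, splits = c(0.32, 0.52, 0.16))
  expect_equal(c(net$r_coa, net$r_coc, net$r_cov), c(64, 104, 32))
  expect_equal(net$r_coa + net$r_coc + net$r_cov, net$r_roi,
               tolerance = 1e-9)
  expect_equal(net$r_coll, 5 * 200)
  expect_error(build_network(200, splits = c(1, 0, 0)),
               class = "octffr_invalid_config")
  expect_error(build_network(200, splits = c(0.5, 0.4, 0.2)),
               class = "octffr_invalid_config")
})

test_that("hyperemia scales only the compartment resistances", {
  net <- build_network(200)
  hyp <- apply_hyperemia(net, 0.25)
  expect_equal(hyp$r_coa, net$r_coa * 0.25)
  expect_equal(hyp$r_roi, net$r_roi * 0.25)
  expect_equal(hyp$c_coa, net$c_coa)
  expect_equal(hyp$r_coll, net$r_coll)
  expect_true(hyp$hyperemic)
  ident <- apply_hyperemia(net, 1)
  expect_equal(ident$r_coa, net$r_coa)
  expect_error(apply_hyperemia(net, 0), class = "octffr_invalid_input")
  expect_error(apply_hyperemia(net, 1.5), class = "octffr_invalid_input")
})

test_that("derivatives vanish on a consistent resistor-chain equilibrium", {
  net <- build_network(120, gamma = 0.75, p_ra = 5)
  q <- 1.3
  p_cov <- 5 + q * net$r_coa
  p_coc <- p_cov + q * net$r_cov
  p_coa <- p_coc + q * net$r_coc
  d <- lpm_derivatives(lpm_state(p_coa, p_coc, p_cov), q, p_lv = 60, net,
                       p_ao = 95, dp_imp_dt = 0)
  expect_equal(unname(d), c(0, 0, 0), tolerance = 1e-12)
})

test_that("the collateral switch opens above threshold and feeds below it", {
  net <- build_network(120, p_coll_threshold = 30)
  st_above <- lpm_state(30 + 1e-9, 20, 10)
  d_above <- lpm_derivatives(st_above, 0, 0, net, p_ao = 95)
  st_below <- lpm_state(25, 20, 10)
  d_below <- lpm_derivatives(st_below, 0, 0, net, p_ao = 95)
  # collateral inflow raises dp_coa/dt only when the switch is closed
  q12_above <- (st_above$p_coa - 20) / net$r_coc
  expect_equal(unname(d_above["p_coa"]), -q12_above / net$c_coa,
               tolerance = 1e-9)
  q_coll <- (95 - 25) / net$r_coll
  q12_below <- (25 - 20) / net$r_coc
  expect_equal(unname(d_below["p_coa"]),
               (q_coll - q12_below) / net$c_coa, tolerance = 1e-9)
  # lowering the threshold can only reduce collateral flow, never below 0
  thresholds <- c(40, 30, 26, 20, 10)
  qc <- vapply(thresholds, function(th) {
    n2 <- build_network(120, p_coll_threshold = th)
    if (25 < th) max(0, (95 - 25)) / n2$r_coll else 0
  }, numeric(1))
  expect_true(all(diff(qc) <= 0) && all(qc >= 0))
})

test_that("implicit stepping converges to the closed-form steady state", {
  net <- build_network(150, p_ra = 5, gamma = 0.75, p_coll_threshold = -Inf)
  q <- 0.9; p_lv <- 40
  st <- lpm_state(90, 90, 90)
  for (i in 1:6000) st <- advance_lpm(net, st, q, p_lv, 95, dt = 0.02)
  expect_equal(st$p_cov, 5 + q * net$r_coa, tolerance = 1e-6)
  expect_equal(st$p_coc, 5 + q * (net$r_coa + net$r_cov), tolerance = 1e-6)
  expect_equal(st$p_coa, 5 + q * (net$r_coa + net$r_cov + net$r_coc),
               tolerance = 1e-6)
})

test_that("small-step implicit integration matches a reference ODE solver", {
  skip_if_not_installed("deSolve")
  net <- build_network(100, p_ra = 5, gamma = 0.75, p_coll_threshold = -Inf)
  # smooth analytic drivers so the reference integrator sees exact rates
  p_lv <- function(t) 40 + 30 * sin(2 * pi * t)
  dp_lv <- function(t) 30 * 2 * pi * cos(2 * pi * t)
  q_in <- function(t) 1 + 0.5 * sin(2 * pi * t)   # exogenous inflow
  rhs <- function(t, y, parms) {
    st <- lpm_state(y[1], y[2], y[3])
    list(unname(lpm_derivatives(st, q_in(t), p_lv(t), net, p_ao = 95,
                                dp_imp_dt = net$gamma * dp_lv(t))))
  }
  y0 <- c(80, 60, 20)
  ref <- deSolve::lsoda(y0, seq(0, 0.5, by = 0.05), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  dt <- 1e-4
  st <- lpm_state(y0[1], y0[2], y0[3])
  for (i in seq_len(round(0.5 / dt))) {
    t1 <- i * dt
    st <- advance_lpm(net, st, q_in(t1), p_lv(t1), 95, dt,
                      p_lv_prev = p_lv(t1 - dt))
  }
  final <- ref[nrow(ref), -1]
  expect_equal(c(st$p_coa, st$p_coc, st$p_cov), unname(final),
               tolerance = 2e-3)
})

test_that("vanishing capacitance reproduces the instantaneous algebraic solution", {
  net <- build_network(150, caps = rep(1e-12, 3), gamma = 0, p_ra = 5,
                       p_coll_threshold = -Inf)
  q <- 1.4
  st <- advance_lpm(net, lpm_state(50, 50, 50), q, 0, 95, dt = 0.01)
  expect_equal(st$p_coa, 5 + q * net$r_roi, tolerance = 1e-6)
})
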