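#' Driving pressure waveforms
#'
#' `aortic_waveform()` builds a periodic aortic pressure: a `sin^2` rise
#' from diastolic to systolic pressure over the systolic fraction of the
#' cycle, then diastolic run-off (the `sin^2` envelope returns to DBP at
#' end-systole, so the diastolic limb decays from DBP, i.e. stays at DBP).
#' `lv_waveform()` builds the left-ventricular pressure: `sbp * sin^2`
#' during systole and a low diastolic baseline. Intramyocardial
#' compression is modelled downstream as `gamma * P_LV`.
#'
#' @param hemo A [patient_hemo()] object.
#' @param systolic_fraction Fraction of the cycle in systole (default 0.35).
#' @param diastolic_mmHg LV diastolic baseline, mmHg (default 8).
#' @return An object of class `waveform`: list with `period` (s),
#'   `value(t)` (vectorized, periodic) and the numerical cycle `mean`.
#' @examples
#' wf <- aortic_waveform(patient_hemo())
#' wf$period; wf$mean
#' @export
aortic_waveform <- function(hemo, systolic_fraction = 0.35) {
  stopifnot(inherits(hemo, "patient_hemo"))
  period <- 60 / hemo$hr
  t_sys <- systolic_fraction * period
  sbp <- hemo$sbp; dbp <- hemo$dbp
  value <- function(t) {
    tt <- t %% period
    ifelse(tt < t_sys, dbp + (sbp - dbp) * sin(pi * tt / t_sys)^2, dbp)
  }
  make_waveform(period, value)
}

#' @rdname aortic_waveform
#' @export
lv_waveform <- function(hemo, systolic_fraction = 0.35, diastolic_mmHg = 8) {
  stopifnot(inherits(hemo, "patient_hemo"))
  period <- 60 / hemo$hr
  t_sys <- systolic_fraction * period
  sbp <- hemo$sbp
  value <- function(t) {
    tt <- t %% period
    ifelse(tt < t_sys, sbp * sin(pi * tt / t_sys)^2, diastolic_mmHg)
  }
  make_waveform(period, value)
}

make_waveform <- function(period, value) {
  tg <- seq(0, period, length.out = 2001)[-2001]
  structure(list(period = period, value = value, mean = mean(value(tg))),
            class = "waveform")
}

#' Build the distal lumped-parameter network
#'
#' Distributes the total distal resistance `R_ROI` over three RC
#' compartments in series (arterioles, capillaries, veins), each with a
#' compliance to ground; the arteriolar and capillary compliances are
#' referenced to the intramyocardial pressure `gamma * P_LV` (systolic
#' compression of intramural vessels), the venous one to zero. A
#' collateral resistor from the aorta switches in when the arteriolar
#' node pressure falls below `p_coll_threshold`.
#'
#' Wiring: the segment outlet feeds node `coa` directly; node-to-node
#' resistors are `r_coc` (coa -> coc) and `r_cov` (coc -> cov), and the
#' terminal venous-to-atrium resistor is `r_coa`, so the series chain
#' totals exactly `R_ROI`.
#'
#' @param r_roi A [roi_total_resistance()] result (or a bare number,
#'   mmHg·s/mL).
#' @param splits Named or positional fractions `(f_coa, f_coc, f_cov)`
#'   summing to 1; defaults 0.32/0.52/0.16.
#' @param caps Compartment compliances `(c_coa, c_coc, c_cov)`, mL/mmHg;
#'   defaults 0.01/0.02/0.05.
#' @param gamma Intramyocardial transmission coefficient (default 0.75).
#' @param p_ra Right-atrial pressure, mmHg.
#' @param r_coll_multiple Collateral resistance as a multiple of `R_ROI`
#'   (default 5).
#' @param p_coll_threshold Arteriolar pressure (mmHg) below which the
#'   collateral switch closes (default 30).
#' @return An object of class `lpm_network`.
#' @export
build_network <- function(r_roi, splits = c(0.32, 0.52, 0.16),
                          caps = c(0.01, 0.02, 0.05), gamma = 0.75,
                          p_ra = 5, r_coll_multiple = 5,
                          p_coll_threshold = 30) {
  r_total <- if (inherits(r_roi, "roi_resistance")) r_roi$r_roi else r_roi
  if (!is.finite(r_total) || r_total <= 0)
    octffr_error("R_ROI must be > 0", "invalid_input")
  splits <- as.numeric(splits); caps <- as.numeric(caps)
  if (length(splits) != 3 || any(splits <= 0) ||
      abs(sum(splits) - 1) > 1e-12)
    octffr_error("splits must be three positive fractions summing to 1",
                 "invalid_config")
  if (length(caps) != 3 || any(caps <= 0))
    octffr_error("capacitances must be three positive values",
                 "invalid_config")
  structure(list(r_coa = splits[1] * r_total, r_coc = splits[2] * r_total,
                 r_cov = splits[3] * r_total,
                 c_coa = caps[1], c_coc = caps[2], c_cov = caps[3],
                 r_coll = r_coll_multiple * r_total,
                 p_coll_threshold = p_coll_threshold,
                 gamma = gamma, p_ra = p_ra, r_roi = r_total,
                 hyperemic = FALSE),
            class = "lpm_network")
}

#' Scale distal resistances to a hyperemic state
#'
#' Maximal pharmacological vasodilation is modelled by multiplying the
#' three compartment resistances by `factor` (default 0.25, i.e. distal
#' resistance drops to 25% of resting). Compliances, the collateral
#' resistance and `gamma` are unchanged.
#'
#' @param net An [build_network()] network.
#' @param factor Multiplier in (0, 1].
#' @return The scaled network, with `hyperemic = TRUE`.
#' @export
apply_hyperemia <- function(net, factor = 0.25) {
  stopifnot(inherits(net, "lpm_network"))
  if (!is.finite(factor) || factor <= 0 || factor > 1)
    octffr_error("hyperemia factor must lie in (0, 1]", "invalid_input")
  net$r_coa <- net$r_coa * factor
  net$r_coc <- net$r_coc * factor
  net$r_cov <- net$r_cov * factor
  net$r_roi <- net$r_roi * factor
  net$hyperemic <- TRUE
  net
}

#' Node-pressure state of the network
#'
#' @param p_coa,p_coc,p_cov Node pressures, mmHg.
#' @return An object of class `lpm_state`.
#' @export
lpm_state <- function(p_coa, p_coc, p_cov) {
  if (any(!is.finite(c(p_coa, p_coc, p_cov))))
    octffr_error("node pressures must be finite", "invalid_input")
  structure(list(p_coa = p_coa, p_coc = p_coc, p_cov = p_cov),
            class = "lpm_state")
}

## Collateral conductance given the switch state.
coll_flow <- function(net, p_coa, p_ao) {
  if (p_coa < net$p_coll_threshold) max(0, p_ao - p_coa) / net$r_coll else 0
}

#' Time derivatives of the network state
#'
#' Pure function giving `d(p_coa, p_coc, p_cov)/dt` for the wiring
#' described in [build_network()]. The arteriolar and capillary
#' compliances store `p_node - p_imp` with `p_imp = gamma * p_lv`, so the
#' intramyocardial pressure rate `dp_imp_dt` enters those two equations.
#'
#' @param state An [lpm_state()].
#' @param q_in Inflow from the imaged-segment outlet, mL/s.
#' @param p_lv Left-ventricular pressure now, mmHg.
#' @param net An [build_network()] network.
#' @param p_ao Aortic pressure now (collateral source), mmHg.
#' @param dp_imp_dt Time derivative of the intramyocardial pressure,
#'   mmHg/s (0 for steady analyses).
#' @return Named numeric vector `c(p_coa, p_coc, p_cov)` of derivatives.
#' @export
lpm_derivatives <- function(state, q_in, p_lv, net, p_ao = state$p_coa,
                            dp_imp_dt = 0) {
  stopifnot(inherits(state, "lpm_state"), inherits(net, "lpm_network"))
  q12 <- (state$p_coa - state$p_coc) / net$r_coc
  q23 <- (state$p_coc - state$p_cov) / net$r_cov
  q_out <- (state$p_cov - net$p_ra) / net$r_coa   # terminal venous resistor
  q_coll <- coll_flow(net, state$p_coa, p_ao)
  c(p_coa = (q_in + q_coll - q12) / net$c_coa + dp_imp_dt,
    p_coc = (q12 - q23) / net$c_coc + dp_imp_dt,
    p_cov = (q23 - q_out) / net$c_cov)
}

#' One implicit time step of the network
#'
#' Backward-Euler step of [lpm_derivatives()]; the RC system is stiff for
#' small compliances, and the implicit step is unconditionally stable and
#' reproduces the instantaneous algebraic resistor solution in the
#' vanishing-compliance limit. The collateral switch state is resolved
#' consistently: the linear system is solved with the switch set from the
#' current pressure and re-solved once if the resulting arteriolar
#' pressure contradicts that setting.
#'
#' @param net An [build_network()] network.
#' @param state Current [lpm_state()].
#' @param q_in Inflow over the step, mL/s.
#' @param p_lv,p_ao LV/aortic pressure at the new time, mmHg.
#' @param dt Step, s.
#' @param p_lv_prev LV pressure at the old time (for the intramyocardial
#'   rate term); defaults to `p_lv`.
#' @return The updated `lpm_state`.
#' @export
advance_lpm <- function(net, state, q_in, p_lv, p_ao, dt, p_lv_prev = p_lv) {
  stopifnot(inherits(net, "lpm_network"), inherits(state, "lpm_state"))
  if (!is.finite(dt) || dt <= 0)
    octffr_error("dt must be > 0", "invalid_input")
  dpimp <- net$gamma * (p_lv - p_lv_prev)
  g12 <- 1 / net$r_coc; g23 <- 1 / net$r_cov; gout <- 1 / net$r_coa
  solve_step <- function(closed) {
    gc <- if (closed) 1 / net$r_coll else 0
    a11 <- net$c_coa / dt + gc + g12
    a22 <- net$c_coc / dt + g12 + g23
    a33 <- net$c_cov / dt + g23 + gout
    b1 <- net$c_coa / dt * (state$p_coa + dpimp) + q_in + gc * p_ao
    b2 <- net$c_coc / dt * (state$p_coc + dpimp)
    b3 <- net$c_cov / dt * (state$p_cov) + gout * net$p_ra
    ## tridiagonal elimination (3x3, off-diagonals -g12, -g23)
    w2 <- a22 - g12^2 / a11
    y2 <- b2 + g12 * b1 / a11
    w3 <- a33 - g23^2 / w2
    y3 <- b3 + g23 * y2 / w2
    p3 <- y3 / w3
    p2 <- (y2 + g23 * p3) / w2
    p1 <- (b1 + g12 * p2) / a11
    c(p1, p2, p3)
  }
  closed <- state$p_coa < net$p_coll_threshold
  p <- solve_step(closed)
  if (!is.finite(p[1]))
    octffr_error("implicit step failed to produce finite pressures",
                 "numerical")
  new_closed <- p[1] < net$p_coll_threshold
  if (new_closed != closed) p <- solve_step(new_closed)
  lpm_state(p[1], p[2], p[3])
}

#' @export
print.lpm_network <- function(x, ...) {
  cat(sprintf(paste0("Coronary LPM (R_ROI = %.1f mmHg·s/mL%s): R %0.1f/",
                     "%0.1f/%0.1f, C %0.3g/%0.3g/%0.3g, gamma %.2f, ",
                     "R_coll %.0f (< %.0f mmHg)\n"),
              x$r_roi, if (x$hyperemic) ", hyperemic" else "",
              x$r_coa, x$r_coc, x$r_cov, x$c_coa, x$c_coc, x$c_cov,
              x$gamma, x$r_coll, x$p_coll_threshold))
  invisible(x)
}
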