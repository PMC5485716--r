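#' Blood viscosity from hematocrit (Einstein dilute-suspension model)
#'
#' `mu = mu_plasma * (1 + 2.5 * hct)`.
#'
#' @param hct Hematocrit, fraction in (0, 1).
#' @param mu_plasma Plasma viscosity, mPa·s (default 1.2).
#' @return Dynamic viscosity, mPa·s.
#' @examples
#' blood_viscosity(0.402)  # 2.406 mPa.s at the cohort-median hematocrit
#' @export
blood_viscosity <- function(hct, mu_plasma = 1.2) {
  if (!is.finite(hct) || hct <= 0 || hct >= 1)
    octffr_error("hematocrit must lie in (0, 1)", "invalid_input")
  if (!is.finite(mu_plasma) || mu_plasma <= 0)
    octffr_error("plasma viscosity must be > 0", "invalid_input")
  mu_plasma * (1 + 2.5 * hct)
}

#' Blood properties bundle
#'
#' @inheritParams blood_viscosity
#' @param rho Density, kg/m^3 (default 1060).
#' @return An object of class `blood_props` with fields `mu` (mPa·s),
#'   `rho` (kg/m^3), `hct`.
#' @export
blood_props <- function(hct, mu_plasma = 1.2, rho = 1060) {
  if (!is.finite(rho) || rho <= 0)
    octffr_error("density must be > 0", "invalid_input")
  structure(list(mu = blood_viscosity(hct, mu_plasma), rho = rho, hct = hct),
            class = "blood_props")
}

#' Lumped loss coefficients of an imaged segment
#'
#' Reduces the lumen profile to the two coefficients of the quasi-steady
#' pressure-drop law `dp = a_v q + a_t q |q|`:
#' * `a_v`, the Poiseuille viscous coefficient, is the axial integral of
#'   `128 mu / (pi D(s)^4)` (trapezoidal rule on the frame grid);
#' * `a_t`, the post-stenotic separation (Borda-Carnot-type) loss,
#'   is `k_t * rho / 2 * (1/A_min - 1/A_ref)^2`, zero for an
#'   unobstructed segment.
#' Both are returned in clinical units (mmHg·s/mL, mmHg·s^2/mL^2).
#'
#' @param profile A [lumen_profile()].
#' @param blood A [blood_props()] bundle.
#' @param k_t Empirical separation-loss constant (default 1.52).
#' @param reference Which area serves as `A_ref`: the proximal frame
#'   (`"proximal"`, default) or the largest frame (`"max_area"`).
#' @return An object of class `roi_loss_model` with `a_v`, `a_t`, the
#'   cumulative viscous coefficient `a_v_cum(s)`, the index of the minimal
#'   lumen area, and the `profile`.
#' @export
loss_coefficients <- function(profile, blood, k_t = 1.52,
                              reference = c("proximal", "max_area")) {
  stopifnot(inherits(profile, "lumen_profile"), inherits(blood, "blood_props"))
  reference <- match.arg(reference)
  if (any(profile$area <= 0))
    octffr_error("non-positive lumen area", "invalid_geometry")
  if (k_t < 0)
    octffr_error("k_t must be >= 0", "invalid_input")
  mu_si <- blood$mu * 1e-3               # mPa.s -> Pa.s
  d_si <- 2 * profile$r_eff * 1e-3       # mm -> m
  s_si <- profile$s * 1e-3
  integrand <- 128 * mu_si / (pi * d_si^4)       # Pa.s/m^3 per metre
  a_v_cum <- drop(pracma::cumtrapz(s_si, integrand)) * .Rconv
  a_v <- a_v_cum[length(a_v_cum)]
  i_min <- which.min(profile$area)
  a_min_si <- profile$area[i_min] * 1e-6         # mm^2 -> m^2
  a_ref_si <- switch(reference,
                     proximal = profile$area[1],
                     max_area = max(profile$area)) * 1e-6
  a_t <- if (a_min_si >= a_ref_si) 0 else
    k_t * blood$rho / 2 * (1 / a_min_si - 1 / a_ref_si)^2 * .Kconv
  structure(list(a_v = a_v, a_t = a_t, a_v_cum = a_v_cum, i_min = i_min,
                 k_t = k_t, reference = reference, blood = blood,
                 profile = profile),
            class = "roi_loss_model")
}

## Signed root of a_v q + a_t q|q| = dp.
roi_flow_root <- function(a_v, a_t, dp) {
  if (dp == 0) return(0)
  sgn <- sign(dp); m <- abs(dp)
  q <- if (a_t == 0) m / a_v
  else (-a_v + sqrt(a_v^2 + 4 * a_t * m)) / (2 * a_t)
  sgn * q
}

#' Quasi-steady pressure-flow solve of the imaged segment
#'
#' Solves `p_in - p_out = a_v q + a_t q |q|` for the unique sign-correct
#' flow, then reconstructs the axial pressure by distributing the viscous
#' drop along the local Poiseuille integrand and placing the separation
#' drop at the minimal-area frame.
#'
#' @param loss A [loss_coefficients()] model.
#' @param p_in,p_out Inlet/outlet pressures, mmHg.
#' @param warn_reynolds Warn when the throat Reynolds number exceeds 2000
#'   (the laminar-flow assumption).
#' @return An object of class `roi_solution`: `q` (mL/s), `p` (mmHg at
#'   each axial grid point), `u_mean` (mm/s, = 1000 q / area).
#' @examples
#' prof <- lumen_profile(generate_pullback(
#'   stenosis_spec(1.5, 20, 0.5, noise_amplitude = 0)))
#' loss <- loss_coefficients(prof, blood_props(0.402))
#' solve_roi_quasisteady(loss, 100, 95)$q
#' @export
solve_roi_quasisteady <- function(loss, p_in, p_out, warn_reynolds = TRUE) {
  stopifnot(inherits(loss, "roi_loss_model"))
  if (!is.finite(p_in) || !is.finite(p_out))
    octffr_error("boundary pressures must be finite", "invalid_input")
  if (loss$a_v == 0 && loss$a_t == 0)
    octffr_error("both loss coefficients are zero: flow is indeterminate",
                 "indeterminate_flow")
  q <- roi_flow_root(loss$a_v, loss$a_t, p_in - p_out)
  p <- p_in - q * loss$a_v_cum
  if (loss$a_t > 0 && q != 0) {
    sep <- loss$a_t * q * abs(q)
    i <- seq_along(p) >= loss$i_min
    p[i] <- p[i] - sep
  }
  if (warn_reynolds && q != 0) {
    prof <- loss$profile
    v_throat <- abs(q) * 1e-6 / (prof$area[loss$i_min] * 1e-6)   # m/s
    re <- loss$blood$rho * v_throat * 2 * prof$r_eff[loss$i_min] * 1e-3 /
      (loss$blood$mu * 1e-3)
    if (re > 2000)
      warning(sprintf("throat Reynolds number %.0f exceeds 2000; %s", re,
                      "laminar assumption questionable"), call. = FALSE)
  }
  structure(list(q = q, p = p, u_mean = 1000 * q / loss$profile$area,
                 s = loss$profile$s),
            class = "roi_solution")
}
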