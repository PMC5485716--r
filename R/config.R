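#' Default simulation settings
#'
#' Nested list of every tunable parameter with its default, overridable
#' per case (YAML `settings:` block or the `settings` argument of
#' [case_config()]). Blocks: `length_lpm` (flow-split and resistance
#' calibration), `blood`, `roi_solver`, `lpm` (network), `coupling`
#' (interface and time-marching controls).
#'
#' @return A nested named list.
#' @export
octffr_settings <- function() {
  list(
    length_lpm = list(
      alpha = 3.46,               # LV-to-RV volume ratio
      rca_length_variant = "additive",
      coronary_fraction = 0.04),  # resting coronary flow / cardiac output
    blood = list(
      mu_plasma_mPas = 1.2,
      rho_kg_m3 = 1060),
    roi_solver = list(
      k_t = 1.52,                 # separation-loss constant
      reference = "proximal"),
    lpm = list(
      splits = c(0.32, 0.52, 0.16),
      capacitances = c(0.01, 0.02, 0.05),  # mL/mmHg
      gamma = 0.75,
      collateral = list(threshold_mmHg = 30, r_multiple = 5),
      hyperemia_factor = 0.25,
      systolic_fraction = 0.35,
      lv_diastolic_mmHg = 8),
    coupling = list(
      dt_fraction = 0.001,
      relax = 0.5,
      tol = 1e-6,
      max_iter = 50,
      ffr_tol = 1e-4,
      max_cycles = 20))
}

#' Assemble a simulation case
#'
#' @param lengths A [branch_lengths()] object.
#' @param branching A [branching_spec()] for the side branches upstream of
#'   the imaged segment.
#' @param hemo A [patient_hemo()] object.
#' @param geometry Either a [stenosis_spec()] (synthetic pullback) or a
#'   path to a contour-stack CSV.
#' @param target Which territory hosts the imaged segment: `"lad"`,
#'   `"lcx"` or `"rca"`.
#' @param settings Overrides merged over [octffr_settings()].
#' @param case_id Optional label.
#' @return An object of class `case_config`.
#' @export
case_config <- function(lengths, branching, hemo, geometry,
                        target = c("lad", "lcx", "rca"),
                        settings = list(), case_id = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(lengths, "branch_lengths"),
            inherits(branching, "branching_spec"),
            inherits(hemo, "patient_hemo"))
  if (is.character(geometry)) {
    if (!file.exists(geometry))
      octffr_error(paste("contour file not found:", geometry),
                   "invalid_config")
  } else if (!inherits(geometry, "stenosis_spec")) {
    octffr_error("geometry must be a stenosis_spec or a contour CSV path",
                 "invalid_config")
  }
  structure(list(case_id = case_id %||% "case", lengths = lengths,
                 branching = branching, hemo = hemo, geometry = geometry,
                 target = target,
                 settings = merge_config(octffr_settings(), settings)),
            class = "case_config")
}

#' Read a case from YAML
#'
#' Expected top-level keys: `case_id`, `target`, `lengths`, `branching`,
#' `hemo`, `geometry` (either stenosis-generator fields or a
#' `contour_file` path, resolved relative to the YAML file), and an
#' optional `settings` block of overrides.
#'
#' @param path YAML file path.
#' @return A [case_config()] object.
#' @export
read_case_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  lengths <- branch_lengths(y$lengths$l_lad, y$lengths$l_lcx,
                            y$lengths$l_rca_rv, y$lengths$l_rca_lv,
                            cutoff_diameter = y$lengths$cutoff_diameter_mm
                              %||% 1)
  branching <- branching_spec(y$branching$r_p,
                              unlist(y$branching$r_d) %||% numeric(),
                              k = y$branching$k %||% 2)
  hemo <- patient_hemo(y$hemo$sbp, y$hemo$dbp, y$hemo$hr,
                       y$hemo$stroke_volume, y$hemo$hct,
                       p_ra = y$hemo$p_ra %||% 5)
  g <- y$geometry
  geometry <- if (!is.null(g$contour_file)) {
    file.path(dirname(path), g$contour_file)
  } else {
    stenosis_spec(g$nominal_radius, g$length, g$pitch,
                  stenoses = g$stenoses,
                  ellipticity = g$ellipticity %||% 1,
                  noise_amplitude = g$noise_amplitude %||% 0.02,
                  n_points = g$n_points %||% 64,
                  seed = g$seed %||% 1)
  }
  case_config(lengths, branching, hemo, geometry,
              target = y$target %||% "lad",
              settings = y$settings %||% list(),
              case_id = y$case_id)
}

#' Paths of the shipped synthetic case battery
#'
#' Three synthetic cases (mild LAD, moderate LCX, severe RCA stenosis)
#' with reference-cohort hemodynamics, used throughout the tests and the
#' worked examples.
#'
#' @return Character vector of YAML paths.
#' @export
shipped_cases <- function() {
  dir <- system.file("extdata", "cases", package = "octffr")
  list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
}

#' Simulate fractional flow reserve for a case
#'
#' Full pipeline: territory flow split from vessel lengths, resting branch
#' resistances from the coronary-fraction rule, distal resistance of the
#' imaged segment via the amplification factor, network construction and
#' hyperemic scaling, lumen profile and loss coefficients from the
#' geometry, then coupled time-marching ([ffr_time_march()]) to the
#' periodic hyperemic FFR.
#'
#' @param case A [case_config()] (or a YAML path).
#' @return An object of class `octffr_ffr` with fields `ffr` (scalar
#'   distal FFR), `ffr_profile` (per-position cycle-mean pressure ratio),
#'   `traces` (final-cycle time series), `cycles_run`, `converged`,
#'   `interface_iterations`, `diagnostics` (cycle-mean flow, capacitor
#'   flux, charge imbalance) and `setup` (the calibrated components).
#' @examples
#' \donttest{
#' res <- simulate_ffr(shipped_cases()[1])
#' res$ffr
#' }
#' @export
simulate_ffr <- function(case) {
  if (is.character(case)) case <- read_case_yaml(case)
  stopifnot(inherits(case, "case_config"))
  st <- case$settings

  split <- flow_fractions(case$lengths, alpha = st$length_lpm$alpha,
                          variant = st$length_lpm$rca_length_variant)
  resist <- branch_resistances(split, case$hemo,
                               coronary_fraction =
                                 st$length_lpm$coronary_fraction)
  r_p <- resist[[paste0("r_", case$target)]]
  rroi <- roi_total_resistance(r_p, amp_factor(case$branching))
  net <- build_network(rroi, splits = st$lpm$splits,
                       caps = st$lpm$capacitances, gamma = st$lpm$gamma,
                       p_ra = case$hemo$p_ra,
                       r_coll_multiple = st$lpm$collateral$r_multiple,
                       p_coll_threshold = st$lpm$collateral$threshold_mmHg)
  net <- apply_hyperemia(net, st$lpm$hyperemia_factor)

  profile <- if (is.character(case$geometry))
    lumen_profile(read_contours(case$geometry))
  else lumen_profile(generate_pullback(case$geometry))
  blood <- blood_props(case$hemo$hct,
                       mu_plasma = st$blood$mu_plasma_mPas,
                       rho = st$blood$rho_kg_m3)
  loss <- loss_coefficients(profile, blood, k_t = st$roi_solver$k_t,
                            reference = st$roi_solver$reference)

  p_ao_wf <- aortic_waveform(case$hemo, st$lpm$systolic_fraction)
  p_lv_wf <- lv_waveform(case$hemo, st$lpm$systolic_fraction,
                         st$lpm$lv_diastolic_mmHg)
  res <- ffr_time_march(loss, net, p_ao_wf, p_lv_wf,
                        control = st$coupling)
  ## one laminar-range check at the cycle-peak flow
  q_peak <- max(abs(res$traces$q_in))
  if (q_peak > 0) {
    re <- blood$rho * (q_peak * 1e-6 / (min(profile$area) * 1e-6)) *
      2 * min(profile$r_eff) * 1e-3 / (blood$mu * 1e-3)
    if (re > 2000)
      warning(sprintf("peak throat Reynolds number %.0f exceeds 2000", re),
              call. = FALSE)
  }
  res$case_id <- case$case_id
  res$setup <- list(split = split, resistances = resist, r_roi = rroi,
                    network = net, loss = loss, settings = st,
                    target = case$target)
  res
}

#' Write an FFR result as JSON
#'
#' `{ffr, ffr_profile: [[s_mm, ffr], ...], cycles_run, converged,
#' settings_echo}`.
#'
#' @param result An [simulate_ffr()] result.
#' @param path Output path.
#' @export
write_ffr_json <- function(result, path) {
  stopifnot(inherits(result, "octffr_ffr"))
  jsonlite::write_json(
    list(case_id = result$case_id,
         ffr = result$ffr,
         ffr_profile = unname(as.matrix(result$ffr_profile)),
         cycles_run = result$cycles_run,
         converged = result$converged,
         settings_echo = result$setup$settings),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
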