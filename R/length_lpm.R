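#' Branch lengths of a coronary tree
#'
#' Container for the per-territory summed vessel lengths measured on
#' angiography above a diameter cutoff. The right coronary artery (RCA)
#' length is split into the part feeding the right ventricle and the part
#' feeding the left ventricle, because the thin right-ventricular wall
#' subtends far less muscle per unit vessel length.
#'
#' @param l_lad,l_lcx Summed vessel length (mm) of the left anterior
#'   descending and left circumflex territories.
#' @param l_rca_rv,l_rca_lv Summed RCA length (mm) feeding the right and
#'   left ventricle respectively.
#' @param cutoff_diameter Diameter (mm) below which sub-vessels were
#'   excluded from the sums; stored as provenance (default 1 mm).
#' @return An object of class `branch_lengths`.
#' @examples
#' branch_lengths(110, 100, 70, 100)
#' @export
branch_lengths <- function(l_lad, l_lcx, l_rca_rv, l_rca_lv,
                           cutoff_diameter = 1) {
  lens <- c(l_lad, l_lcx, l_rca_rv, l_rca_lv)
  if (any(!is.finite(lens)) || any(lens < 0))
    octffr_error("all branch lengths must be finite and >= 0", "invalid_input")
  if (all(lens == 0))
    octffr_error("at least one branch length must be > 0", "invalid_input")
  if (!is.finite(cutoff_diameter) || cutoff_diameter <= 0)
    octffr_error("cutoff_diameter must be > 0", "invalid_input")
  structure(list(l_lad = l_lad, l_lcx = l_lcx,
                 l_rca_rv = l_rca_rv, l_rca_lv = l_rca_lv,
                 cutoff_diameter = cutoff_diameter),
            class = "branch_lengths")
}

#' Read/write branch lengths as JSON
#'
#' Lengths are exchanged as a flat JSON object with explicit units:
#' `{"l_lad": .., "l_lcx": .., "l_rca_rv": .., "l_rca_lv": ..,
#' "cutoff_diameter_mm": .., "units": "mm"}`.
#'
#' @param path File path.
#' @param x A [branch_lengths()] object.
#' @return `read_branch_lengths` returns a `branch_lengths` object;
#'   `write_branch_lengths` returns `path` invisibly.
#' @export
read_branch_lengths <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  branch_lengths(j$l_lad, j$l_lcx, j$l_rca_rv, j$l_rca_lv,
                 cutoff_diameter = j$cutoff_diameter_mm %||% 1)
}

#' @rdname read_branch_lengths
#' @export
write_branch_lengths <- function(x, path) {
  stopifnot(inherits(x, "branch_lengths"))
  jsonlite::write_json(
    list(l_lad = x$l_lad, l_lcx = x$l_lcx,
         l_rca_rv = x$l_rca_rv, l_rca_lv = x$l_rca_lv,
         cutoff_diameter_mm = x$cutoff_diameter, units = "mm"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Patient hemodynamic scalars
#'
#' Brachial cuff pressures, heart rate, stroke volume, hematocrit and the
#' assumed right-atrial pressure. Defaults are the medians of the reference
#' cohort used throughout the package examples.
#'
#' @param sbp,dbp Systolic/diastolic brachial pressure, mmHg.
#' @param hr Heart rate, beats/min.
#' @param stroke_volume Stroke volume, mL.
#' @param hct Hematocrit as a fraction in (0, 1).
#' @param p_ra Right-atrial pressure, mmHg (default 5).
#' @return An object of class `patient_hemo`.
#' @export
patient_hemo <- function(sbp = 140, dbp = 81, hr = 67, stroke_volume = 65,
                         hct = 0.402, p_ra = 5) {
  ## equality allowed so the pulseless (constant-pressure) limit used by
  ## steady-state analyses is constructible
  if (!(is.finite(sbp) && is.finite(dbp) && sbp >= dbp && dbp > 0))
    octffr_error("need sbp >= dbp > 0", "invalid_input")
  if (!is.finite(hr) || hr <= 0)
    octffr_error("heart rate must be > 0", "invalid_input")
  if (!is.finite(stroke_volume) || stroke_volume <= 0)
    octffr_error("stroke volume must be > 0", "invalid_input")
  if (!is.finite(hct) || hct <= 0 || hct >= 1)
    octffr_error("hematocrit must be a fraction in (0, 1)", "invalid_input")
  structure(list(sbp = sbp, dbp = dbp, hr = hr,
                 stroke_volume = stroke_volume, hct = hct, p_ra = p_ra),
            class = "patient_hemo")
}

#' Mean aortic pressure estimated from cuff pressure
#'
#' Standard one-third pulse-pressure estimate, MAP = DBP + (SBP - DBP)/3.
#'
#' @param hemo A [patient_hemo()] object.
#' @return Mean arterial pressure, mmHg.
#' @export
map_pressure <- function(hemo) {
  stopifnot(inherits(hemo, "patient_hemo"))
  hemo$dbp + (hemo$sbp - hemo$dbp) / 3
}

#' Effective RCA length weighted by the LV/RV volume ratio
#'
#' The RCA feeds both ventricles, but right-ventricular wall is thin, so
#' RV-feeding length induces less flow per millimetre. The RV part is
#' down-weighted by `alpha`, the LV-to-RV muscle volume ratio.
#'
#' Two variants are available. `"additive"` (default) returns
#' `l_rv / alpha + l_lv`, which has the correct single-territory limits and
#' produces territory splits on the scale observed clinically.
#' `"as_printed"` returns the harmonic combination
#' `1 / (alpha / l_rv + 1 / l_lv)`; it is retained for fidelity with the
#' original formulation but degenerates when either length is zero.
#'
#' @param l_rv,l_lv RV-/LV-feeding RCA lengths, mm.
#' @param alpha LV-to-RV volume ratio (default 3.46, the composite-group
#'   clinical value; the observed range is roughly +/-30%).
#' @param variant `"additive"` or `"as_printed"`.
#' @return Effective length, mm.
#' @examples
#' rca_effective_length(70, 100)                       # 120.23
#' rca_effective_length(50, 60, variant = "as_printed") # 11.65
#' @export
rca_effective_length <- function(l_rv, l_lv, alpha = 3.46,
                                 variant = c("additive", "as_printed")) {
  variant <- match.arg(variant)
  if (!is.finite(alpha) || alpha <= 0)
    octffr_error("alpha must be > 0", "invalid_input")
  if (l_rv < 0 || l_lv < 0)
    octffr_error("lengths must be >= 0", "invalid_input")
  if (l_rv + l_lv <= 0)
    octffr_error("both RCA territory lengths are zero", "invalid_input")
  if (variant == "additive") return(l_rv / alpha + l_lv)
  if (l_rv == 0 || l_lv == 0)
    octffr_error(paste("the harmonic ('as_printed') form is degenerate when",
                       "one territory length is zero; use the 'additive'",
                       "variant"), "degenerate_formula")
  1 / (alpha / l_rv + 1 / l_lv)
}

#' Territory flow fractions from vessel lengths
#'
#' Resting flow divides among LAD, LCX and RCA in proportion to the vessel
#' length each territory subtends (longer vessel, more muscle fed, more
#' flow); the RCA term uses [rca_effective_length()].
#'
#' @param lengths A [branch_lengths()] object.
#' @inheritParams rca_effective_length
#' @return An object of class `flow_split` with fields `f_lad`, `f_lcx`,
#'   `f_rca` summing to 1, plus the `alpha` and `variant` used.
#' @examples
#' flow_fractions(branch_lengths(110, 100, 70, 100))
#' @export
flow_fractions <- function(lengths, alpha = 3.46,
                           variant = c("additive", "as_printed")) {
  stopifnot(inherits(lengths, "branch_lengths"))
  variant <- match.arg(variant)
  l_rca <- if (lengths$l_rca_rv + lengths$l_rca_lv > 0)
    rca_effective_length(lengths$l_rca_rv, lengths$l_rca_lv, alpha, variant)
  else 0
  l <- c(lad = lengths$l_lad, lcx = lengths$l_lcx, rca = l_rca)
  if (sum(l) <= 0)
    octffr_error("all effective lengths are zero", "invalid_input")
  f <- l / sum(l)
  structure(list(f_lad = unname(f["lad"]), f_lcx = unname(f["lcx"]),
                 f_rca = unname(f["rca"]), alpha = alpha, variant = variant),
            class = "flow_split")
}

#' Resting branch resistances from the coronary-fraction rule
#'
#' Total resting coronary flow is taken as a fraction of cardiac output
#' (default 4%), cardiac output as heart rate times stroke volume, and the
#' perfusion pressure as the estimated mean aortic pressure minus
#' right-atrial pressure. Each territory resistance is then
#' `delta_p / (fraction * q_cor)`.
#'
#' @param split A [flow_fractions()] result.
#' @param hemo A [patient_hemo()] object.
#' @param coronary_fraction Fraction of cardiac output perfusing the
#'   coronaries at rest, in (0, 0.2]; default 0.04.
#' @param map_estimate Mean aortic pressure, mmHg; defaults to
#'   [map_pressure()] of `hemo`.
#' @return An object of class `branch_resistances` with per-territory
#'   resistances (mmHg·s/mL), the `delta_p` used (mmHg) and the total
#'   resting coronary flow `q_cor` (mL/s).
#' @export
branch_resistances <- function(split, hemo, coronary_fraction = 0.04,
                               map_estimate = map_pressure(hemo)) {
  stopifnot(inherits(split, "flow_split"), inherits(hemo, "patient_hemo"))
  if (!is.finite(coronary_fraction) ||
      coronary_fraction <= 0 || coronary_fraction > 0.2)
    octffr_error("coronary_fraction must be in (0, 0.2]", "invalid_input")
  if (map_estimate <= hemo$p_ra)
    octffr_error("mean aortic pressure must exceed right-atrial pressure",
                 "invalid_input")
  co_mL_min <- hemo$hr * hemo$stroke_volume
  q_cor <- coronary_fraction * co_mL_min / 60   # mL/s
  delta_p <- map_estimate - hemo$p_ra
  f <- c(lad = split$f_lad, lcx = split$f_lcx, rca = split$f_rca)
  if (any(f == 0)) {
    zero <- names(f)[f == 0]
    octffr_error(paste0("branch(es) with zero flow fraction would have ",
                        "infinite resistance: ", paste(zero, collapse = ", ")),
                 "infinite_resistance")
  }
  r <- delta_p / (f * q_cor)
  structure(list(r_lad = unname(r["lad"]), r_lcx = unname(r["lcx"]),
                 r_rca = unname(r["rca"]), delta_p = delta_p, q_cor = q_cor),
            class = "branch_resistances")
}

#' Branching geometry upstream of the imaged segment
#'
#' Parent radius and the radii of the N side branches that leave between
#' the parent ostium and the imaged region of interest, with the exponent
#' `k` of the radius-flow scaling law `Q = m * r^k`.
#'
#' @param r_p Parent vessel radius, mm.
#' @param r_d Numeric vector of daughter (side-branch) radii, mm; may be
#'   empty.
#' @param k Scaling exponent, in \[2, 3\]; default 2 (flow proportional to
#'   cross-sectional area).
#' @return An object of class `branching_spec`.
#' @export
branching_spec <- function(r_p, r_d = numeric(), k = 2) {
  if (!is.finite(r_p) || r_p <= 0)
    octffr_error("parent radius must be > 0", "invalid_input")
  if (length(r_d) && (any(!is.finite(r_d)) || any(r_d <= 0)))
    octffr_error("daughter radii must all be > 0", "invalid_input")
  if (!is.finite(k) || k < 2 || k > 3)
    octffr_error("scaling exponent k must lie in [2, 3]", "invalid_input")
  structure(list(r_p = r_p, r_d = as.numeric(r_d), k = k),
            class = "branching_spec")
}

#' Resistance amplification factor
#'
#' Fraction of parent-branch flow that reaches the imaged segment after the
#' upstream side branches have taken their share under the `Q = m * r^k`
#' scaling law: `AMP_R = 1 - sum_i (r_di / r_p)^k`. The proportionality
#' constant `m` cancels. Dividing the parent resistance by `AMP_R` gives
#' the total distal resistance seen from the segment outlet, so more
#' branching upstream means a larger amplification of resistance.
#'
#' @param spec A [branching_spec()] object.
#' @return `AMP_R`, guaranteed in (0, 1] on success.
#' @examples
#' amp_factor(branching_spec(2, c(1)))      # 0.75
#' amp_factor(branching_spec(3, c(1, 2)))   # 4/9
#' @export
amp_factor <- function(spec) {
  stopifnot(inherits(spec, "branching_spec"))
  s <- if (length(spec$r_d)) sum((spec$r_d / spec$r_p)^spec$k) else 0
  if (s >= 1)
    octffr_error(paste0("summed daughter term (", format(s), ") >= 1: the ",
                        "side branches would consume all parent flow and ",
                        "AMP_R would be <= 0"), "non_physical_branching")
  1 - s
}

#' Total distal resistance of the imaged segment
#'
#' @param r_p_value Resistance of the parent territory (one of the
#'   [branch_resistances()] values), mmHg·s/mL.
#' @param amp_r Amplification factor from [amp_factor()], in (0, 1].
#' @return An object of class `roi_resistance` with fields `r_roi`
#'   (= `r_p_value / amp_r`), `amp_r` and `r_p_value`.
#' @export
roi_total_resistance <- function(r_p_value, amp_r) {
  if (!is.finite(r_p_value) || r_p_value <= 0)
    octffr_error("parent resistance must be > 0", "invalid_input")
  if (!is.finite(amp_r) || amp_r <= 0 || amp_r > 1)
    octffr_error("AMP_R must lie in (0, 1]", "non_physical_branching")
  structure(list(r_roi = r_p_value / amp_r, amp_r = amp_r,
                 r_p_value = r_p_value),
            class = "roi_resistance")
}

#' Reference-cohort territory flow splits
#'
#' Length-based flow-distribution estimates (percent of total coronary flow
#' to LAD, LCX and RCA) for the 13 patients of the reference cohort. The
#' printed column means are 33, 30 and 37 percent; note the 13 RCA values
#' themselves average 37.85, i.e. the printed RCA mean is not the column
#' mean.
#'
#' @return A data.frame with columns `case`, `q_lad_pct`, `q_lcx_pct`,
#'   `q_rca_pct`.
#' @export
reported_flow_splits <- function() {
  data.frame(
    case = 1:13,
    q_lad_pct = c(30, 35, 19, 34, 19, 35, 36, 25, 44, 40, 34, 34, 38),
    q_lcx_pct = c(30, 30, 26, 31, 36, 31, 31, 36, 25, 23, 33, 37, 26),
    q_rca_pct = c(41, 35, 55, 35, 46, 34, 33, 39, 31, 36, 33, 38, 36)
  )
}

#' @export
print.flow_split <- function(x, ...) {
  cat(sprintf("Territory flow split (alpha = %.3g, %s variant)\n",
              x$alpha, x$variant))
  cat(sprintf("  LAD %5.1f%%   LCX %5.1f%%   RCA %5.1f%%\n",
              100 * x$f_lad, 100 * x$f_lcx, 100 * x$f_rca))
  invisible(x)
}

#' @export
print.branch_resistances <- function(x, ...) {
  cat(sprintf(paste0("Resting branch resistances (mmHg·s/mL): ",
                     "LAD %.1f, LCX %.1f, RCA %.1f\n"),
              x$r_lad, x$r_lcx, x$r_rca))
  cat(sprintf("  delta_p = %.1f mmHg, q_cor = %.3f mL/s\n",
              x$delta_p, x$q_cor))
  invisible(x)
}
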