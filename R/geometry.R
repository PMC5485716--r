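#' Synthetic stenosis / pullback specification
#'
#' Parameters for a synthetic OCT-like pullback: a straight tube of
#' `nominal_radius` sampled at frame pitch `pitch`, with zero or more
#' localized area stenoses. Each stenosis is a Gaussian dip in lumen area
#' parameterized by its centre, full width at half maximum, and fractional
#' area reduction at the centre. Frames are slightly elliptic
#' (`ellipticity` = major/minor axis ratio) with seeded smooth radial
#' noise, emulating the look of segmented pullback contours.
#'
#' @param nominal_radius Reference lumen radius, mm.
#' @param length Pullback length, mm.
#' @param pitch Frame spacing, mm (sub-millimetre for OCT-like stacks).
#' @param stenoses Data.frame (or list of lists) with columns `center_s`
#'   (mm), `width` (FWHM, mm) and `area_reduction` (fraction in \[0, 1)).
#' @param ellipticity Major-to-minor axis ratio of each frame, >= 1.
#' @param noise_amplitude Maximum radial perturbation as a fraction of the
#'   local radius, in \[0, 0.02\]; 0 gives analytically exact frames.
#' @param n_points Contour vertices per frame.
#' @param seed Integer seed making every generated fixture reproducible.
#' @param direction Acquisition order of the frames; pullbacks are
#'   acquired `"distal_to_proximal"` in practice, but generated stacks
#'   default to `"proximal_to_distal"` (axial coordinate increasing).
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(nominal_radius, length, pitch,
                          stenoses = NULL, ellipticity = 1,
                          noise_amplitude = 0.02, n_points = 64, seed = 1,
                          direction = c("proximal_to_distal",
                                        "distal_to_proximal")) {
  direction <- match.arg(direction)
  if (!is.finite(nominal_radius) || nominal_radius <= 0)
    octffr_error("nominal_radius must be > 0", "invalid_input")
  if (!is.finite(length) || length <= 0)
    octffr_error("length must be > 0", "invalid_input")
  if (!is.finite(pitch) || pitch <= 0 || pitch >= length)
    octffr_error("pitch must be positive and smaller than length",
                 "invalid_input")
  if (is.null(stenoses)) {
    stenoses <- data.frame(center_s = numeric(), width = numeric(),
                           area_reduction = numeric())
  } else if (!is.data.frame(stenoses)) {
    stenoses <- do.call(rbind, lapply(stenoses, as.data.frame))
  }
  if (nrow(stenoses)) {
    if (any(stenoses$area_reduction < 0) || any(stenoses$area_reduction >= 1))
      octffr_error("area_reduction must lie in [0, 1)", "invalid_input")
    if (any(stenoses$center_s < 0) || any(stenoses$center_s > length))
      octffr_error("stenosis centres must lie within [0, length]",
                   "invalid_input")
    if (any(stenoses$width <= 0))
      octffr_error("stenosis width must be > 0", "invalid_input")
  }
  if (ellipticity < 1)
    octffr_error("ellipticity must be >= 1", "invalid_input")
  if (noise_amplitude < 0 || noise_amplitude > 0.02)
    octffr_error("noise_amplitude must lie in [0, 0.02]", "invalid_input")
  if (n_points < 16)
    octffr_error("need at least 16 contour points per frame", "invalid_input")
  structure(list(nominal_radius = nominal_radius, length = length,
                 pitch = pitch, stenoses = stenoses,
                 ellipticity = ellipticity,
                 noise_amplitude = noise_amplitude,
                 n_points = as.integer(n_points), seed = as.integer(seed),
                 direction = direction),
            class = "stenosis_spec")
}

## Target lumen area along the axis, before the 5% floor.
stenosis_area_profile <- function(spec, s) {
  a0 <- pi * spec$nominal_radius^2
  red <- rep(0, length(s))
  if (nrow(spec$stenoses)) {
    for (j in seq_len(nrow(spec$stenoses))) {
      sg <- spec$stenoses$width[j] / 2.355  # FWHM -> sigma
      red <- red + spec$stenoses$area_reduction[j] *
        exp(-(s - spec$stenoses$center_s[j])^2 / (2 * sg^2))
    }
  }
  a0 * (1 - red)
}

#' Generate a synthetic contour stack
#'
#' Builds an OCT-pullback-like stack of closed lumen contours from a
#' [stenosis_spec()]. The area at axial position `s` follows the Gaussian
#' stenosis profile and is clipped below at 5% of the nominal area (with a
#' warning) to keep downstream solvers well-posed. Each frame is an
#' ellipse of the target area, perturbed by seeded smooth (low-order
#' Fourier) radial noise.
#'
#' @param spec A [stenosis_spec()].
#' @return An object of class `contour_stack`: list of `frames`
#'   (each with axial position `s` and an `n x 2` matrix `points`),
#'   plus `pitch` and `direction`.
#' @export
generate_pullback <- function(spec) {
  stopifnot(inherits(spec, "stenosis_spec"))
  s <- seq(0, spec$length, by = spec$pitch)
  if (length(s) < 3)
    octffr_error("pitch too coarse: fewer than 3 frames", "invalid_input")
  area <- stenosis_area_profile(spec, s)
  a0 <- pi * spec$nominal_radius^2
  floor_a <- 0.05 * a0
  if (any(area < floor_a)) {
    warning("stenosis profile drives lumen area below 5% of nominal; ",
            "clipping at the floor", call. = FALSE)
    area <- pmax(area, floor_a)
  }
  theta <- seq(0, 2 * pi, length.out = spec$n_points + 1)[-(spec$n_points + 1)]
  frames <- with_local_seed(spec$seed, {
    lapply(seq_along(s), function(i) {
      r_f <- sqrt(area[i] / pi)
      a_ax <- r_f * sqrt(spec$ellipticity)
      b_ax <- r_f / sqrt(spec$ellipticity)
      delta <- 0
      if (spec$noise_amplitude > 0) {
        # zero-mean low-order Fourier perturbation, sup-norm <= amplitude
        m <- 2:4
        co <- stats::rnorm(3); si <- stats::rnorm(3)
        raw <- drop(cos(outer(theta, m)) %*% co + sin(outer(theta, m)) %*% si)
        delta <- spec$noise_amplitude * raw / max(abs(raw))
      }
      cbind(x = a_ax * cos(theta) * (1 + delta),
            y = b_ax * sin(theta) * (1 + delta))
    })
  })
  if (spec$direction == "distal_to_proximal") {
    frames <- rev(frames)
    s <- rev(s)
  }
  structure(list(frames = lapply(seq_along(s), function(i)
                   list(s = s[i], points = frames[[i]])),
                 pitch = spec$pitch, direction = spec$direction),
            class = "contour_stack")
}

#' Area of a closed planar contour
#'
#' Shoelace area of a simple closed polygon, independent of vertex
#' orientation. Self-intersecting contours (a segmentation failure mode)
#' are rejected.
#'
#' @param points `n x 2` numeric matrix of vertices (mm), first vertex not
#'   repeated.
#' @param check Verify the polygon is simple (O(n^2) segment test).
#' @return Area in mm^2.
#' @export
contour_area <- function(points, check = TRUE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3 || ncol(points) != 2 || any(!is.finite(points)))
    octffr_error("need a finite n x 2 matrix with >= 3 vertices",
                 "invalid_geometry")
  if (check && !is_simple_polygon(points))
    octffr_error("polygon is self-intersecting", "invalid_geometry")
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

## Vectorized all-pairs proper-intersection test between non-adjacent edges.
is_simple_polygon <- function(points) {
  n <- nrow(points)
  p1 <- points
  p2 <- points[c(2:n, 1), , drop = FALSE]
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adjacent <- (j - i == 1) | (i == 1 & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  d1 <- p2[i, ] - p1[i, ]
  d2 <- p2[j, ] - p1[j, ]
  w <- p1[j, ] - p1[i, ]
  den <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  t1 <- (w[, 1] * d2[, 2] - w[, 2] * d2[, 1]) / den
  t2 <- (w[, 1] * d1[, 2] - w[, 2] * d1[, 1]) / den
  hit <- abs(den) > 1e-14 & t1 > 1e-12 & t1 < 1 - 1e-12 &
    t2 > 1e-12 & t2 < 1 - 1e-12
  !any(hit, na.rm = TRUE)
}

#' Axial lumen profile of a contour stack
#'
#' Per-frame shoelace areas and effective radii `sqrt(area/pi)` on an
#' axial grid re-based to start at 0 and oriented proximal-to-distal
#' regardless of the acquisition direction.
#'
#' @param stack A [generate_pullback()] result (or one read back with
#'   [read_contours()]).
#' @return An object of class `lumen_profile` with fields `s`, `area`,
#'   `r_eff` (all vectors) and scalar `length`, in mm / mm^2.
#' @export
lumen_profile <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  s <- vapply(stack$frames, function(f) f$s, numeric(1))
  area <- vapply(seq_along(stack$frames), function(i) {
    tryCatch(contour_area(stack$frames[[i]]$points),
             octffr_error = function(e)
               octffr_error(sprintf("frame %d: %s", i, conditionMessage(e)),
                            "invalid_geometry"))
  }, numeric(1))
  if (is.unsorted(s)) {       # distal-to-proximal acquisition
    o <- order(s)
    s <- s[o]; area <- area[o]
  }
  s <- s - s[1]
  structure(list(s = s, area = area, r_eff = sqrt(area / pi),
                 length = s[length(s)]),
            class = "lumen_profile")
}

#' Read/write contour stacks as CSV
#'
#' One row per contour vertex, columns `frame_index, s_mm, point_index,
#' x_mm, y_mm`, header mandatory. Coordinates are written with 17
#' significant digits so a written stack reads back bit-for-bit.
#'
#' @param stack A `contour_stack`.
#' @param path File path.
#' @param direction Acquisition direction recorded for a stack read back
#'   from CSV (the file itself stores axial positions, not direction).
#' @return `read_contours` returns a `contour_stack`; `write_contours`
#'   returns `path` invisibly.
#' @export
write_contours <- function(stack, path) {
  stopifnot(inherits(stack, "contour_stack"))
  rows <- lapply(seq_along(stack$frames), function(i) {
    f <- stack$frames[[i]]
    data.frame(frame_index = i,
               s_mm = sprintf("%.17g", f$s),
               point_index = seq_len(nrow(f$points)),
               x_mm = sprintf("%.17g", f$points[, 1]),
               y_mm = sprintf("%.17g", f$points[, 2]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path, direction = "proximal_to_distal") {
  d <- utils::read.csv(path, colClasses = c(frame_index = "integer",
                                            s_mm = "numeric",
                                            point_index = "integer",
                                            x_mm = "numeric",
                                            y_mm = "numeric"))
  frames <- lapply(split(d, d$frame_index), function(f) {
    f <- f[order(f$point_index), ]
    list(s = f$s_mm[1], points = cbind(x = f$x_mm, y = f$y_mm))
  })
  frames <- frames[order(as.integer(names(frames)))]
  names(frames) <- NULL
  s <- vapply(frames, function(f) f$s, numeric(1))
  ds <- diff(s)
  if (length(ds) && max(abs(abs(ds) - abs(ds[1]))) > 1e-9)
    octffr_error("frames are not uniformly spaced", "invalid_input")
  structure(list(frames = frames, pitch = abs(ds[1]), direction = direction),
            class = "contour_stack")
}

#' @export
print.lumen_profile <- function(x, ...) {
  cat(sprintf(paste0("Lumen profile: %d frames over %.1f mm, area ",
                     "%.2f-%.2f mm^2 (min r_eff %.3f mm)\n"),
              length(x$s), x$length, min(x$area), max(x$area), min(x$r_eff)))
  invisible(x)
}
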