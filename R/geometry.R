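#' Four-antenna circular array
#'
#' Builds the antenna layout used for differential imaging: two antenna pairs
#' on a circle of radius `aperture_radius`, the antennas of a pair separated
#' by `pair_separation` degrees and corresponding antennas of the two pairs
#' by `pair_offset` degrees. The absolute `orientation` rotates the whole
#' array; relative angles are what the imaging operator depends on.
#'
#' Antenna angular positions are `orientation + c(0, pair_separation,
#' pair_offset, pair_offset + pair_separation)` for antennas 1--4, so with
#' the defaults antennas 1--3 and 2--4 are 90° apart and 1--2 and 3--4 are
#' 35° apart.
#'
#' The effective radiating point of each antenna can move inward with
#' frequency (the phase center of a horn is frequency dependent);
#' `phase_center_poly` gives the inward offset in mm as polynomial
#' coefficients in frequency (GHz), lowest order first, degree at most 5.
#' The default zero polynomial keeps the radiating points on the aperture
#' circle.
#'
#' @param aperture_radius Radius of the aperture circle, mm.
#' @param pair_separation Angular separation within a pair, degrees.
#' @param pair_offset Angular separation between corresponding antennas of
#'   the two pairs, degrees.
#' @param orientation Angular position of antenna 1, degrees
#'   (counter-clockwise from the +x axis).
#' @param phase_center_poly Numeric polynomial coefficients (mm vs GHz),
#'   lowest order first; length at most 6.
#' @param min_separation Smallest allowed angular separation between any two
#'   antennas, degrees.
#' @return An object of class `antenna_array`.
#' @examples
#' arr <- antenna_array()
#' antenna_positions(arr, 1e9)
#' @export
antenna_array <- function(aperture_radius = 100, pair_separation = 35,
                          pair_offset = 90, orientation = 107.5,
                          phase_center_poly = 0, min_separation = 5) {
  stopifnot(aperture_radius > 0, pair_separation > 0, pair_separation < 90)
  angles <- orientation +
    c(0, pair_separation, pair_offset, pair_offset + pair_separation)
  sep <- outer(angles, angles, function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  })
  if (any(sep[upper.tri(sep)] < min_separation)) {
    abort(sprintf(
      "antennas overlap: smallest angular separation %.1f deg is below %g deg",
      min(sep[upper.tri(sep)]), min_separation
    ))
  }
  if (length(phase_center_poly) > 6) {
    abort("phase_center_poly must have degree at most 5 (6 coefficients)")
  }
  structure(
    list(
      n_antennas = 4L,
      aperture_radius = aperture_radius,
      angular_positions = angles,
      phase_center_poly = phase_center_poly
    ),
    class = "antenna_array"
  )
}

#' @export
print.antenna_array <- function(x, ...) {
  cat("<antenna_array> 4 antennas, aperture radius ", x$aperture_radius,
      " mm\n  angular positions (deg): ",
      paste(round(x$angular_positions, 2), collapse = ", "), "\n", sep = "")
  cat("  phase-center polynomial: ",
      if (all(x$phase_center_poly == 0)) "zero (radiating at aperture)"
      else paste(signif(x$phase_center_poly, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Frequency-dependent phase-center offset
#'
#' Evaluates the inward offset (mm) of the effective radiating point from
#' the aperture as a polynomial in frequency (GHz). No extrapolation is
#' allowed outside the 0.5--3 GHz operating band.
#'
#' @param f Frequency in Hz, within 0.5--3 GHz.
#' @param poly Polynomial coefficients, lowest order first (length <= 6).
#' @return Offset in mm, vectorized over `f`.
#' @export
phase_center_offset <- function(f, poly) {
  if (length(poly) > 6) {
    abort("phase-center polynomial must have degree at most 5")
  }
  if (any(f < 0.5e9 - 1e-6 | f > 3e9 + 1e-6)) {
    abort("frequency outside the 0.5-3 GHz band: no extrapolation")
  }
  fg <- f / 1e9
  out <- numeric(length(fg))
  for (i in seq_along(poly)) out <- out + poly[i] * fg^(i - 1)
  out
}

#' Radiating positions of the array antennas at a frequency
#'
#' @param array An [antenna_array()].
#' @param f Frequency in Hz (scalar).
#' @return A tibble with columns `antenna`, `angle_deg`, `x`, `y` (mm); the
#'   radiating radius is the aperture radius minus the phase-center offset.
#' @export
antenna_positions <- function(array, f) {
  stopifnot(inherits(array, "antenna_array"), length(f) == 1)
  off <- if (all(array$phase_center_poly == 0)) 0 else
    phase_center_offset(f, array$phase_center_poly)
  r <- array$aperture_radius - off
  th <- array$angular_positions * pi / 180
  tibble::tibble(
    antenna = seq_len(array$n_antennas),
    angle_deg = array$angular_positions,
    x = r * cos(th),
    y = r * sin(th)
  )
}

#' Euclidean path length between two points
#'
#' @param a,b Numeric length-2 vectors `(x, y)` or n-by-2 matrices, mm.
#' @return Distance(s) in mm.
#' @examples
#' path_length(c(100, 0), c(0, 0))  # 100
#' @export
path_length <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  stopifnot(ncol(a) == 2, ncol(b) == 2, all(is.finite(a)), all(is.finite(b)))
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  unname(sqrt(rowSums((a - b)^2)))
}

#' Circular imaging grid
#'
#' Square lattice of focal points (pixel centers) clipped to a circular
#' region of interest centered on the array center. Pixel centers sit at
#' integer multiples of `pitch`, so the grid is symmetric under `x -> -x`
#' and `y -> -y`.
#'
#' @param roi_radius Radius of the region of interest, mm.
#' @param pitch Lattice spacing, mm (each pixel covers `pitch^2` mm²).
#' @return A tibble (class `imaging_grid`) with columns `pixel`, `x`, `y`
#'   (mm) and attributes `roi_radius` and `pitch`.
#' @examples
#' nrow(imaging_grid(100, 1))  # ~ pi * 100^2
#' @export
imaging_grid <- function(roi_radius = 100, pitch = 1) {
  stopifnot(roi_radius > 0)
  if (pitch <= 0) abort("pitch must be positive")
  if (pitch > roi_radius) abort("pitch larger than the ROI radius")
  m <- floor(roi_radius / pitch)
  ax <- seq(-m, m) * pitch
  g <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$x^2 + g$y^2 <= roi_radius^2, , drop = FALSE]
  g <- g[order(g$y, g$x), , drop = FALSE]
  out <- tibble::tibble(pixel = seq_len(nrow(g)), x = g$x, y = g$y)
  structure(out, roi_radius = roi_radius, pitch = pitch,
            class = c("imaging_grid", class(out)))
}
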