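#' Differential S-parameter set
#'
#' Entry-wise difference `background - target` of two acquisitions on the
#' same frequency grid. Static structure (antennas, phantom shell, baseline
#' coupling) is identical in both states and cancels exactly, leaving only
#' the change caused by the target.
#'
#' @param background,target `sparam_set` objects with identical frequency
#'   grids.
#' @param band Usable frequency band `c(low, high)` in Hz used to initialize
#'   the band mask (default 0.5--2 GHz).
#' @param channels Tibble of `(tx, rx)` transmission channels used for
#'   imaging; defaults to the six unordered off-diagonal pairs.
#' @return An object of class `differential_set`: `frequencies`, `delta`
#'   (4 x 4 x n complex), `band_mask`, `channels`.
#' @export
differential <- function(background, target, band = c(0.5e9, 2e9),
                         channels = default_channels()) {
  stopifnot(inherits(background, "sparam_set"), inherits(target, "sparam_set"))
  fb <- background$frequencies; ft <- target$frequencies
  if (length(fb) != length(ft) || max(abs(fb - ft)) > 1e-3) {
    abort("background and target frequency grids differ")
  }
  if (any(channels$tx == channels$rx)) {
    abort("imaging channels must be off-diagonal (tx != rx)")
  }
  structure(
    list(frequencies = fb,
         delta = background$s - target$s,
         band_mask = fb >= band[1] & fb <= band[2],
         channels = channels,
         delta_temperature =
           target$metadata$temperature - background$metadata$temperature),
    class = "differential_set"
  )
}

#' Restrict a differential set to a frequency band
#'
#' @param dset A [differential()] set.
#' @param f_low,f_high Band limits in Hz (`f_low < f_high`).
#' @return The differential set with its band mask restricted; the number of
#'   retained points is available as `sum(dset$band_mask)`.
#' @export
select_band <- function(dset, f_low, f_high) {
  stopifnot(inherits(dset, "differential_set"))
  if (f_low >= f_high) abort("inverted band limits: f_low must be < f_high")
  mask <- dset$frequencies >= f_low & dset$frequencies <= f_high
  if (!any(mask)) abort("empty band selection")
  dset$band_mask <- mask
  dset
}

#' @export
print.differential_set <- function(x, ...) {
  cat("<differential_set> ", length(x$frequencies), " points, ",
      sum(x$band_mask), " in band; ", nrow(x$channels),
      " channels\n", sep = "")
  invisible(x)
}

#' Wavenumber in a lossless dielectric
#'
#' \eqn{k(f) = 2\pi f \sqrt{\varepsilon_r} / c}, using the real relative
#' permittivity of the background medium.
#'
#' @param f Frequency in Hz.
#' @param eps_r Real relative permittivity (> 0).
#' @return Wavenumber in rad/m.
#' @export
wavenumber <- function(f, eps_r) {
  if (any(eps_r <= 0)) abort("eps_r must be positive")
  2 * pi * f * sqrt(eps_r) / .c0
}

#' Background-medium permittivity function for focusing
#'
#' Convenience constructor for the `medium` argument of [mfbf_image()]: the
#' real relative permittivity of water at the background temperature, as a
#' function of frequency.
#'
#' @param params A [debye_water()] parameterization.
#' @param temperature Background temperature, °C.
#' @return A function `f -> eps_r` (real).
#' @export
background_medium <- function(params = debye_water(), temperature = 25) {
  force(params); force(temperature)
  function(f) Re(debye_permittivity(f, temperature, params))
}

as_medium_fn <- function(medium) {
  if (is.function(medium)) return(medium)
  if (inherits(medium, "phantom_scene")) {
    return(background_medium(medium$params, medium$background_temperature))
  }
  abort("medium must be a function f -> eps_r or a phantom_scene")
}

# focusing phase factors for the four antennas at one frequency:
# npix x 4 matrix of exp(sign * i k rho), distances in meters
focus_factors <- function(grid, pos, k, sign) {
  e <- matrix(0i, nrow(grid), 4)
  for (a in 1:4) {
    rho <- 1e-3 * sqrt((pos[a, 1] - grid$x)^2 + (pos[a, 2] - grid$y)^2)
    e[, a] <- exp(sign * 1i * k * rho)
  }
  e
}

#' Multi-frequency bi-focusing (MFBF) image
#'
#' For each focal point (pixel) of the grid, coherently sums the
#' differential transmission data over the masked frequencies and the listed
#' channels:
#' \deqn{I(x, y) = \sum_f \sum_{T_i} \sum_{R_j}
#'   \frac{\Delta S_{T_i R_j}(f)}{k^2}\,
#'   e^{jk\rho_{R_j}}\, e^{jk\rho_{T_i}},}
#' with the wavenumber of the background medium and Euclidean distances from
#' the focal point to the (frequency-dependent) antenna radiating points.
#' The transmit and receive phase factors compensate the propagation delays
#' of the forward problem, so the sum peaks where the scatterer sits.
#'
#' @param dset A [differential()] set (non-empty band mask and channels).
#' @param array An [antenna_array()].
#' @param grid An [imaging_grid()].
#' @param medium Background medium: a function `f -> eps_r` (see
#'   [background_medium()]) or a [phantom_scene()].
#' @param conjugate Logical; use `exp(-jk rho)` focusing exponentials
#'   instead of the `exp(+jk rho)` convention (both are supported; the
#'   default is the matched-filter back-propagation reading).
#' @param normalize Logical; if `TRUE` the `magnitude` column is divided by
#'   its maximum (the raw maximum is kept in the `normalization` attribute).
#' @return An `image_map`: a tibble with columns `pixel`, `x`, `y`,
#'   `intensity` (complex) and `magnitude`, plus attributes `roi_radius`,
#'   `pitch` and `normalization`.
#' @export
mfbf_image <- function(dset, array, grid, medium, conjugate = FALSE,
                       normalize = FALSE) {
  stopifnot(inherits(dset, "differential_set"),
            inherits(grid, "imaging_grid"))
  if (!any(dset$band_mask)) abort("empty band mask: nothing to image")
  if (nrow(dset$channels) == 0) abort("empty channel list: nothing to image")
  eps_fn <- as_medium_fn(medium)
  sgn <- if (conjugate) -1 else 1
  freqs <- dset$frequencies[dset$band_mask]
  fidx <- which(dset$band_mask)
  ch <- dset$channels
  intensity <- complex(nrow(grid))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    k <- wavenumber(f, eps_fn(f))
    pos <- as.matrix(antenna_positions(array, f)[, c("x", "y")])
    e <- focus_factors(grid, pos, k, sgn)
    for (j in seq_len(nrow(ch))) {
      ds <- dset$delta[ch$tx[j], ch$rx[j], fidx[i]]
      if (ds != 0) intensity <- intensity + (ds / k^2) * e[, ch$tx[j]] * e[, ch$rx[j]]
    }
  }
  new_image_map(grid, intensity, normalize)
}

new_image_map <- function(grid, intensity, normalize = FALSE) {
  mag <- Mod(intensity)
  norm <- max(mag)
  out <- tibble::tibble(pixel = grid$pixel, x = grid$x, y = grid$y,
                        intensity = intensity,
                        magnitude = if (normalize && norm > 0) mag / norm
                                    else mag)
  structure(out,
            roi_radius = attr(grid, "roi_radius"),
            pitch = attr(grid, "pitch"),
            normalization = norm,
            class = c("image_map", class(out)))
}

#' Peak of a reconstructed image
#'
#' Location and value of the maximum display intensity; ties are broken by
#' the lowest pixel index.
#'
#' @param image An `image_map`.
#' @return A one-row tibble with `pixel`, `x`, `y`, `magnitude`.
#' @export
image_peak <- function(image) {
  if (all(image$magnitude == 0)) {
    abort("all-zero image: the peak is undefined")
  }
  i <- which.max(image$magnitude)  # first (lowest pixel index) on ties
  image[i, c("pixel", "x", "y", "magnitude")]
}

#' Reconstruct every step of a cooling series
#'
#' Takes the first (hottest) acquisition as the fixed background and images
#' each later acquisition against it over the selected band. The focusing
#' operator is built once and reused across the whole series.
#'
#' @param series A [cooling_series()].
#' @param array An [antenna_array()].
#' @param grid An [imaging_grid()].
#' @param medium Background medium (function or [phantom_scene()]); defaults
#'   to the series' own scene.
#' @param band Imaging band `c(low, high)`, Hz.
#' @param conjugate Focusing phase convention, as in [mfbf_image()].
#' @param keep_images Logical; retain the per-step `image_map`s (memory
#'   permitting) or only the peak summary.
#' @return An object of class `mfbf_series`: `peaks` (tibble with `delta_t`,
#'   `temperature`, `peak_x`, `peak_y`, `peak_magnitude`) and `images` (list
#'   of `image_map` or `NULL`).
#' @export
reconstruct_series <- function(series, array, grid, medium = NULL,
                               band = c(0.5e9, 2e9), conjugate = FALSE,
                               keep_images = FALSE) {
  stopifnot(inherits(series, "cooling_series"))
  if (is.null(medium)) {
    if (is.null(series$scene)) {
      abort("series carries no scene; supply `medium` explicitly")
    }
    medium <- series$scene
  }
  eps_fn <- as_medium_fn(medium)
  sgn <- if (conjugate) -1 else 1
  bg <- series$s_sets[[1]]
  n <- length(series$s_sets)
  freqs <- bg$frequencies
  mask <- freqs >= band[1] & freqs <= band[2]
  if (!any(mask)) abort("empty band selection")
  fsel <- which(mask)
  ch <- default_channels()
  # data matrix: (n_f_in_band * n_channels) x (n - 1) differential entries
  dmat <- matrix(0i, length(fsel) * nrow(ch), n - 1)
  for (s in 2:n) {
    d <- bg$s - series$s_sets[[s]]$s
    dmat[, s - 1] <- as.vector(vapply(seq_len(nrow(ch)), function(j) {
      d[ch$tx[j], ch$rx[j], fsel]
    }, complex(length(fsel))))
  }
  # focusing operator, built frequency by frequency: npix x (n_f * n_ch)
  op <- matrix(0i, nrow(grid), length(fsel) * nrow(ch))
  for (i in seq_along(fsel)) {
    f <- freqs[fsel[i]]
    k <- wavenumber(f, eps_fn(f))
    pos <- as.matrix(antenna_positions(array, f)[, c("x", "y")])
    e <- focus_factors(grid, pos, k, sgn)
    for (j in seq_len(nrow(ch))) {
      op[, (j - 1) * length(fsel) + i] <-
        (e[, ch$tx[j]] * e[, ch$rx[j]]) / k^2
    }
  }
  intensity <- op %*% dmat                 # npix x (n - 1)
  temps <- series$temperatures
  images <- if (keep_images) vector("list", n - 1) else NULL
  peaks <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    im <- new_image_map(grid, intensity[, s])
    if (keep_images) images[[s]] <- im
    pk <- image_peak(im)
    peaks[[s]] <- tibble::tibble(
      delta_t = round(temps[1] - temps[s + 1], 6),
      temperature = temps[s + 1],
      peak_x = pk$x, peak_y = pk$y, peak_magnitude = pk$magnitude
    )
  }
  structure(list(peaks = dplyr::bind_rows(peaks), images = images,
                 band = band, n_band = length(fsel)),
            class = "mfbf_series")
}

#' @export
print.mfbf_series <- function(x, ...) {
  cat("<mfbf_series> ", nrow(x$peaks), " differential images, ",
      x$n_band, " frequency points in band\n", sep = "")
  print(x$peaks, n = 5)
  invisible(x)
}

#' Plot a reconstructed image map
#'
#' @param object An `image_map`.
#' @param normalize Scale magnitudes to a 0--1 range for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.image_map <- function(object, normalize = TRUE, ...) {
  mag <- if (normalize && max(object$magnitude) > 0) {
    object$magnitude / max(object$magnitude)
  } else object$magnitude
  df <- data.frame(x = object$x, y = object$y, magnitude = mag)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|I|") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
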