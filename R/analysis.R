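#' Localization error of a reconstructed image
#'
#' Euclidean distance (mm) between the image's intensity maximum and the
#' true target center. Invariant under any global positive rescaling of the
#' image.
#'
#' @param image An `image_map`.
#' @param true_center `(x, y)` of the true target, mm.
#' @return Distance in mm.
#' @export
localization_error <- function(image, true_center) {
  pk <- image_peak(image)
  path_length(c(pk$x, pk$y), true_center)
}

#' Regression of reconstructed peak magnitude on temperature difference
#'
#' Ordinary least-squares line of peak |I| versus the temperature contrast,
#' quantifying how linearly the imaging response scales with the underlying
#' dielectric change.
#'
#' @param delta_t Temperature differences, °C (at least 3).
#' @param peak_magnitude Peak display intensities (un-normalized, so the
#'   trend across images is meaningful).
#' @return An object of class `peak_fit` wrapping the `lm` fit, with
#'   [tidy()], [glance()] and [autoplot()] methods; `$r_squared` holds the
#'   coefficient of determination.
#' @export
peak_vs_deltaT <- function(delta_t, peak_magnitude) {
  stopifnot(length(delta_t) == length(peak_magnitude))
  if (length(delta_t) < 3) abort("at least 3 points are required")
  r2 <- linearity_r2(delta_t, peak_magnitude)
  df <- data.frame(delta_t = delta_t, peak_magnitude = peak_magnitude)
  fit <- lm(peak_magnitude ~ delta_t, data = df)
  structure(
    list(fit = fit, data = tibble::as_tibble(df),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2),
    class = "peak_fit"
  )
}

#' @export
print.peak_fit <- function(x, ...) {
  cat("<peak_fit> peak |I| ~ delta_T over ", nrow(x$data), " points\n",
      "  slope ", signif(x$slope, 4), ", intercept ",
      signif(x$intercept, 4), ", R^2 = ", signif(x$r_squared, 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.peak_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "delta_t"),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.peak_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, nobs = nrow(x$data))
}

#' @export
autoplot.peak_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$delta_t,
                               y = .data$peak_magnitude)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", color = "red") +
    ggplot2::labs(x = expression(Delta * T ~ "(°C)"),
                  y = "peak |I| (a.u.)")
}

#' Detection threshold of a cooling series
#'
#' The smallest temperature difference from which the reconstructed maximum
#' stays within `tolerance` of the true target for every larger contrast.
#' This turns the visual judgement "a distinct peak emerges at the target"
#' into a reproducible, monotone criterion.
#'
#' @param delta_t Temperature differences, °C (any order; sorted
#'   internally).
#' @param localization_error Matching localization errors, mm.
#' @param tolerance Acceptance radius, mm. Default 9 mm: the 4-mm inclusion
#'   radius plus a 5-mm margin.
#' @return The threshold ΔT in °C, with attribute `detected`; `NA` (with
#'   `detected = FALSE`) if no contrast in the series localizes reliably.
#' @export
detection_threshold <- function(delta_t, localization_error, tolerance = 9) {
  stopifnot(length(delta_t) == length(localization_error))
  o <- order(delta_t)
  dt <- delta_t[o]; err <- localization_error[o]
  ok <- rev(cumprod(rev(err <= tolerance)) == 1)
  if (!any(ok)) {
    return(structure(NA_real_, detected = FALSE))
  }
  structure(dt[which(ok)[1]], detected = TRUE)
}

#' Dielectric contrast equivalent to a temperature difference
#'
#' Converts a detected temperature threshold into the corresponding relative
#' variations of permittivity and conductivity, by scaling the per-0.1 °C
#' sensitivities averaged over the imaging band.
#'
#' @param delta_t Temperature difference, °C (a multiple of 0.1).
#' @param table A [sensitivity_table()].
#' @param band Frequency band over which sensitivities are averaged, Hz.
#' @return A one-row tibble with `delta_t`, `eps_percent`, `sigma_percent`.
#' @examples
#' threshold_to_contrast(0.4, sensitivity_table())
#' @export
threshold_to_contrast <- function(delta_t, table = sensitivity_table(),
                                  band = c(0.5e9, 2e9)) {
  stopifnot(length(delta_t) == 1, delta_t >= 0)
  if (abs(delta_t / 0.1 - round(delta_t / 0.1)) > 1e-6) {
    abort("delta_t must be a multiple of the 0.1 degC protocol step")
  }
  rows <- table$frequency >= band[1] & table$frequency <= band[2]
  if (!any(rows)) abort("no sensitivity-table rows in the requested band")
  steps <- round(delta_t / 0.1)
  tibble::tibble(
    delta_t = delta_t,
    eps_percent = steps * mean(table$eta_eps[rows]),
    sigma_percent = steps * mean(table$eta_sigma[rows])
  )
}

#' Full detection report for a reconstructed cooling series
#'
#' Combines per-step localization errors and peak magnitudes with the
#' peak-versus-contrast regression, the detection threshold, and its
#' equivalent dielectric contrast.
#'
#' @param peaks Peak summary tibble from [reconstruct_series()] (columns
#'   `delta_t`, `peak_x`, `peak_y`, `peak_magnitude`).
#' @param true_center `(x, y)` of the true target, mm.
#' @param tolerance Localization tolerance for detection, mm.
#' @param sensitivity A [sensitivity_table()] used for the contrast
#'   conversion, or `NULL` to skip it.
#' @param band Band for the sensitivity averaging, Hz.
#' @return An object of class `detection_report` with elements `data`
#'   (per-step tibble), `fit` (a `peak_fit`), `threshold_delta_t` and
#'   `contrast`; has [tidy()], [glance()] and [autoplot()] methods.
#' @export
detection_report <- function(peaks, true_center = c(-25, 10), tolerance = 9,
                             sensitivity = NULL, band = c(0.5e9, 2e9)) {
  stopifnot(all(c("delta_t", "peak_x", "peak_y", "peak_magnitude") %in%
                  names(peaks)))
  if (nrow(peaks) == 0) abort("empty peak series")
  err <- path_length(cbind(peaks$peak_x, peaks$peak_y),
                     matrix(true_center, 1))
  data <- tibble::tibble(
    delta_t = peaks$delta_t,
    peak_magnitude = peaks$peak_magnitude,
    localization_error = err
  )
  fit <- peak_vs_deltaT(data$delta_t, data$peak_magnitude)
  thr <- detection_threshold(data$delta_t, data$localization_error,
                             tolerance)
  contrast <- if (!is.null(sensitivity) && isTRUE(attr(thr, "detected"))) {
    threshold_to_contrast(as.numeric(thr), sensitivity, band)
  } else NULL
  structure(
    list(data = data, fit = fit, threshold_delta_t = thr,
         tolerance = tolerance, contrast = contrast),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report> ", nrow(x$data), " contrasts\n", sep = "")
  det <- isTRUE(attr(x$threshold_delta_t, "detected"))
  cat("  threshold: ",
      if (det) paste0(as.numeric(x$threshold_delta_t), " degC ",
                      "(localization tolerance ", x$tolerance, " mm)")
      else "undetected", "\n", sep = "")
  cat("  peak-vs-contrast R^2 = ", signif(x$fit$r_squared, 4), "\n", sep = "")
  if (!is.null(x$contrast)) {
    cat("  equivalent contrast: ", signif(x$contrast$eps_percent, 2),
        "% in eps_r, ", signif(x$contrast$sigma_percent, 2),
        "% in sigma\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.detection_report <- function(x, ...) x$data

#' @export
glance.detection_report <- function(x, ...) {
  tibble::tibble(
    threshold_delta_t = as.numeric(x$threshold_delta_t),
    detected = isTRUE(attr(x$threshold_delta_t, "detected")),
    r.squared = x$fit$r_squared,
    slope = x$fit$slope,
    eps_percent = if (is.null(x$contrast)) NA_real_ else
      x$contrast$eps_percent,
    sigma_percent = if (is.null(x$contrast)) NA_real_ else
      x$contrast$sigma_percent,
    nobs = nrow(x$data)
  )
}

#' @export
autoplot.detection_report <- function(object, ...) {
  autoplot(object$fit, ...)
}

#' Export a detection report as delimited text
#'
#' @param report A [detection_report()].
#' @param path Output path (per-step table); a companion
#'   `<path>.summary.tsv` holds the scalar summary.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(report, path) {
  write.table(report$data, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(glance(report), paste0(path, ".summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Thermal budget of the cooling experiment
#'
#' Heat-capacity bookkeeping showing that the cooling target cannot warm the
#' phantom appreciably on the experiment's timescale: thermal capacities
#' `C = m c_p` of phantom and target, heat released by the target cooling
#' over `delta_t_target`, the conservative bulk temperature rise if all of
#' it went into the phantom water, and the convective cooling time constant
#' \eqn{\tau = \rho c_p V / (h A)} of the phantom for a range of air-water
#' convective coefficients (`A` is the full cylinder surface,
#' \eqn{2\pi r H + 2\pi r^2}).
#'
#' @param phantom_volume Phantom water volume, m³ (default: a 105-mm radius,
#'   100-mm high cylinder).
#' @param target_volume Target water volume, m³ (default: a 5-mm radius,
#'   100-mm long cylinder, i.e. the tube's outer radius, giving the nominal
#'   ~7.8 g water mass).
#' @param delta_t_target Target cooling span, °C.
#' @param h Air-water convective coefficients, W/(m²·K).
#' @param phantom_radius,phantom_height Phantom cylinder dimensions, m (for
#'   the surface area).
#' @param cp Specific heat of water, J/(kg·°C).
#' @param density Water density, kg/m³.
#' @return An object of class `thermal_budget` (a list) with masses (kg),
#'   capacities (J/°C), `released_heat` (J), `bulk_rise` (°C) and a tibble
#'   `tau` of time constants (s and h) per `h` value.
#' @examples
#' thermal_budget()
#' @export
thermal_budget <- function(phantom_volume = pi * 0.105^2 * 0.1,
                           target_volume = pi * 0.005^2 * 0.1,
                           delta_t_target = 4.5,
                           h = c(5, 10),
                           phantom_radius = 0.105, phantom_height = 0.1,
                           cp = 4186, density = 1000) {
  if (any(c(phantom_volume, target_volume, delta_t_target, h,
            phantom_radius, phantom_height, cp, density) <= 0)) {
    abort("all thermal-budget inputs must be positive")
  }
  m_phantom <- density * phantom_volume
  m_target <- density * target_volume
  c_phantom <- m_phantom * cp
  c_target <- m_target * cp
  q <- c_target * delta_t_target
  rise <- q / c_phantom
  area <- 2 * pi * phantom_radius * phantom_height +
    2 * pi * phantom_radius^2
  tau_s <- density * cp * phantom_volume / (h * area)
  structure(
    list(phantom_mass = m_phantom, target_mass = m_target,
         phantom_capacity = c_phantom, target_capacity = c_target,
         released_heat = q, bulk_rise = rise,
         surface_area = area,
         tau = tibble::tibble(h = h, tau_s = tau_s, tau_h = tau_s / 3600)),
    class = "thermal_budget"
  )
}

#' @export
print.thermal_budget <- function(x, ...) {
  cat("<thermal_budget>\n")
  cat("  phantom: ", signif(x$phantom_mass, 3), " kg, C = ",
      signif(x$phantom_capacity, 3), " J/degC\n", sep = "")
  cat("  target:  ", signif(x$target_mass, 3), " kg, C = ",
      signif(x$target_capacity, 3), " J/degC\n", sep = "")
  cat("  released heat ", signif(x$released_heat, 3), " J -> bulk rise ",
      signif(x$bulk_rise, 2), " degC\n", sep = "")
  for (i in seq_len(nrow(x$tau))) {
    cat("  h = ", x$tau$h[i], " W/m2K: tau = ",
        signif(x$tau$tau_h[i], 3), " h\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.thermal_budget <- function(x, ...) {
  tibble::tibble(
    phantom_capacity = x$phantom_capacity,
    target_capacity = x$target_capacity,
    released_heat = x$released_heat,
    bulk_rise = x$bulk_rise,
    tau_h_min = min(x$tau$tau_h),
    tau_h_max = max(x$tau$tau_h)
  )
}
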