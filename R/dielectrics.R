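#' Single-Debye parameterizations of pure water
#'
#' Returns a parameterization of the temperature dependence of the three
#' Debye parameters of pure (deionized) water: the static permittivity
#' \eqn{\varepsilon_s(T)}, the infinite-frequency permittivity
#' \eqn{\varepsilon_\infty(T)} and the relaxation time \eqn{\tau(T)}.
#'
#' Two published coefficient sets are provided:
#' \describe{
#'   \item{`"stogryn1971"`}{(default) the classic fit used throughout the
#'     microwave remote-sensing literature: \eqn{\varepsilon_s} from the
#'     Malmberg--Maryott cubic, a cubic fit for \eqn{2\pi\tau}, and
#'     \eqn{\varepsilon_\infty = 4.9}.}
#'   \item{`"kaatze1989"`}{a log-linear \eqn{\varepsilon_s}, an Arrhenius-type
#'     \eqn{\tau} with a quadratic correction, and a linear
#'     \eqn{\varepsilon_\infty(T)}.}
#' }
#' Both are valid well beyond the 25--50 °C span used here.
#'
#' @param source Character; which published coefficient set to use.
#' @return An object of class `debye_parameterization`: a list with function
#'   fields `static_permittivity`, `inf_permittivity` (dimensionless) and
#'   `relaxation_time` (seconds), each a function of temperature in °C, plus
#'   `valid_temperature_range` (°C) and a `label`.
#' @examples
#' w <- debye_water()
#' w$static_permittivity(25)   # ~78.4
#' @export
debye_water <- function(source = c("stogryn1971", "kaatze1989")) {
  source <- match.arg(source)
  p <- switch(source,
    stogryn1971 = list(
      static_permittivity = function(t) {
        87.740 - 0.40008 * t + 9.398e-4 * t^2 + 1.410e-6 * t^3
      },
      inf_permittivity = function(t) rep_len(4.9, length(t)),
      relaxation_time = function(t) {
        (1.1109e-10 - 3.824e-12 * t + 6.938e-14 * t^2 - 5.096e-16 * t^3) /
          (2 * pi)
      },
      valid_temperature_range = c(0, 60),
      label = "stogryn1971"
    ),
    kaatze1989 = list(
      static_permittivity = function(t) 10^(1.94404 - 1.991e-3 * t),
      inf_permittivity = function(t) 5.77 - 0.0274 * t,
      relaxation_time = function(t) {
        3.745e-15 * (1 + 7e-5 * (t - 27.5)^2) * exp(2.2957e3 / (t + 273.15))
      },
      valid_temperature_range = c(0, 60),
      label = "kaatze1989"
    )
  )
  structure(p, class = "debye_parameterization")
}

#' @export
print.debye_parameterization <- function(x, ...) {
  cat("<debye_parameterization> ", x$label, "\n", sep = "")
  cat("  valid temperature range: ",
      paste(x$valid_temperature_range, collapse = " to "), " degC\n", sep = "")
  cat("  at 25 degC: eps_s = ", signif(x$static_permittivity(25), 5),
      ", eps_inf = ", signif(x$inf_permittivity(25), 4),
      ", tau = ", signif(x$relaxation_time(25) * 1e12, 4), " ps\n", sep = "")
  invisible(x)
}

check_temperature_range <- function(temperature, params) {
  rng <- params$valid_temperature_range
  if (any(temperature < rng[1] | temperature > rng[2])) {
    abort(sprintf(
      "temperature outside the validity range [%g, %g] degC of '%s'",
      rng[1], rng[2], params$label
    ))
  }
  invisible(TRUE)
}

#' Complex permittivity of water from the Debye relaxation model
#'
#' Evaluates the single-pole Debye model
#' \deqn{\varepsilon(f, T) = \varepsilon_\infty(T) +
#'   \frac{\varepsilon_s(T) - \varepsilon_\infty(T)}{1 + j 2\pi f \tau(T)},}
#' which yields \eqn{\varepsilon = \varepsilon' - j\varepsilon''} with
#' \eqn{\varepsilon'' \ge 0} (time convention \eqn{e^{+j\omega t}}).
#'
#' @param f Frequency in Hz (vector, recycled against `temperature`).
#' @param temperature Temperature in °C.
#' @param params A [debye_water()] parameterization.
#' @return Complex permittivity (dimensionless), vectorized.
#' @examples
#' debye_permittivity(1e9, 25)            # ~ 78 - 4i
#' Re(debye_permittivity(0, 25))          # static limit, eps_s(25)
#' @export
debye_permittivity <- function(f, temperature, params = debye_water()) {
  stopifnot(is.numeric(f), all(f >= 0))
  check_temperature_range(temperature, params)
  es <- params$static_permittivity(temperature)
  ei <- params$inf_permittivity(temperature)
  tau <- params$relaxation_time(temperature)
  ei + (es - ei) / (1 + 1i * 2 * pi * f * tau)
}

#' Effective conductivity from the dielectric loss factor
#'
#' Converts the (non-negative) imaginary part of the complex permittivity,
#' \eqn{\varepsilon''}, into an effective conductivity
#' \eqn{\sigma = 2\pi f \varepsilon_0 \varepsilon''} in S/m. No static ionic
#' term is included (deionized water: \eqn{\sigma \to 0} as \eqn{f \to 0}).
#'
#' @param f Frequency in Hz.
#' @param eps_imag Loss factor \eqn{\varepsilon''} (positive by the
#'   \eqn{\varepsilon' - j\varepsilon''} sign convention).
#' @return Conductivity in S/m.
#' @export
conductivity_from_permittivity <- function(f, eps_imag) {
  stopifnot(is.numeric(f), all(f >= 0))
  out <- 2 * pi * f * .eps0 * eps_imag
  if (any(out < 0)) {
    abort(paste(
      "negative conductivity: 'eps_imag' must be the positive loss factor",
      "(use -Im(eps) under the eps' - j*eps'' convention)"
    ))
  }
  out
}

#' Tabulate dielectric properties of water
#'
#' Evaluates the Debye model on a frequency/temperature grid and returns a
#' tidy table of the real permittivity and effective conductivity.
#'
#' @inheritParams debye_permittivity
#' @return A tibble with columns `frequency` (Hz), `temperature` (°C),
#'   `permittivity` (complex), `relative_permittivity` and
#'   `conductivity` (S/m); one row per frequency/temperature combination.
#' @examples
#' dielectric_sample(c(0.5e9, 1e9), temperature = c(25, 36))
#' @export
dielectric_sample <- function(f, temperature, params = debye_water()) {
  grid <- expand.grid(frequency = f, temperature = temperature,
                      KEEP.OUT.ATTRS = FALSE)
  eps <- debye_permittivity(grid$frequency, grid$temperature, params)
  tibble::tibble(
    frequency = grid$frequency,
    temperature = grid$temperature,
    permittivity = eps,
    relative_permittivity = Re(eps),
    conductivity = conductivity_from_permittivity(grid$frequency, -Im(eps))
  )
}

#' Coefficient of determination of an ordinary least-squares line
#'
#' Fits `y ~ x` by ordinary least squares and returns
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param x,y Numeric vectors of equal length (at least 3 points).
#' @return \eqn{R^2 \in (-\infty, 1]}.
#' @examples
#' linearity_r2(1:10, 2 * (1:10) + 3)  # exactly collinear: 1
#' @export
linearity_r2 <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) abort("at least 3 points are required")
  if (sd(x) == 0) abort("'x' values are all identical; no line can be fit")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    abort("'y' values are all identical (SS_tot = 0); R^2 is undefined")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / ss_tot
}

#' Per-step relative sensitivity of a dielectric property
#'
#' Converts the total change of a property between the two endpoint
#' temperatures of the cooling protocol (26.0 °C and 36.5 °C) into a per-step
#' (0.1 °C) relative change, in percent:
#' \deqn{\eta = 100 \cdot \frac{v(26) - v(36.5)}{n_T \cdot v_{ref}}.}
#'
#' The reference defaults to the low-temperature value `value_low_t`
#' (self-normalization). The published conductivity sensitivities are
#' normalized instead by the relative permittivity at 26 °C; pass that value
#' as `reference` to reproduce them (see [sensitivity_table()]).
#'
#' @param value_low_t Property value at the low (final) temperature, 26 °C.
#' @param value_high_t Property value at the high (initial) temperature,
#'   36.5 °C.
#' @param n_steps Number of 0.1 °C increments between the endpoints (105 for
#'   the 26.0--36.5 °C protocol).
#' @param reference Normalization value; defaults to `value_low_t`.
#' @return Per-step relative sensitivity, in percent.
#' @export
relative_sensitivity <- function(value_low_t, value_high_t, n_steps,
                                 reference = value_low_t) {
  stopifnot(length(n_steps) == 1, n_steps >= 1)
  if (any(reference == 0)) abort("zero reference value: sensitivity undefined")
  100 * (value_low_t - value_high_t) / (n_steps * reference)
}

#' Per-frequency temperature sensitivities of water dielectrics
#'
#' For each frequency, computes the per-0.1 °C relative sensitivities of the
#' relative permittivity (`eta_eps`) and of the conductivity (`eta_sigma`)
#' over the 26.0--36.5 °C protocol (105 steps), in percent.
#'
#' `eta_eps` is self-normalized by \eqn{\varepsilon_r(26\,°C)}. `eta_sigma`
#' divides the per-step change of \eqn{\sigma} (S/m) by
#' \eqn{\varepsilon_r(26\,°C)} at the same frequency: this is the
#' normalization under which the published per-frequency conductivity
#' sensitivities (and the derived contrast equivalents of a temperature
#' difference) are mutually consistent, and it gives `eta_sigma` an exact
#' \eqn{f^2} scaling in the low-loss regime.
#'
#' @param params A [debye_water()] parameterization.
#' @param frequencies Frequencies in Hz, within 0.5--3 GHz.
#' @param t_low,t_high Endpoint temperatures of the protocol, °C.
#' @param step Temperature resolution, °C.
#' @return A tibble (class `sensitivity_table`) with columns `frequency`
#'   (Hz), `eta_eps` (%), `eta_sigma` (%), and attribute `n_steps`.
#' @examples
#' sensitivity_table(debye_water(), seq(0.5e9, 3e9, by = 0.5e9))
#' @export
sensitivity_table <- function(params = debye_water(),
                              frequencies = seq(0.5e9, 3e9, by = 0.5e9),
                              t_low = 26, t_high = 36.5, step = 0.1) {
  stopifnot(t_low < t_high, step > 0)
  if (any(frequencies < 0.5e9 - 1e-6 | frequencies > 3e9 + 1e-6)) {
    abort("frequencies must lie within the 0.5-3 GHz characterization band")
  }
  n_steps <- round((t_high - t_low) / step)
  eps_lo <- debye_permittivity(frequencies, t_low, params)
  eps_hi <- debye_permittivity(frequencies, t_high, params)
  er_lo <- Re(eps_lo)
  sig_lo <- conductivity_from_permittivity(frequencies, -Im(eps_lo))
  sig_hi <- conductivity_from_permittivity(frequencies, -Im(eps_hi))
  out <- tibble::tibble(
    frequency = frequencies,
    eta_eps = relative_sensitivity(er_lo, Re(eps_hi), n_steps),
    eta_sigma = relative_sensitivity(sig_lo, sig_hi, n_steps,
                                     reference = er_lo)
  )
  structure(out,
            n_steps = n_steps, t_low = t_low, t_high = t_high,
            class = c("sensitivity_table", class(out)))
}

#' Export a sensitivity table as delimited text
#'
#' Writes the table as tab-separated text with frequency in GHz, mirroring
#' the layout of the published per-frequency sensitivity tables.
#'
#' @param table A [sensitivity_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_table <- function(table, path) {
  out <- data.frame(
    frequency_ghz = table$frequency / 1e9,
    eta_eps_percent = table$eta_eps,
    eta_sigma_percent = table$eta_sigma
  )
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
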