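#' Cylindrical phantom scene with a circular inclusion
#'
#' Describes the imaging scene: a water-filled cylinder (the head phantom)
#' at a fixed background temperature, containing one circular inclusion (the
#' tube target) that is either water at a different temperature or an
#' arbitrary medium supplied as a permittivity function (e.g. air for the
#' strong-contrast validation case).
#'
#' @param params A [debye_water()] parameterization for the water media.
#' @param background_temperature Background water temperature, °C.
#' @param inclusion_center `(x, y)` center of the inclusion, mm.
#' @param inclusion_radius Inclusion radius, mm (default 4: an 8-mm tube).
#' @param inclusion_temperature Inclusion water temperature, °C (ignored if
#'   `inclusion_permittivity` is given).
#' @param inclusion_permittivity Optional function `f -> complex permittivity`
#'   overriding the water model for the inclusion (e.g.
#'   `function(f) 1 + 0i` for air).
#' @param phantom_inner_radius Inner radius of the phantom shell, mm.
#' @param roi_radius Imaging region radius, mm; the inclusion must lie
#'   entirely inside it.
#' @return An object of class `phantom_scene`.
#' @examples
#' phantom_scene(inclusion_temperature = 40.5)
#' @export
phantom_scene <- function(params = debye_water(),
                          background_temperature = 25,
                          inclusion_center = c(-25, 10),
                          inclusion_radius = 4,
                          inclusion_temperature = 36,
                          inclusion_permittivity = NULL,
                          phantom_inner_radius = 105,
                          roi_radius = 100) {
  stopifnot(length(inclusion_center) == 2, is.numeric(inclusion_center))
  if (inclusion_radius <= 0) abort("inclusion_radius must be positive")
  if (sqrt(sum(inclusion_center^2)) + inclusion_radius > roi_radius) {
    abort("inclusion is not entirely inside the imaging region")
  }
  if (!is.null(inclusion_permittivity) &&
      !is.function(inclusion_permittivity)) {
    abort("inclusion_permittivity must be NULL or a function of frequency")
  }
  structure(
    list(
      params = params,
      background_temperature = background_temperature,
      inclusion_center = inclusion_center,
      inclusion_radius = inclusion_radius,
      inclusion_temperature = inclusion_temperature,
      inclusion_permittivity = inclusion_permittivity,
      phantom_inner_radius = phantom_inner_radius,
      roi_radius = roi_radius
    ),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("<phantom_scene> background water at ", x$background_temperature,
      " degC, inner radius ", x$phantom_inner_radius, " mm\n", sep = "")
  cat("  inclusion: radius ", x$inclusion_radius, " mm at (",
      x$inclusion_center[1], ", ", x$inclusion_center[2], ") mm, ",
      if (is.null(x$inclusion_permittivity))
        paste0("water at ", x$inclusion_temperature, " degC")
      else "custom medium", "\n", sep = "")
  invisible(x)
}

#' Complex permittivity of the scene media
#'
#' @param scene A [phantom_scene()].
#' @param f Frequencies in Hz.
#' @param which `"background"` or `"inclusion"`.
#' @return Complex permittivity, vectorized over `f`.
#' @export
scene_permittivity <- function(scene, f,
                               which = c("background", "inclusion")) {
  which <- match.arg(which)
  if (which == "background") {
    debye_permittivity(f, scene$background_temperature, scene$params)
  } else if (!is.null(scene$inclusion_permittivity)) {
    scene$inclusion_permittivity(f)
  } else {
    debye_permittivity(f, scene$inclusion_temperature, scene$params)
  }
}

#' Frequency-sweep and noise settings of an acquisition
#'
#' @param f_start,f_stop Sweep limits, Hz.
#' @param n_points Number of frequency points (linear sweep).
#' @param noise_floor_db Per-point additive complex-noise floor, dB
#'   (20*log10 of the expected noise magnitude); `-Inf` disables noise.
#' @param highband_cutoff Frequency (Hz) above which antenna transmission
#'   collapses: synthetic off-diagonal entries are forced below -80 dB with
#'   randomized phase, emulating the loss of usable transmission there.
#' @param seed Integer seed governing all randomness of the acquisition.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(f_start = 0.5e9, f_stop = 3e9, n_points = 201,
                             noise_floor_db = -100,
                             highband_cutoff = 2.3e9, seed = 1L) {
  stopifnot(n_points >= 2, f_start < f_stop)
  structure(
    list(f_start = f_start, f_stop = f_stop, n_points = as.integer(n_points),
         noise_floor_db = noise_floor_db,
         highband_cutoff = highband_cutoff, seed = as.integer(seed)),
    class = "acquisition_spec"
  )
}

#' Frequency grid of an acquisition
#' @param acq An [acquisition_spec()].
#' @return Frequencies in Hz.
#' @export
acq_frequencies <- function(acq) {
  seq(acq$f_start, acq$f_stop, length.out = acq$n_points)
}

# complex background wavenumber, rad/m; Im <= 0 so exp(-i k d) decays
background_wavenumber <- function(f, eps_bg) {
  2 * pi * f * sqrt(eps_bg) / .c0
}

# outgoing 2D Green's function of a homogeneous medium, large-argument
# Hankel form; k in rad/m, d in meters (valid for |k d| >~ 2, which holds
# for every antenna-to-ROI path in the 0.5-3 GHz band in water)
green2d <- function(k, d) {
  (-1i / 4) * sqrt(2 / (pi * k * d)) * exp(-1i * (k * d - pi / 4))
}

# quadrature cell centers (mm) covering the inclusion disk
born_cells <- function(scene, cell) {
  if (cell > scene$inclusion_radius / 4) {
    abort("quadrature cell must not exceed a quarter of the inclusion radius")
  }
  r <- scene$inclusion_radius
  ax <- seq(-r + cell / 2, r - cell / 2, by = cell)
  g <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$x^2 + g$y^2 <= r^2, , drop = FALSE]
  cbind(g$x + scene$inclusion_center[1], g$y + scene$inclusion_center[2])
}

# unordered transmission channels of a 4-port array
default_channels <- function() {
  tibble::tibble(tx = c(1L, 1L, 1L, 2L, 2L, 3L),
                 rx = c(2L, 3L, 4L, 3L, 4L, 4L))
}

#' First-order Born scattering contribution of the inclusion
#'
#' Computes the weak-scattering (Born) transmission contribution of the
#' inclusion between a transmit and a receive point:
#' \deqn{k_b^2 \int_{incl} \Delta\chi\, G(tx, r)\, G(r, rx)\, dA,}
#' with contrast \eqn{\Delta\chi = (\varepsilon_{incl} -
#' \varepsilon_{bg})/\varepsilon_{bg}}, the complex background wavenumber
#' \eqn{k_b}, and the outgoing 2D Green's function `G` of the background
#' medium, discretized on a square sub-millimeter quadrature grid.
#'
#' @param scene A [phantom_scene()].
#' @param tx_xy,rx_xy Transmit/receive points `(x, y)`, mm (must differ).
#' @param f Frequencies in Hz.
#' @param cell Quadrature cell side, mm (at most `inclusion_radius / 4`).
#' @return Complex scattering contribution, vectorized over `f`.
#' @export
born_transmission <- function(scene, tx_xy, rx_xy, f, cell = 0.25) {
  if (isTRUE(all.equal(tx_xy, rx_xy))) {
    abort("transmit and receive points must differ")
  }
  cells <- born_cells(scene, cell)
  d_tx <- path_length(matrix(tx_xy, 1), cells) * 1e-3
  d_rx <- path_length(matrix(rx_xy, 1), cells) * 1e-3
  da <- (cell * 1e-3)^2
  eps_bg <- scene_permittivity(scene, f, "background")
  chi <- (scene_permittivity(scene, f, "inclusion") - eps_bg) / eps_bg
  k <- background_wavenumber(f, eps_bg)
  vapply(seq_along(f), function(i) {
    k[i]^2 * chi[i] * da *
      sum(green2d(k[i], d_tx) * green2d(k[i], d_rx))
  }, complex(1))
}

# Precomputes everything about the forward model that does not depend on
# the inclusion contrast: baseline coupling, Born geometry kernel per
# (frequency, channel), and the deterministic high-band replacement values.
forward_components <- function(scene, array, acq, cell = 0.25) {
  freqs <- acq_frequencies(acq)
  nf <- length(freqs)
  ch <- default_channels()
  eps_bg <- scene_permittivity(scene, freqs, "background")
  k <- background_wavenumber(freqs, eps_bg)
  cells <- born_cells(scene, cell)
  da <- (cell * 1e-3)^2

  freq_dep_pos <- any(array$phase_center_poly != 0)
  pos0 <- as.matrix(antenna_positions(array, freqs[1])[, c("x", "y")])

  baseline <- array(0i, c(4, 4, nf))
  kernel <- matrix(0i, nf, nrow(ch))
  for (i in seq_len(nf)) {
    pos <- if (freq_dep_pos)
      as.matrix(antenna_positions(array, freqs[i])[, c("x", "y")]) else pos0
    # antenna-to-antenna baseline: smooth decaying channel, cancels in the
    # differential; diagonal is a placeholder reflection (unused for imaging)
    d_aa <- as.matrix(stats::dist(pos)) * 1e-3
    b <- 0.05 * sqrt(0.05 / pmax(d_aa, 1e-6)) * exp(-1i * k[i] * d_aa)
    diag(b) <- 0.4 * exp(-1i * 2 * pi * freqs[i] * 1e-9)
    baseline[, , i] <- b
    # Born geometry factor: k^2 dA sum_cells G(tx,.) G(.,rx)
    d_ac <- 1e-3 * sqrt(
      outer(pos[, 1], cells[, 1], "-")^2 + outer(pos[, 2], cells[, 2], "-")^2
    )
    g <- green2d(k[i], d_ac)              # 4 x n_cells
    m <- g %*% t(g)                       # m[t, r] = sum_c g[t,c] g[r,c]
    kernel[i, ] <- k[i]^2 * da * m[cbind(ch$tx, ch$rx)]
  }

  hb_mask <- freqs > acq$highband_cutoff
  hb_values <- NULL
  if (any(hb_mask)) {
    hb_values <- withr::with_seed(acq$seed, {
      n <- sum(hb_mask) * nrow(ch)
      mag <- 10^((-85 - 15 * stats::runif(n)) / 20)
      matrix(mag * exp(2i * pi * stats::runif(n)), sum(hb_mask), nrow(ch))
    })
  }
  list(freqs = freqs, eps_bg = eps_bg, k = k, channels = ch,
       baseline = baseline, kernel = kernel,
       hb_mask = hb_mask, hb_values = hb_values)
}

# assemble one S-parameter set from precomputed components
assemble_sparams <- function(fc, chi, acq, noise, noise_seed,
                             temperature, timestamp) {
  nf <- length(fc$freqs)
  ch <- fc$channels
  s <- fc$baseline
  for (j in seq_len(nrow(ch))) {
    v <- fc$kernel[, j] * chi
    s[ch$tx[j], ch$rx[j], ] <- s[ch$tx[j], ch$rx[j], ] + v
    s[ch$rx[j], ch$tx[j], ] <- s[ch$rx[j], ch$tx[j], ] + v
  }
  if (any(fc$hb_mask)) {
    idx <- which(fc$hb_mask)
    for (j in seq_len(nrow(ch))) {
      s[ch$tx[j], ch$rx[j], idx] <- fc$hb_values[, j]
      s[ch$rx[j], ch$tx[j], idx] <- fc$hb_values[, j]
    }
  }
  if (noise && is.finite(acq$noise_floor_db)) {
    sdn <- 10^(acq$noise_floor_db / 20) / sqrt(2)
    s <- s + withr::with_seed(noise_seed, {
      n <- array(complex(real = rnorm(16 * nf, sd = sdn),
                         imaginary = rnorm(16 * nf, sd = sdn)), c(4, 4, nf))
      # symmetrize so synthetic reciprocity survives the noise
      for (i in 1:3) for (jj in (i + 1):4) n[jj, i, ] <- n[i, jj, ]
      n
    })
  }
  structure(
    list(frequencies = fc$freqs, s = s,
         metadata = list(temperature = temperature,
                         background_temperature = NA_real_,
                         timestamp = timestamp, z0 = 50,
                         noise_floor_db = if (noise) acq$noise_floor_db
                                          else -Inf)),
    class = "sparam_set"
  )
}

#' Simulate a four-port S-parameter acquisition
#'
#' Total synthetic scattering parameters of the scene: a smooth baseline
#' coupling between antennas (identical in background and target states, so
#' it cancels exactly in the differential), plus the first-order Born
#' contribution of the inclusion, plus optional circular complex Gaussian
#' noise at the acquisition noise floor. Above the high-band cutoff,
#' transmission entries are replaced by values below -80 dB with randomized
#' (but seed-deterministic) phase. The result is reciprocal by construction;
#' diagonal (reflection) entries hold a placeholder model and are not used
#' for imaging.
#'
#' @param scene A [phantom_scene()].
#' @param array An [antenna_array()].
#' @param acq An [acquisition_spec()].
#' @param noise Logical; add the additive noise term?
#' @param noise_seed Seed for the noise draw (defaults to `acq$seed`).
#' @param cell Born quadrature cell, mm.
#' @param timestamp Acquisition time, s (metadata).
#' @return An object of class `sparam_set`: `frequencies` (Hz), `s`
#'   (4 x 4 x n complex array), `metadata`.
#' @export
simulate_sparams <- function(scene, array, acq, noise = TRUE,
                             noise_seed = acq$seed, cell = 0.25,
                             timestamp = 0) {
  fc <- forward_components(scene, array, acq, cell)
  eps_inc <- scene_permittivity(scene, fc$freqs, "inclusion")
  chi <- (eps_inc - fc$eps_bg) / fc$eps_bg
  out <- assemble_sparams(fc, chi, acq, noise, noise_seed,
                          temperature = scene$inclusion_temperature,
                          timestamp = timestamp)
  out$metadata$background_temperature <- scene$background_temperature
  out
}

#' @export
print.sparam_set <- function(x, ...) {
  cat("<sparam_set> 4-port, ", length(x$frequencies), " points, ",
      signif(min(x$frequencies) / 1e9, 3), "-",
      signif(max(x$frequencies) / 1e9, 3), " GHz\n", sep = "")
  cat("  inclusion temperature: ", x$metadata$temperature,
      " degC, timestamp: ", signif(x$metadata$timestamp, 4), " s\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.sparam_set <- function(x, ...) {
  nf <- length(x$frequencies)
  idx <- expand.grid(rx = 1:4, tx = 1:4, fi = seq_len(nf),
                     KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    frequency = x$frequencies[idx$fi],
    tx = idx$tx, rx = idx$rx,
    s = x$s[cbind(idx$rx, idx$tx, idx$fi)]
  )
}

#' Simulate the cooling experiment
#'
#' Generates one S-parameter set per 0.1 °C step while the inclusion cools
#' from `t_start` to `t_stop` inside the constant-temperature background.
#' Acquisition timestamps follow a two-phase timing model (cooling slows as
#' the target approaches room temperature): the first 23 inter-acquisition
#' intervals have mean 4.78 s (sd 0.99 s) and the remaining ones mean 5.77 s
#' (sd 0.68 s).
#'
#' @param scene A [phantom_scene()]; its inclusion temperature is overridden
#'   step by step.
#' @param array An [antenna_array()].
#' @param acq An [acquisition_spec()].
#' @param t_start,t_stop,step Cooling protocol, °C (default 40.5 down to
#'   36.0 in 0.1 °C steps: 46 acquisitions).
#' @param timing_seed Seed for the timing draw.
#' @param timing_noise Logical; if `FALSE` the intervals are exactly their
#'   phase means (total duration `23 * 4.78 + 22 * 5.77` s for the default
#'   protocol).
#' @param noise Logical; per-acquisition additive noise.
#' @param cell Born quadrature cell, mm.
#' @return An object of class `cooling_series`: `temperatures`,
#'   `acquisition_times` (s), `s_sets` (list of `sparam_set`), plus the
#'   scene, array and acquisition used.
#' @export
cooling_series <- function(scene, array, acq,
                           t_start = 40.5, t_stop = 36.0, step = 0.1,
                           timing_seed = acq$seed + 1L, timing_noise = TRUE,
                           noise = TRUE, cell = 0.25) {
  stopifnot(step > 0, t_start > t_stop)
  temps <- round(seq(t_start, t_stop, by = -step), 6)
  n <- length(temps)
  n_fast <- min(23L, n - 1L)
  mu <- c(rep(4.78, n_fast), rep(5.77, n - 1L - n_fast))
  sdv <- c(rep(0.99, n_fast), rep(0.68, n - 1L - n_fast))
  intervals <- if (timing_noise) {
    withr::with_seed(timing_seed, pmax(rnorm(n - 1L, mu, sdv), 0.5))
  } else mu
  times <- c(0, cumsum(intervals))

  fc <- forward_components(scene, array, acq, cell)
  s_sets <- vector("list", n)
  for (i in seq_len(n)) {
    eps_inc <- debye_permittivity(fc$freqs, temps[i], scene$params)
    chi <- (eps_inc - fc$eps_bg) / fc$eps_bg
    seed_i <- (acq$seed + 7919L * i) %% 2147483629L
    s_sets[[i]] <- assemble_sparams(fc, chi, acq, noise, seed_i,
                                    temperature = temps[i],
                                    timestamp = times[i])
    s_sets[[i]]$metadata$background_temperature <-
      scene$background_temperature
  }
  structure(
    list(temperatures = temps, acquisition_times = times, s_sets = s_sets,
         scene = scene, array = array, acq = acq),
    class = "cooling_series"
  )
}

#' @export
print.cooling_series <- function(x, ...) {
  cat("<cooling_series> ", length(x$temperatures), " acquisitions, ",
      x$temperatures[1], " down to ",
      x$temperatures[length(x$temperatures)], " degC\n", sep = "")
  cat("  total duration ",
      signif(max(x$acquisition_times), 4), " s, mean interval ",
      signif(mean(diff(x$acquisition_times)), 3), " s\n", sep = "")
  invisible(x)
}

#' Write a four-port Touchstone (.s4p) file
#'
#' Standard Touchstone v1 format: real/imaginary pairs, frequency in Hz,
#' 50-ohm reference, one S-matrix row per data line. Scene metadata is
#' stored in comment lines (`! key = value`) and recovered by
#' [read_touchstone()].
#'
#' @param sset A `sparam_set`.
#' @param path Output path (conventionally `.s4p`).
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(sset, path) {
  stopifnot(inherits(sset, "sparam_set"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    abort(sprintf("cannot open '%s' for writing", path))
  }
  on.exit(close(con))
  md <- sset$metadata
  writeLines(c(
    "! synthetic 4-port scattering parameters (diffmwi)",
    sprintf("! temperature_c = %.6g", md$temperature),
    sprintf("! background_temperature_c = %.6g", md$background_temperature),
    sprintf("! timestamp_s = %.6g", md$timestamp),
    "# Hz S RI R 50"
  ), con)
  nf <- length(sset$frequencies)
  for (i in seq_len(nf)) {
    for (r in 1:4) {
      vals <- as.vector(rbind(Re(sset$s[r, , i]), Im(sset$s[r, , i])))
      prefix <- if (r == 1) sprintf("%.12e", sset$frequencies[i]) else "    "
      writeLines(paste(prefix, paste(sprintf("%.12e", vals), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a four-port Touchstone (.s4p) file
#'
#' @param path File written by [write_touchstone()] (or any 4-port
#'   Touchstone v1 file in RI format).
#' @return A `sparam_set`.
#' @export
read_touchstone <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such Touchstone file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  md <- list(temperature = NA_real_, background_temperature = NA_real_,
             timestamp = NA_real_, z0 = 50)
  comment <- grepl("^\\s*!", lines)
  for (ln in lines[comment]) {
    m <- regmatches(ln, regexec("!\\s*([a-z_]+)\\s*=\\s*([-0-9.eE+]+)", ln))[[1]]
    if (length(m) == 3) {
      key <- sub("_c$|_s$", "", m[2])
      if (key == "temperature") md$temperature <- as.numeric(m[3])
      if (key == "background_temperature")
        md$background_temperature <- as.numeric(m[3])
      if (key == "timestamp") md$timestamp <- as.numeric(m[3])
    }
  }
  opt <- which(grepl("^\\s*#", lines))
  if (length(opt) != 1) {
    abort(sprintf("malformed Touchstone header in '%s': expected one '#' option line, found %d",
                  path, length(opt)))
  }
  tok <- toupper(strsplit(trimws(sub("^\\s*#", "", lines[opt])), "\\s+")[[1]])
  unit_scale <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)[tok[1]]
  if (is.na(unit_scale) || tok[2] != "S") {
    abort(sprintf("malformed Touchstone option line %d in '%s': '%s'",
                  opt, path, lines[opt]))
  }
  if (tok[3] != "RI") {
    abort(sprintf("unsupported Touchstone format '%s' in '%s' (line %d): only RI is handled",
                  tok[3], path, opt))
  }
  if (length(tok) >= 5 && tok[4] == "R") md$z0 <- as.numeric(tok[5])
  data_lines <- lines[!comment & !grepl("^\\s*#", lines) &
                        nzchar(trimws(lines))]
  nums <- suppressWarnings(as.numeric(unlist(strsplit(trimws(data_lines),
                                                      "\\s+"))))
  if (anyNA(nums)) {
    abort(sprintf("malformed numeric data in Touchstone file '%s'", path))
  }
  if (length(nums) %% 33 != 0) {
    abort(sprintf("malformed Touchstone data in '%s': %d values is not a whole number of 4-port blocks (33 values each)",
                  path, length(nums)))
  }
  nf <- length(nums) %/% 33
  block <- matrix(nums, nrow = 33)
  freqs <- block[1, ] * unit_scale
  s <- array(0i, c(4, 4, nf))
  for (i in seq_len(nf)) {
    v <- block[-1, i]
    # data lines are row-major (one S-matrix row per line)
    s[, , i] <- matrix(complex(real = v[seq(1, 31, 2)],
                               imaginary = v[seq(2, 32, 2)]), 4, 4,
                       byrow = TRUE)
  }
  structure(list(frequencies = freqs, s = s, metadata = md),
            class = "sparam_set")
}

#' Write a cooling series to disk as Touchstone files plus a manifest
#'
#' @param series A [cooling_series()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Manifest tibble (columns `index`, `temperature_c`, `timestamp_s`,
#'   `file`), invisibly; also written as `manifest.tsv` in `dir`.
#' @export
write_cooling_series <- function(series, dir, prefix = "acq") {
  stopifnot(inherits(series, "cooling_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(series$temperatures)
  files <- sprintf("%s_%02d.s4p", prefix, seq_len(n))
  for (i in seq_len(n)) {
    write_touchstone(series$s_sets[[i]], file.path(dir, files[i]))
  }
  manifest <- tibble::tibble(
    index = seq_len(n),
    temperature_c = series$temperatures,
    timestamp_s = series$acquisition_times,
    file = files
  )
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cooling series back from a manifest
#'
#' @param manifest_path Path to a `manifest.tsv` written by
#'   [write_cooling_series()].
#' @return A `cooling_series` (without the generating scene/array objects).
#' @export
read_cooling_series <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("no such manifest: '%s'", manifest_path))
  }
  man <- read.table(manifest_path, header = TRUE, sep = "\t")
  dir <- dirname(manifest_path)
  s_sets <- lapply(file.path(dir, man$file), read_touchstone)
  structure(
    list(temperatures = man$temperature_c,
         acquisition_times = man$timestamp_s,
         s_sets = s_sets, scene = NULL, array = NULL, acq = NULL),
    class = "cooling_series"
  )
}
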