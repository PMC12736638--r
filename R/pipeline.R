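#' Default run configuration
#'
#' The full set of parameters driving the end-to-end synthetic experiment:
#' geometry, scene, acquisition, cooling protocol, reconstruction and
#' analysis settings. [read_run_config()] merges a YAML file over these
#' defaults after validating it.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    geometry = list(
      aperture_radius = 100, pair_separation = 35, pair_offset = 90,
      orientation = 107.5, phase_center_poly = 0,
      roi_radius = 100, pitch = 1
    ),
    scene = list(
      debye_source = "stogryn1971",
      background_temperature = 25,
      inclusion_center = c(-25, 10),
      inclusion_radius = 4,
      phantom_inner_radius = 105
    ),
    acquisition = list(
      f_start = 0.5e9, f_stop = 3e9, n_points = 201,
      noise_floor_db = -100, highband_cutoff = 2.3e9, seed = 1
    ),
    cooling = list(
      t_start = 40.5, t_stop = 36.0, step = 0.1,
      timing_noise = TRUE
    ),
    reconstruction = list(
      band_low = 0.5e9, band_high = 2e9,
      conjugate = FALSE
    ),
    analysis = list(
      tolerance_mm = 9
    ),
    output = list(dir = "diffmwi-run")
  )
}

validate_config <- function(config, reference = default_config(),
                            path = "config") {
  if (!is.list(config)) abort(sprintf("%s: expected a mapping", path))
  unknown <- setdiff(names(config), names(reference))
  if (length(unknown)) {
    abort(sprintf("%s$%s: unknown key", path, unknown[1]))
  }
  for (key in names(config)) {
    if (is.list(reference[[key]])) {
      validate_config(config[[key]], reference[[key]],
                      paste0(path, "$", key))
    }
  }
  invisible(TRUE)
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected with the offending field path; missing keys
#' fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: '%s'", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
  modifyList(default_config(), user)
}

config_objects <- function(config) {
  g <- config$geometry
  s <- config$scene
  a <- config$acquisition
  list(
    array = antenna_array(
      aperture_radius = g$aperture_radius,
      pair_separation = g$pair_separation, pair_offset = g$pair_offset,
      orientation = g$orientation, phase_center_poly = g$phase_center_poly
    ),
    grid = imaging_grid(g$roi_radius, g$pitch),
    scene = phantom_scene(
      params = debye_water(s$debye_source),
      background_temperature = s$background_temperature,
      inclusion_center = unlist(s$inclusion_center),
      inclusion_radius = s$inclusion_radius,
      inclusion_temperature = config$cooling$t_start,
      phantom_inner_radius = s$phantom_inner_radius,
      roi_radius = g$roi_radius
    ),
    acq = acquisition_spec(
      f_start = a$f_start, f_stop = a$f_stop, n_points = a$n_points,
      noise_floor_db = a$noise_floor_db,
      highband_cutoff = a$highband_cutoff, seed = a$seed
    )
  )
}

#' Simulate the cooling experiment described by a configuration
#'
#' Runs [cooling_series()] and writes one Touchstone file per temperature
#' step plus a `manifest.tsv` into the configured output directory (created
#' if missing).
#'
#' @param config A configuration list ([default_config()] or
#'   [read_run_config()]).
#' @param dir Output directory; defaults to the configured one.
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(config = default_config(),
                         dir = config$output$dir) {
  obj <- config_objects(config)
  cc <- config$cooling
  series <- cooling_series(
    obj$scene, obj$array, obj$acq,
    t_start = cc$t_start, t_stop = cc$t_stop, step = cc$step,
    timing_noise = isTRUE(cc$timing_noise)
  )
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory: ", dir)
  }
  manifest <- write_cooling_series(series, dir)
  message(sprintf(
    "simulated %d acquisitions (seed %d), mean interval %.2f s",
    length(series$temperatures), obj$acq$seed,
    mean(diff(series$acquisition_times))
  ))
  invisible(manifest)
}

#' Reconstruct a simulated dataset from its manifest
#'
#' Reads the Touchstone files listed in a manifest, forms the differential
#' data of every step against the first (hottest) acquisition, and images
#' them over the configured band.
#'
#' @param config A configuration list.
#' @param manifest_path Path to `manifest.tsv`; defaults to the configured
#'   output directory.
#' @param keep_images Retain per-step images (see [reconstruct_series()]).
#' @return An `mfbf_series`; its peak summary is also written next to the
#'   manifest as `peaks.tsv`.
#' @export
run_reconstruct <- function(config = default_config(),
                            manifest_path = file.path(config$output$dir,
                                                      "manifest.tsv"),
                            keep_images = FALSE) {
  obj <- config_objects(config)
  series <- read_cooling_series(manifest_path)
  r <- config$reconstruction
  message(sprintf(
    "imaging band %.2f-%.2f GHz", r$band_low / 1e9, r$band_high / 1e9
  ))
  res <- reconstruct_series(
    series, obj$array, obj$grid,
    medium = background_medium(debye_water(config$scene$debye_source),
                               config$scene$background_temperature),
    band = c(r$band_low, r$band_high),
    conjugate = isTRUE(r$conjugate),
    keep_images = keep_images
  )
  message(sprintf("%d frequency points in band, %d differential images",
                  res$n_band, nrow(res$peaks)))
  write.table(res$peaks, file.path(dirname(manifest_path), "peaks.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  res
}

#' Analyze a reconstructed series
#'
#' Builds the [detection_report()] for a peak summary: localization errors
#' against the configured true target position, the peak-versus-contrast
#' regression, the detection threshold and its dielectric-contrast
#' equivalent.
#'
#' @param config A configuration list.
#' @param peaks Peak summary tibble (from [run_reconstruct()] or read from
#'   `peaks.tsv`).
#' @param path Optional output path for [write_detection_report()].
#' @return A `detection_report`.
#' @export
run_analyze <- function(config = default_config(), peaks, path = NULL) {
  if (nrow(peaks) < 3) abort("need at least 3 reconstructed steps to analyze")
  sens <- sensitivity_table(debye_water(config$scene$debye_source))
  rep <- detection_report(
    peaks,
    true_center = unlist(config$scene$inclusion_center),
    tolerance = config$analysis$tolerance_mm,
    sensitivity = sens,
    band = c(config$reconstruction$band_low,
             config$reconstruction$band_high)
  )
  if (!is.null(path)) write_detection_report(rep, path)
  rep
}
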