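test_that("scene construction enforces its geometric invariants", {
  expect_error(phantom_scene(inclusion_radius = -1), "positive")
  expect_error(phantom_scene(inclusion_center = c(99, 0)), "inside")
  s <- air_scene()
  expect_equal(scene_permittivity(s, 1e9, "inclusion"), 1 + 0i)
  s2 <- thermal_scene(40.5)
  expect_equal(scene_permittivity(s2, 1e9, "inclusion"),
               debye_permittivity(1e9, 40.5))
  expect_equal(scene_permittivity(s2, 1e9, "background"),
               debye_permittivity(1e9, 25))
})

test_that("Born contribution is zero at zero contrast and linear in it", {
  tx <- c(100, 0); rx <- c(0, 100); f <- 1e9
  s0 <- phantom_scene(inclusion_temperature = 25)  # same as background
  expect_equal(born_transmission(s0, tx, rx, f), 0 + 0i)
  # doubling the contrast doubles the signal
  base <- debye_permittivity(f, 25)
  chi <- 0.01
  s1 <- phantom_scene(inclusion_permittivity = function(ff)
    debye_permittivity(ff, 25) * (1 + chi))
  s2 <- phantom_scene(inclusion_permittivity = function(ff)
    debye_permittivity(ff, 25) * (1 + 2 * chi))
  b1 <- born_transmission(s1, tx, rx, f)
  b2 <- born_transmission(s2, tx, rx, f)
  expect_equal(b2 / b1, 2 + 0i, tolerance = 1e-12)
  expect_gt(Mod(b1), 0)
})

test_that("centered inclusion gives mirror-symmetric channel magnitudes", {
  s <- phantom_scene(inclusion_center = c(0, 0), inclusion_radius = 4,
                     inclusion_temperature = 40)
  f <- 1.5e9
  b_right <- born_transmission(s, c(0, 100), c(100, 0), f)
  b_left <- born_transmission(s, c(0, 100), c(-100, 0), f)
  b_down <- born_transmission(s, c(0, -100), c(100, 0), f)
  expect_equal(Mod(b_left) / Mod(b_right), 1, tolerance = 1e-10)
  expect_equal(Mod(b_down) / Mod(b_right), 1, tolerance = 1e-10)
})

test_that("quadrature cell coarser than a quarter radius is rejected", {
  s <- thermal_scene(40)
  expect_error(born_transmission(s, c(100, 0), c(0, 100), 1e9, cell = 2),
               "quarter")
  expect_error(born_transmission(s, c(100, 0), c(100, 0), 1e9), "differ")
})

test_that("zero contrast with noise disabled gives identically zero differential", {
  arr <- fix_array(); acq <- quick_acq()
  a <- simulate_sparams(phantom_scene(inclusion_temperature = 25), arr, acq,
                        noise = FALSE)
  b <- simulate_sparams(phantom_scene(inclusion_temperature = 25), arr, acq,
                        noise = FALSE)
  expect_identical(a$s, b$s)
  d <- differential(a, b)
  expect_true(all(d$delta == 0))
})

test_that("air-filled inclusion dwarfs the thermal contrast at every in-band frequency", {
  arr <- fix_array(); acq <- quick_acq(n_points = 21)
  bg <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  th <- simulate_sparams(thermal_scene(36.0), arr, acq, noise = FALSE)
  air <- simulate_sparams(air_scene(), arr, acq, noise = FALSE)
  d_th <- differential(bg, th)
  d_air <- differential(bg, air)
  inband <- which(d_th$band_mask)
  for (i in inband) {
    expect_gt(Mod(d_air$delta[1, 2, i]), 10 * Mod(d_th$delta[1, 2, i]))
  }
})

test_that("transmission above the high-band cutoff collapses below -80 dB", {
  arr <- fix_array(); acq <- quick_acq(n_points = 201)
  s <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  hi <- which(s$frequencies > 2.3e9)
  offdiag <- which(upper.tri(matrix(0, 4, 4)) | lower.tri(matrix(0, 4, 4)),
                   arr.ind = TRUE)
  for (i in hi) {
    mags <- 20 * log10(Mod(s$s[cbind(offdiag, i)]))
    expect_true(all(mags < -80))
  }
})

test_that("synthetic data are reciprocal, exactly without noise and near the floor with it", {
  arr <- fix_array()
  s0 <- simulate_sparams(thermal_scene(40.5), arr, quick_acq(), noise = FALSE)
  for (i in seq_along(s0$frequencies)) {
    expect_identical(s0$s[, , i], t(s0$s[, , i]))
  }
  s1 <- simulate_sparams(thermal_scene(40.5), arr,
                         quick_acq(noise_floor_db = -100), noise = TRUE)
  asym <- max(vapply(seq_along(s1$frequencies), function(i) {
    max(Mod(s1$s[, , i] - t(s1$s[, , i])))
  }, numeric(1)))
  expect_equal(asym, 0)  # noise is drawn symmetrized
})

test_that("seeded simulations are bit-reproducible", {
  arr <- fix_array()
  acq <- quick_acq(noise_floor_db = -100, seed = 99L)
  a <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = TRUE)
  b <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = TRUE)
  expect_identical(a$s, b$s)
})

test_that("thermal differential magnitude grows with the temperature contrast", {
  arr <- fix_array(); acq <- quick_acq(n_points = 21)
  ser <- cooling_series(thermal_scene(), arr, acq, noise = FALSE,
                        timing_noise = FALSE)
  inband <- ser$s_sets[[1]]$frequencies <= 2e9
  mags <- vapply(2:46, function(i) {
    d <- ser$s_sets[[1]]$s - ser$s_sets[[i]]$s
    Mod(d[1, 2, which(inband)[5]])
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("cooling protocol covers 40.5 down to 36.0 in 46 steps", {
  arr <- fix_array()
  ser <- cooling_series(thermal_scene(), arr, quick_acq(), noise = FALSE,
                        timing_noise = FALSE)
  expect_length(ser$temperatures, 46)
  expect_equal(ser$temperatures[1], 40.5)
  expect_equal(ser$temperatures[46], 36.0)
  expect_equal(unique(round(diff(ser$temperatures), 6)), -0.1)
  # degenerate timing: exact two-phase total
  expect_equal(max(ser$acquisition_times), 23 * 4.78 + 22 * 5.77)
})

test_that("two-phase timing model reproduces the protocol's mean interval", {
  arr <- fix_array(); acq <- quick_acq(n_points = 2)
  means <- vapply(1:40, function(sd) {
    ser <- cooling_series(thermal_scene(), arr, acq, timing_seed = sd,
                          noise = FALSE)
    mean(diff(ser$acquisition_times))
  }, numeric(1))
  expect_equal(mean(means), 5.27, tolerance = 0.015)
})

test_that("Touchstone files round-trip frequencies, matrices and metadata", {
  arr <- fix_array()
  s <- simulate_sparams(thermal_scene(38.2), arr,
                        quick_acq(noise_floor_db = -90, n_points = 7),
                        noise = TRUE, timestamp = 12.5)
  path <- withr::local_tempfile(fileext = ".s4p")
  write_touchstone(s, path)
  back <- read_touchstone(path)
  expect_equal(back$frequencies, s$frequencies, tolerance = 1e-12)
  rel <- max(Mod(back$s - s$s)) / max(Mod(s$s))
  expect_lt(rel, 1e-9)
  expect_equal(back$metadata$temperature, 38.2)
  expect_equal(back$metadata$timestamp, 12.5)
})

test_that("a 201-point acquisition writes 201 Touchstone data blocks", {
  arr <- fix_array()
  s <- simulate_sparams(thermal_scene(40.5), arr, quick_acq(n_points = 201),
                        noise = FALSE)
  path <- withr::local_tempfile(fileext = ".s4p")
  write_touchstone(s, path)
  lines <- readLines(path)
  data <- lines[!grepl("^\\s*[!#]", lines) & nzchar(trimws(lines))]
  expect_equal(length(data), 201 * 4)
  expect_equal(length(read_touchstone(path)$frequencies), 201)
})

test_that("malformed Touchstone input is rejected with location context", {
  path <- withr::local_tempfile(fileext = ".s4p")
  writeLines(c("! comment", "# GHz S MA R 50", "1 0 0"), path)
  expect_error(read_touchstone(path), "only RI")
  writeLines(c("! no option line at all", "1 0 0"), path)
  expect_error(read_touchstone(path), "option line")
  writeLines(c("# Hz S RI R 50", "1e9 1 2 3"), path)
  expect_error(read_touchstone(path), "whole number")
  expect_error(read_touchstone("does-not-exist.s4p"), "no such")
})

test_that("a cooling series survives the manifest round trip", {
  arr <- fix_array()
  ser <- cooling_series(thermal_scene(), arr, quick_acq(n_points = 5),
                        noise = FALSE, timing_noise = FALSE)
  dir <- withr::local_tempdir()
  man <- write_cooling_series(ser, dir)
  expect_equal(nrow(man), 46)
  back <- read_cooling_series(file.path(dir, "manifest.tsv"))
  expect_equal(back$temperatures, ser$temperatures)
  expect_equal(back$acquisition_times, ser$acquisition_times,
               tolerance = 1e-6)
  rel <- max(Mod(back$s_sets[[46]]$s - ser$s_sets[[46]]$s)) /
    max(Mod(ser$s_sets[[46]]$s))
  expect_lt(rel, 1e-9)
})
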