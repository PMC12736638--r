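test_that("differential subtracts entry-wise and is antisymmetric", {
  arr <- fix_array(); acq <- quick_acq()
  a <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  b <- simulate_sparams(thermal_scene(36.0), arr, acq, noise = FALSE)
  d1 <- differential(a, b)
  d2 <- differential(b, a)
  expect_equal(d1$delta, a$s - b$s)
  expect_equal(d2$delta, -d1$delta)
  d0 <- differential(a, a)
  expect_true(all(d0$delta == 0))
  b$frequencies <- b$frequencies + 1e6
  expect_error(differential(a, b), "frequency grids differ")
})

test_that("thermal differential matches the direct Born-difference oracle", {
  arr <- fix_array(); acq <- quick_acq(n_points = 9)
  bg <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  tg <- simulate_sparams(thermal_scene(36.0), arr, acq, noise = FALSE)
  d <- differential(bg, tg)
  for (fi in which(d$band_mask)) {
    f <- d$frequencies[fi]
    pos <- antenna_positions(arr, f)
    oracle <- born_transmission(thermal_scene(40.5), c(pos$x[1], pos$y[1]),
                                c(pos$x[3], pos$y[3]), f) -
      born_transmission(thermal_scene(36.0), c(pos$x[1], pos$y[1]),
                        c(pos$x[3], pos$y[3]), f)
    expect_equal(d$delta[1, 3, fi], oracle, tolerance = 1e-10)
  }
})

test_that("band selection keeps the expected frequency counts", {
  arr <- fix_array(); acq <- quick_acq(n_points = 201)
  a <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  d <- differential(a, a)
  expect_equal(sum(d$band_mask), 121)  # default 0.5-2 GHz
  expect_equal(sum(select_band(d, 0.5e9, 3e9)$band_mask), 201)
  expect_equal(sum(select_band(d, 0.5e9, 2e9)$band_mask), 121)
  expect_error(select_band(d, 2e9, 1e9), "inverted")
  expect_error(select_band(d, 3.5e9, 4e9), "empty")
})

test_that("wavenumber follows 2*pi*f*sqrt(eps)/c", {
  c0 <- 299792458
  expect_equal(wavenumber(1e9, 1), 2 * pi * 1e9 / c0)
  expect_equal(wavenumber(1e9, 4), 2 * wavenumber(1e9, 1))
  er <- Re(debye_permittivity(1e9, 25))
  expect_equal(wavenumber(1e9, er), 2 * pi * 1e9 * sqrt(er) / c0,
               tolerance = 1e-12)
  expect_error(wavenumber(1e9, -2), "positive")
})

test_that("all-zero differential data give an identically zero image", {
  arr <- fix_array(); acq <- quick_acq()
  a <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  d <- differential(a, a)
  im <- mfbf_image(d, arr, imaging_grid(100, 10), background_medium())
  expect_true(all(im$intensity == 0))
  expect_error(image_peak(im), "undefined")
})

test_that("a matched synthetic point source focuses at its pixel", {
  arr <- fix_array(); acq <- quick_acq(n_points = 3)
  a <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  d <- differential(a, a)  # zero; overwrite one frequency by hand
  grid <- imaging_grid(100, 2)
  target <- c(-24, 10)
  f <- d$frequencies[1]
  d$band_mask <- c(TRUE, FALSE, FALSE)
  k <- wavenumber(f, background_medium()(f))
  pos <- antenna_positions(arr, f)
  for (j in seq_len(nrow(d$channels))) {
    tx <- d$channels$tx[j]; rx <- d$channels$rx[j]
    rho <- 1e-3 * (path_length(c(pos$x[tx], pos$y[tx]), target) +
                     path_length(c(pos$x[rx], pos$y[rx]), target))
    d$delta[tx, rx, 1] <- k^2 * exp(-1i * k * rho)
    d$delta[rx, tx, 1] <- d$delta[tx, rx, 1]
  }
  im <- mfbf_image(d, arr, grid, background_medium())
  pk <- image_peak(im)
  expect_lte(path_length(c(pk$x, pk$y), target), attr(grid, "pitch"))
})

test_that("imaging is linear in the differential data", {
  arr <- fix_array(); acq <- quick_acq(n_points = 7)
  bg <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  tgA <- simulate_sparams(thermal_scene(39.0), arr, acq, noise = FALSE)
  tgB <- simulate_sparams(thermal_scene(37.0), arr, acq, noise = FALSE)
  d1 <- differential(bg, tgA)
  d2 <- differential(bg, tgB)
  grid <- imaging_grid(100, 10)
  med <- background_medium()
  dmix <- d1
  dmix$delta <- 2.5 * d1$delta - 1.5i * d2$delta
  im_mix <- mfbf_image(dmix, arr, grid, med)
  im1 <- mfbf_image(d1, arr, grid, med)
  im2 <- mfbf_image(d2, arr, grid, med)
  expect_equal(im_mix$intensity,
               2.5 * im1$intensity - 1.5i * im2$intensity,
               tolerance = 1e-12)
})

test_that("vectorized imaging equals the naive triple-loop sum", {
  arr <- fix_array(); acq <- quick_acq(n_points = 9)
  bg <- simulate_sparams(thermal_scene(40.5), arr, acq, noise = FALSE)
  tg <- simulate_sparams(thermal_scene(36.0), arr, acq, noise = FALSE)
  d <- differential(bg, tg)
  grid <- imaging_grid(100, 10)
  med <- background_medium()
  for (conj in c(FALSE, TRUE)) {
    im <- mfbf_image(d, arr, grid, med, conjugate = conj)
    oracle <- brute_mfbf(d, arr, grid, med, conjugate = conj)
    expect_lt(max(Mod(im$intensity - oracle)) / max(Mod(oracle)), 1e-10)
  }
})

test_that("the air-target validation case localizes inside the inclusion", {
  arr <- fix_array(); acq <- quick_acq(n_points = 61)
  bg <- simulate_sparams(phantom_scene(inclusion_temperature = 25), arr,
                         acq, noise = FALSE)
  tg <- simulate_sparams(air_scene(), arr, acq, noise = FALSE)
  d <- differential(bg, tg)
  im <- mfbf_image(d, arr, imaging_grid(100, 1), background_medium())
  pk <- image_peak(im)
  expect_lte(path_length(c(pk$x, pk$y), c(-25, 10)), 4)
})

test_that("series reconstruction agrees with imaging each step separately", {
  arr <- fix_array(); acq <- quick_acq(n_points = 21)
  ser <- cooling_series(thermal_scene(), arr, acq, t_start = 40.5,
                        t_stop = 40.0, noise = FALSE, timing_noise = FALSE)
  grid <- imaging_grid(100, 5)
  res <- reconstruct_series(ser, arr, grid, keep_images = TRUE)
  expect_equal(nrow(res$peaks), 5)
  expect_equal(res$peaks$delta_t, seq(0.1, 0.5, by = 0.1))
  for (i in c(1, 5)) {
    d <- differential(ser$s_sets[[1]], ser$s_sets[[i + 1]])
    im <- mfbf_image(d, arr, grid, background_medium())
    expect_equal(res$images[[i]]$intensity, im$intensity, tolerance = 1e-10)
  }
})
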