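# shared fixtures, all built in code

fix_array <- function(...) antenna_array(...)

# fast sweep for forward-model tests (full band, few points)
quick_acq <- function(n_points = 11, noise_floor_db = -Inf, seed = 1L,
                      ...) {
  acquisition_spec(n_points = n_points, noise_floor_db = noise_floor_db,
                   seed = seed, ...)
}

thermal_scene <- function(temp = 40.5, ...) {
  phantom_scene(inclusion_temperature = temp, ...)
}

air_scene <- function(...) {
  phantom_scene(inclusion_permittivity = function(f) 1 + 0i, ...)
}

# independent triple-loop evaluation of the bi-focusing sum, kept naive on
# purpose: one pixel at a time, straight from the formula
brute_mfbf <- function(dset, array, grid, eps_fn, conjugate = FALSE) {
  sgn <- if (conjugate) -1 else 1
  fidx <- which(dset$band_mask)
  pos_by_f <- lapply(fidx, function(fi) {
    antenna_positions(array, dset$frequencies[fi])
  })
  k_by_f <- vapply(fidx, function(fi) {
    f <- dset$frequencies[fi]
    2 * pi * f * sqrt(eps_fn(f)) / 299792458
  }, numeric(1))
  out <- complex(nrow(grid))
  for (p in seq_len(nrow(grid))) {
    acc <- 0 + 0i
    for (i in seq_along(fidx)) {
      pos <- pos_by_f[[i]]
      k <- k_by_f[i]
      for (j in seq_len(nrow(dset$channels))) {
        tx <- dset$channels$tx[j]
        rx <- dset$channels$rx[j]
        rho_t <- 1e-3 * sqrt((pos$x[tx] - grid$x[p])^2 +
                               (pos$y[tx] - grid$y[p])^2)
        rho_r <- 1e-3 * sqrt((pos$x[rx] - grid$x[p])^2 +
                               (pos$y[rx] - grid$y[p])^2)
        acc <- acc + dset$delta[tx, rx, fidx[i]] / k^2 *
          exp(sgn * 1i * k * (rho_t + rho_r))
      }
    }
    out[p] <- acc
  }
  out
}
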