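make_unit_scan <- function(grid = energy_grid()) {
  # identity normalizer: one primary count per bin, no attenuation
  structure(list(with_sample = rep(1, length(grid$centers)),
                 without_sample = rep(1, length(grid$centers)),
                 energy_grid = grid,
                 metadata = list(exposure = 1, mode = "noiseless",
                                 phantom_id = "unit", seed = NULL)),
            class = "transmission_scan")
}

test_that("transmission correction divides by the per-energy normalizer and thickness", {
  ph <- make_brain_phantom(0.3)
  st <- simulate_stack(ph, default_geom, default_spectrum, mode = "noiseless")
  # identity normalizer and unit thickness: output equals input
  cc <- transmission_correct(st, make_unit_scan(), thickness = 1)
  expect_equal(cc$values, st$counts)
  # Ns proportional to Nt per bin reduces to the constant of proportionality
  scan <- simulate_transmission(ph, default_spectrum)
  st2 <- st
  st2$counts <- array(rep(5 * scan$with_sample, each = 80 * 80),
                      dim = dim(st$counts))
  cc2 <- transmission_correct(st2, scan, thickness = 1)
  expect_equal(range(cc2$values), c(5, 5))
  # counting uncertainty propagates as sqrt(N)/Nt
  expect_equal(cc$sd, sqrt(st$counts))
})

test_that("non-positive normalizer bins are flagged and excluded with a warning", {
  ph <- make_brain_phantom(0.3)
  st <- simulate_stack(ph, default_geom, default_spectrum, mode = "noiseless")
  scan <- simulate_transmission(ph, default_spectrum)
  scan$with_sample[30] <- 0  # inside the 30-45 keV analysis band
  expect_warning(cc <- transmission_correct(st, scan), "non-positive")
  expect_true(all(is.na(cc$values[, , 30])))
  expect_error(transmission_correct(st, make_unit_scan(energy_grid(10:50, c(30, 45)))),
               "energy grids")
})

test_that("q binning averages contributing pixels and conserves the bookkeeping sums", {
  ph <- make_brain_phantom(0.4)
  st <- simulate_stack(ph, default_geom, default_spectrum, mode = "poisson", seed = 11)
  scan <- simulate_transmission(ph, default_spectrum)
  cc <- transmission_correct(st, scan)
  sp <- bin_to_q(cc, default_geom, default_qgrid)
  expect_equal(dim(sp$s), c(length(default_qgrid$centers), 15))
  # pixel-count-weighted sum over q bins == sum over contributing pixels
  mask <- pixel_angle_map(default_geom)$mask
  theta <- pixel_angle_map(default_geom)$theta[mask]
  for (j in c(1, 8, 15)) {
    k <- which(abs(sp$energy_grid$centers - sp$energies[j]) < 1e-9)
    q <- q_of(sp$energies[j], theta)
    edges <- default_qgrid$bin_edges
    inside <- q >= edges[1] & q < edges[length(edges)]
    expect_equal(sum(sp$s[, j] * sp$n_pixels[, j], na.rm = TRUE),
                 sum(cc$values[, , k][mask][inside]))
  }
  # spatially constant corrected values give a flat profile in every energy bin
  cc_flat <- cc
  cc_flat$values[] <- 3.5
  sp_flat <- bin_to_q(cc_flat, default_geom, default_qgrid)
  expect_true(all(abs(sp_flat$s - 3.5) < 1e-12, na.rm = TRUE))
  # empty mask is rejected
  geom_blocked <- instrument_geometry(beamstop_radius = 40)
  expect_error(bin_to_q(cc, geom_blocked, default_qgrid), "mask")
})

test_that("energy summation skips missing cells and honors the band", {
  ph <- make_brain_phantom(0.4)
  sp <- bin_to_q(transmission_correct(
    simulate_stack(ph, default_geom, default_spectrum, mode = "noiseless"),
    simulate_transmission(ph, default_spectrum)), default_geom, default_qgrid)
  full <- sum_energy(sp)
  expect_equal(length(full$s), length(default_qgrid$centers))
  # a single-bin band returns that bin's row
  e1 <- sp$energies[3]
  one <- sum_energy(sp, band = c(e1 - 0.4, e1 + 0.4))
  expect_equal(one$s, sp$s[, 3])
  expect_error(sum_energy(sp, band = c(46, 49)), "empty")
  # all-zero spectral profile sums to zero
  sp0 <- sp; sp0$s[] <- 0; sp0$sd[] <- 0
  expect_true(all(sum_energy(sp0)$s == 0, na.rm = TRUE))
})

test_that("reduction is scale-equivariant and thickness-invariant", {
  ph <- make_brain_phantom(0.6, thickness = 8)
  st <- simulate_stack(ph, default_geom, default_spectrum, mode = "noiseless")
  scan <- simulate_transmission(ph, default_spectrum)
  p1 <- reduce_stack(st, scan, default_geom, default_qgrid)
  stc <- st; stc$counts <- stc$counts * 7
  p7 <- reduce_stack(stc, scan, default_geom, default_qgrid)
  expect_equal(p7$s, 7 * p1$s)
  # phantoms differing only in thickness reduce to the same profile
  ph2 <- make_brain_phantom(0.6, thickness = 14)
  p2 <- reduce_stack(simulate_stack(ph2, default_geom, default_spectrum,
                                    mode = "noiseless"),
                     simulate_transmission(ph2, default_spectrum),
                     default_geom, default_qgrid)
  expect_lt(max(abs(p2$s / p1$s - 1), na.rm = TRUE), 1e-6)
})

test_that("noiseless reduction recovers the generating S(q) shape (oracle equivalence)", {
  ph <- make_bsa_phantom()
  prof <- simulate_and_reduce(ph, mode = "noiseless")
  truth <- s_of_q(ph, prof$q_grid$centers)
  expect_gt(cor(prof$s, truth, use = "complete.obs"), 0.99)
  # provenance names the generating phantom
  expect_equal(prof$provenance$phantom_id, "bsa")
})
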