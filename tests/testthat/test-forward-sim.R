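test_that("BSA phantom has cross-beta maxima at 6.04 and 13.24 nm^-1", {
  ph <- make_bsa_phantom()
  qs <- seq(0.5, 28, by = 0.01)
  s <- s_of_q(ph, qs)
  expect_true(all(s >= 0))
  # local maxima of the model itself
  loc <- which(diff(sign(diff(s))) == -2) + 1
  expect_true(any(abs(qs[loc] - 6.04) < 0.1))
  expect_true(any(abs(qs[loc] - 13.24) < 0.3))
  # the 6.04 reflection dominates the 3.6-8.4 window over the background
  bg <- scattering_model(list(power_law_background(0.8, 1.5)))
  win <- qs >= 3.6 & qs <= 8.4
  expect_gt(sum(s[win] - s_of_q(bg, qs[win])), sum(s_of_q(bg, qs[win])))
})

test_that("brain phantom couples the 6.04 nm^-1 amplitude linearly to plaque density", {
  wt <- make_brain_phantom(0)
  kinds <- vapply(wt$scattering_model$components, `[[`, "", "kind")
  expect_false("bragg-peak" %in% kinds)
  ad1 <- make_brain_phantom(1); ad2 <- make_brain_phantom(2)
  amp_of <- function(p) {
    cc <- Filter(function(x) x$kind == "bragg-peak", p$scattering_model$components)
    cc[[1]]$amplitude
  }
  expect_equal(amp_of(ad2), 2 * amp_of(ad1))
  expect_error(make_brain_phantom(-0.5), "non-negative")
  # density 1 is anchored at 15% excess area over the wild-type window
  win <- c(3.6, 8.4)
  a_wt <- integrate(function(q) s_of_q(wt, q), win[1], win[2])$value
  a_ad <- integrate(function(q) s_of_q(ad1, q), win[1], win[2])$value
  expect_equal((a_ad - a_wt) / a_wt, 0.15, tolerance = 1e-6)
})

test_that("Kramers spectrum follows (kVp - E)/E and vanishes above the tube voltage", {
  grid <- energy_grid()
  sp <- kramers_spectrum(50, grid)
  expect_true(all(sp$photons_per_bin >= 0))
  e <- grid$centers
  above <- e >= 50
  expect_true(all(sp$photons_per_bin[above] == 0))
  i <- which(abs(e - 30.5) < 1e-9); j <- which(abs(e - 40.5) < 1e-9)
  expect_equal(sp$photons_per_bin[i] / sp$photons_per_bin[j],
               ((50 - 30.5) / 30.5) / ((50 - 40.5) / 40.5))
  # filtration multiplies in
  spf <- kramers_spectrum(50, grid, filtration = function(e) rep(0.5, length(e)))
  expect_equal(spf$photons_per_bin, sp$photons_per_bin * 0.5)
})

test_that("simulate_stack honors exposure, masking and the seed contract", {
  ph <- make_brain_phantom(0.5)
  expect_error(simulate_stack(ph, default_geom, default_spectrum,
                              mode = "poisson"), "seed")
  z <- simulate_stack(ph, default_geom, default_spectrum, exposure = 0,
                      mode = "noiseless")
  expect_true(all(z$counts == 0))
  s1 <- simulate_stack(ph, default_geom, default_spectrum, mode = "poisson", seed = 3)
  s2 <- simulate_stack(ph, default_geom, default_spectrum, mode = "poisson", seed = 3)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0) && all(s1$counts == round(s1$counts)))
  # beamstop pixels record nothing
  mask <- pixel_angle_map(default_geom)$mask
  expect_true(all(s1$counts[!mask] == 0))
  # noiseless counts scale linearly with exposure
  a <- simulate_stack(ph, default_geom, default_spectrum, 300, mode = "noiseless")
  b <- simulate_stack(ph, default_geom, default_spectrum, 600, mode = "noiseless")
  expect_equal(b$counts, 2 * a$counts)
})

test_that("noiseless stack with constant S and flat spectrum is flat after the geometry factor", {
  flat <- structure(list(photons_per_bin = rep(1e6, 44),
                         energy = energy_grid()$centers, tube_voltage = 50,
                         grid = energy_grid()), class = "source_spectrum")
  ph <- phantom(scattering_model(list(power_law_background(1, slope = 0))),
                thickness = 5, mu_30 = 0)
  st <- simulate_stack(ph, default_geom, flat, mode = "noiseless")
  omega <- solid_angle_map(default_geom)
  mask <- pixel_angle_map(default_geom)$mask
  norm <- st$counts[, , 10][mask] / omega[mask]
  expect_lt(diff(range(norm)) / mean(norm), 1e-12)
})

test_that("transmission scan realizes Beer-Lambert attenuation", {
  sp <- default_spectrum
  ph0 <- phantom(scattering_model(list(power_law_background(1))),
                 thickness = 10, mu_30 = 0)
  t0 <- simulate_transmission(ph0, sp)
  expect_equal(t0$with_sample, t0$without_sample)
  ph <- make_brain_phantom(0, thickness = 10)
  tr <- simulate_transmission(ph, sp)
  pos <- tr$without_sample > 0
  expect_equal((tr$with_sample / tr$without_sample)[pos],
               exp(-attenuation(ph, sp$grid$centers) * 10)[pos])
  # doubling the thickness squares the transmission ratio
  tr2 <- simulate_transmission(make_brain_phantom(0, thickness = 20), sp)
  expect_equal((tr2$with_sample / tr2$without_sample)[pos],
               ((tr$with_sample / tr$without_sample)^2)[pos])
})
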