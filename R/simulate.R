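# Forward simulator of the spectral SAXS bench: polychromatic source,
# per-pixel scattering means via the transmission-weighted cross-section
# model, Poisson counting noise, and transmission (primary-beam) scans.

#' Bremsstrahlung source spectrum (Kramers model)
#'
#' Unfiltered tungsten-anode bremsstrahlung shape per energy bin,
#' proportional to `(kVp - E) / E` below the tube voltage and zero above,
#' optionally multiplied by a filtration transmission curve.  The amplitude
#' is expressed as photons per energy bin per mAs of exposure; the default
#' scale gives count rates typical of a benchtop system (tens of counts per
#' pixel per bin for a 10-mm tissue sample at 600 mAs).
#'
#' @param tube_voltage Tube voltage, kVp.
#' @param grid An [energy_grid()]; the spectrum is evaluated at bin centres.
#' @param filtration Optional function of energy (keV) returning a
#'   transmission factor in `[0, 1]`.
#' @param photons_per_mas Amplitude scale, photons per bin per mAs at
#'   `(kVp - E)/E = 1`.
#' @return Object of class `source_spectrum` with `photons_per_bin` (per
#'   mAs), `energy` (bin centres) and `tube_voltage`.
#' @export
kramers_spectrum <- function(tube_voltage = 50, grid = energy_grid(),
                             filtration = NULL, photons_per_mas = 1.4e4) {
  if (tube_voltage <= 0) stop("tube_voltage must be positive")
  e <- grid$centers
  n <- pmax(0, (tube_voltage - e) / e) * photons_per_mas
  if (!is.null(filtration)) n <- n * filtration(e)
  if (any(n < 0)) stop("filtration must not produce negative intensities")
  structure(list(photons_per_bin = n, energy = e,
                 tube_voltage = tube_voltage, grid = grid),
            class = "source_spectrum")
}

# per-pixel per-bin mean counts for a phantom in the beam
.stack_means <- function(ph, geometry, spectrum, exposure_mas) {
  grid <- spectrum$grid
  am <- pixel_angle_map(geometry)
  omega <- solid_angle_map(geometry)
  ne <- length(grid$centers)
  lam <- array(0, dim = c(geometry$n_pixels_x, geometry$n_pixels_y, ne))
  trans <- exp(-attenuation(ph, grid$centers) * ph$thickness)
  for (k in seq_len(ne)) {
    q <- q_of(grid$centers[k], am$theta)
    s <- s_of_q(ph$scattering_model, q)
    lk <- spectrum$photons_per_bin[k] * exposure_mas * trans[k] *
      s * ph$thickness * omega
    lk[!am$mask] <- 0  # beamstop shadow
    lam[, , k] <- lk
  }
  lam
}

#' Simulate a spectroscopic detector stack
#'
#' Forward model of one acquisition: the per-pixel per-bin mean is
#' `spectrum(E) * exposure * exp(-mu(E) T) * S(q(i,j,E)) * T * omega(i,j)`
#' where `T` is the sample thickness and `omega` the pixel solid angle.
#' Beamstop-shadowed pixels record zero.  In `"poisson"` mode counts are
#' integer Poisson draws (a seed is required, so every stack is reproducible
#' bit for bit); in `"noiseless"` mode the exact real-valued means are
#' returned, which is the oracle used by the reduction round-trip tests.
#'
#' @param phantom A [phantom()].
#' @param geometry An [instrument_geometry()].
#' @param spectrum A [kramers_spectrum()] (or compatible) source spectrum.
#' @param exposure Exposure in mAs (time x tube current); default 600
#'   (300 s at 2 mA).
#' @param mode `"poisson"` or `"noiseless"`.
#' @param seed Integer RNG seed; mandatory in `"poisson"` mode.
#' @return Object of class `detector_stack`: `counts` (x-pixels x y-pixels x
#'   energy bins), `energy_grid`, and `metadata` (geometry, exposure,
#'   phantom id, thickness, mode, seed).
#' @export
simulate_stack <- function(phantom, geometry = instrument_geometry(),
                           spectrum = kramers_spectrum(),
                           exposure = 600,
                           mode = c("poisson", "noiseless"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "phantom"), exposure >= 0)
  if (mode == "poisson" && is.null(seed))
    stop("poisson mode requires a seed (reproducibility contract)")
  lam <- .stack_means(phantom, geometry, spectrum, exposure)
  counts <- if (mode == "poisson") {
    set.seed(seed)
    array(stats::rpois(length(lam), lam), dim = dim(lam))
  } else lam
  structure(list(
    counts = counts,
    energy_grid = spectrum$grid,
    metadata = list(geometry = geometry, exposure = exposure,
                    phantom_id = phantom$id, thickness = phantom$thickness,
                    plaque_density = phantom$plaque_density,
                    mode = mode, seed = seed)
  ), class = "detector_stack")
}

#' @export
print.detector_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<detector_stack> %d x %d px x %d energy bins, %.4g counts total (%s)\n",
              d[1], d[2], d[3], sum(x$counts), x$metadata$mode))
  invisible(x)
}

#' Simulate a transmission (primary-beam) scan
#'
#' Spectroscopic measurement of the primary beam with and without the sample
#' in place, acquired without the beamstop at a reduced tube current.  In
#' the noiseless limit the with/without ratio per bin equals the
#' Beer-Lambert factor `exp(-mu(E) T)`.
#'
#' @inheritParams simulate_stack
#' @param exposure Exposure in mAs; default 12 (60 s at 0.2 mA).
#' @param beam_area_factor Effective number of pixel solid angles collected
#'   by the open primary beam (sets the count scale only).
#' @return Object of class `transmission_scan` with `with_sample` and
#'   `without_sample` counts per energy bin, plus the energy grid.
#' @export
simulate_transmission <- function(phantom, spectrum = kramers_spectrum(),
                                  exposure = 12, beam_area_factor = 50,
                                  mode = c("noiseless", "poisson"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "phantom"), exposure >= 0)
  grid <- spectrum$grid
  without <- spectrum$photons_per_bin * exposure * beam_area_factor
  withs <- without * exp(-attenuation(phantom, grid$centers) * phantom$thickness)
  if (mode == "poisson") {
    if (is.null(seed)) stop("poisson mode requires a seed")
    set.seed(seed)
    without <- stats::rpois(length(without), without)
    withs <- stats::rpois(length(withs), withs)
  }
  structure(list(with_sample = withs, without_sample = without,
                 energy_grid = grid,
                 metadata = list(exposure = exposure, mode = mode,
                                 phantom_id = phantom$id, seed = seed)),
            class = "transmission_scan")
}
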