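# Instrument geometry and the pixel -> scattering angle -> momentum transfer
# mapping.  All lengths are in mm, energies in keV, momentum transfer in nm^-1.

#' hc constant used in the momentum-transfer relation, in keV nm
#' @keywords internal
.hc_keV_nm <- 1.24

#' Instrument geometry of the spectral SAXS bench
#'
#' Describes the detector and beam geometry needed to map detector pixels to
#' scattering angles: an 80 x 80 photon-counting array with 250-um pixels at
#' a sample-to-detector distance (SDD) of 214 mm, a dual-pinhole collimator,
#' and a circular beamstop that blocks the unscattered primary beam.
#'
#' Pixel centres sit at `(i + 0.5) * pixel_pitch` mm for 0-based index `i`,
#' so the detector occupies `[0, n * pitch]` mm in each direction.  The beam
#' centre is given in the same mm coordinates and defaults to the array
#' corner `(0, 0)`: with a centred beam the largest reachable radius (~14 mm)
#' cannot cover the analyzed momentum-transfer range up to 28 nm^-1, whereas
#' the corner placement reaches ~28 mm along the diagonal.  The default
#' beamstop radius of 1.83 mm puts the 30-keV momentum transfer at the
#' beamstop edge at 1.3 nm^-1, the lower edge of the analyzed q range.
#'
#' @param n_pixels_x,n_pixels_y Detector size in pixels.
#' @param pixel_pitch Pixel pitch in mm.
#' @param sdd Sample-to-detector distance in mm.
#' @param beam_center Numeric length-2, beam position in the detector plane
#'   (mm); may lie at or beyond the array edge.
#' @param beamstop_radius Beamstop radius in mm (pixels with radius <= this
#'   are masked out of the analysis).
#' @param pinhole_diameters Diameters of the two collimating pinholes, mm.
#' @param pinhole_separation Distance between the pinholes, mm.
#' @return An object of class `instrument_geometry`.
#' @examples
#' geom <- instrument_geometry()
#' am <- pixel_angle_map(geom)
#' range(am$theta[am$mask])
#' @export
instrument_geometry <- function(n_pixels_x = 80L, n_pixels_y = 80L,
                                pixel_pitch = 0.25, sdd = 214,
                                beam_center = c(0, 0),
                                beamstop_radius = 1.83,
                                pinhole_diameters = c(2.5, 1.0),
                                pinhole_separation = 160) {
  stopifnot(n_pixels_x >= 1, n_pixels_y >= 1,
            length(beam_center) == 2, is.numeric(beam_center))
  if (sdd <= 0) stop("sdd must be positive")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  if (beamstop_radius < 0) stop("beamstop_radius must be non-negative")
  geom <- structure(list(
    n_pixels_x = as.integer(n_pixels_x), n_pixels_y = as.integer(n_pixels_y),
    pixel_pitch = pixel_pitch, sdd = sdd,
    beam_center = as.numeric(beam_center),
    beamstop_radius = beamstop_radius,
    pinhole_diameters = pinhole_diameters,
    pinhole_separation = pinhole_separation
  ), class = "instrument_geometry")
  # small-angle regime: every pixel must see the sample below 2-theta = 10 deg
  r_max <- max(.pixel_radius(geom))
  if (atan(r_max / sdd) >= 10 * pi / 180)
    stop("geometry violates the small-angle design: a pixel sees 2-theta >= 10 degrees")
  geom
}

#' @export
print.instrument_geometry <- function(x, ...) {
  cat(sprintf("<instrument_geometry> %d x %d px @ %.3g mm, SDD %.5g mm\n",
              x$n_pixels_x, x$n_pixels_y, x$pixel_pitch, x$sdd))
  cat(sprintf("  beam centre (%.3g, %.3g) mm, beamstop radius %.3g mm\n",
              x$beam_center[1], x$beam_center[2], x$beamstop_radius))
  invisible(x)
}

# radial distance (mm) of each pixel centre from the beam centre
.pixel_radius <- function(geom) {
  cx <- (seq_len(geom$n_pixels_x) - 0.5) * geom$pixel_pitch
  cy <- (seq_len(geom$n_pixels_y) - 0.5) * geom$pixel_pitch
  dx <- cx - geom$beam_center[1]
  dy <- cy - geom$beam_center[2]
  sqrt(outer(dx^2, dy^2, `+`))
}

#' Per-pixel scattering half-angle map and analysis mask
#'
#' For a pixel centre at radial distance `r` from the beam centre, the full
#' scattering angle is `2 * theta = arctan(r / sdd)` (evaluated exactly; no
#' small-angle approximation).  Pixels with `r <= beamstop_radius` are
#' shadowed by the beamstop and excluded from the analysis mask.
#'
#' @param geometry An [instrument_geometry()].
#' @return A list with `theta` (matrix of half-angles, radians), `r` (radii,
#'   mm) and `mask` (logical matrix, `TRUE` for analyzable pixels).
#' @export
pixel_angle_map <- function(geometry) {
  stopifnot(inherits(geometry, "instrument_geometry"))
  r <- .pixel_radius(geometry)
  theta <- atan(r / geometry$sdd) / 2
  mask <- r > geometry$beamstop_radius
  list(theta = theta, r = r, mask = mask)
}

#' Momentum transfer from photon energy and scattering half-angle
#'
#' `q = 4 pi E sin(theta) / hc` with `hc = 1.24 keV nm`, giving q in nm^-1
#' for E in keV.  Strictly increasing in both energy and half-angle.
#'
#' @param energy Photon energy in keV (scalar or vector).
#' @param theta Scattering half-angle in radians, in `[0, pi/2)`.
#' @return Momentum transfer in nm^-1 (recycled to the common length).
#' @examples
#' q_of(30, 0.5 * atan(1.83 / 214))  # lower edge of the analyzed q range
#' @export
q_of <- function(energy, theta) {
  if (any(energy <= 0)) stop("energy must be positive")
  if (any(theta < 0) || any(theta >= pi / 2)) stop("theta must be in [0, pi/2)")
  4 * pi * energy * sin(theta) / .hc_keV_nm
}

#' Per-pixel momentum-transfer map at one photon energy
#'
#' Composes [pixel_angle_map()] and [q_of()]; pixels under the beamstop (or
#' otherwise masked) carry `NA`.
#'
#' @inheritParams pixel_angle_map
#' @param energy Photon energy in keV.
#' @return Matrix of q values (nm^-1) with `NA` at masked pixels.
#' @export
pixel_q_map <- function(geometry, energy) {
  am <- pixel_angle_map(geometry)
  q <- q_of(energy, am$theta)
  q[!am$mask] <- NA_real_
  q
}

#' Per-pixel solid-angle factor
#'
#' Plain solid angle subtended by a pixel at the sample,
#' `(pitch^2 / sdd^2) * cos^3(2 theta)`; used by the forward simulator as the
#' per-pixel geometry factor (no polarization or oblique-incidence terms).
#'
#' @inheritParams pixel_angle_map
#' @return Matrix of solid angles (steradian).
#' @export
solid_angle_map <- function(geometry) {
  am <- pixel_angle_map(geometry)
  (geometry$pixel_pitch^2 / geometry$sdd^2) * cos(2 * am$theta)^3
}

#' Energy grid of the spectroscopic detector
#'
#' @param bin_edges Strictly increasing energy bin edges in keV; default
#'   1-keV bins spanning 6-50 keV.
#' @param analysis_band Length-2 energy band (keV) used in the reduction;
#'   default 30-45 keV.
#' @return An object of class `energy_grid` with `bin_edges`, `centers`,
#'   `analysis_band`.
#' @export
energy_grid <- function(bin_edges = 6:50, analysis_band = c(30, 45)) {
  bin_edges <- as.numeric(bin_edges)
  if (any(diff(bin_edges) <= 0)) stop("energy bin edges must be strictly increasing")
  if (analysis_band[1] < min(bin_edges) || analysis_band[2] > max(bin_edges))
    stop("analysis_band must lie within the recorded energy range")
  structure(list(
    bin_edges = bin_edges,
    centers = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
    analysis_band = as.numeric(analysis_band)
  ), class = "energy_grid")
}

#' Momentum-transfer grid
#'
#' Uniform q bins; the default grid uses the 1.2 nm^-1 bin width over
#' 1.3-27.7 nm^-1 (22 bins within the analyzable 1.3-28 nm^-1 range), and
#' the amyloid-sensitive integration window 3.6-8.4 nm^-1.
#'
#' @param bin_edges Uniformly spaced q bin edges, nm^-1.
#' @param aup_window Length-2 window (nm^-1) for the area-under-peak burden
#'   statistic.
#' @return An object of class `q_grid` with `bin_edges`, `centers`,
#'   `bin_width`, `aup_window`.
#' @export
q_grid <- function(bin_edges = seq(1.3, 27.7, by = 1.2),
                   aup_window = c(3.6, 8.4)) {
  bin_edges <- as.numeric(bin_edges)
  w <- diff(bin_edges)
  if (length(w) < 1 || any(w <= 0)) stop("q bin edges must be strictly increasing")
  if (diff(range(w)) > 1e-9 * mean(w)) stop("q bins must be uniform")
  structure(list(
    bin_edges = bin_edges,
    centers = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
    bin_width = mean(w),
    aup_window = as.numeric(aup_window)
  ), class = "q_grid")
}
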