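# Reduction chain: transmission correction -> per-energy q binning ->
# energy summation.  Counts in, relative scattering cross-section S(q) out.

#' Transmission-correct a detector stack
#'
#' Divides the scattered counts in every pixel by the transmitted primary
#' counts in the same energy bin, `corrected(i,j,E) = Ns(i,j,E) / Nt(E)`,
#' removing the source spectrum, sample attenuation and detector response in
#' one step.  The primary beam is a single spot, so the normalizer is a
#' per-energy scalar broadcast over pixels (per-pixel flat fielding is out
#' of scope).  The result is additionally divided by the sample thickness
#' recorded in the stack metadata, so that corrected data estimate the
#' cross-section per unit path length and samples differing only in
#' thickness reduce to identical profiles.
#'
#' Counting uncertainty is propagated as `sqrt(Ns) / (Nt * T)`.  Energy bins
#' whose normalizer is zero or negative inside the analysis band are flagged
#' `NA` with a warning — the transmission scan has insufficient statistics
#' there.
#'
#' @param stack A `detector_stack`.
#' @param scan A `transmission_scan` on the same energy grid.
#' @param thickness Path length (mm) used for normalization; defaults to the
#'   stack metadata value, or 1 when absent.
#' @return Object of class `corrected_stack` with real-valued `values` and
#'   `sd` arrays, the energy grid and the inherited metadata.
#' @export
transmission_correct <- function(stack, scan,
                                 thickness = NULL) {
  stopifnot(inherits(stack, "detector_stack"),
            inherits(scan, "transmission_scan"))
  if (!isTRUE(all.equal(stack$energy_grid$bin_edges, scan$energy_grid$bin_edges)))
    stop("energy grids of stack and transmission scan do not match")
  if (is.null(thickness))
    thickness <- if (!is.null(stack$metadata$thickness)) stack$metadata$thickness else 1
  grid <- stack$energy_grid
  nt <- as.numeric(scan$with_sample)
  bad <- nt <= 0
  band <- grid$analysis_band
  in_band <- grid$centers >= band[1] & grid$centers <= band[2]
  if (any(bad & in_band))
    warning(sprintf("%d analysis energy bin(s) have non-positive primary counts; excluded",
                    sum(bad & in_band)))
  ntq <- nt * thickness
  ntq[bad] <- NA_real_
  values <- sweep(stack$counts, 3, ntq, `/`)
  sdv <- sweep(sqrt(pmax(stack$counts, 0)), 3, ntq, `/`)
  structure(list(values = values, sd = sdv, energy_grid = grid,
                 metadata = c(stack$metadata, list(normalized_thickness = thickness))),
            class = "corrected_stack")
}

#' Bin a corrected stack into momentum-transfer bins per energy bin
#'
#' For every energy bin inside the analysis band, pixels are assigned to q
#' bins through the per-pixel q map at that bin's centre energy, and the
#' corrected values of the contributing (unmasked) pixels are averaged —
#' the mean, not the sum, so the annular pixel-multiplicity pattern of the
#' detector does not imprint on the profile.  q-by-energy cells with no
#' contributing pixel are `NA` (missing), never zero.
#'
#' @param corrected A `corrected_stack` from [transmission_correct()].
#' @param geometry The [instrument_geometry()] of the acquisition (defaults
#'   to the one in the stack metadata).
#' @param grid A [q_grid()].
#' @return Object of class `spectral_profile`: matrices `s`, `sd`,
#'   `n_pixels` of size (q bins x analysis energy bins), `q_grid`,
#'   `energies` (bin centres), `energy_grid`.
#' @export
bin_to_q <- function(corrected, geometry = NULL, grid = q_grid()) {
  stopifnot(inherits(corrected, "corrected_stack"), inherits(grid, "q_grid"))
  if (is.null(geometry)) geometry <- corrected$metadata$geometry
  stopifnot(inherits(geometry, "instrument_geometry"))
  am <- pixel_angle_map(geometry)
  if (!any(am$mask)) stop("analysis mask is empty: no unmasked pixels")
  egrid <- corrected$energy_grid
  band <- egrid$analysis_band
  sel <- which(egrid$centers >= band[1] & egrid$centers <= band[2])
  nq <- length(grid$centers)
  s <- sdm <- matrix(NA_real_, nq, length(sel))
  npx <- matrix(0L, nq, length(sel))
  edges <- grid$bin_edges
  theta <- am$theta[am$mask]
  for (j in seq_along(sel)) {
    k <- sel[j]
    q <- q_of(egrid$centers[k], theta)
    idx <- findInterval(q, edges, rightmost.closed = FALSE)
    keep <- idx >= 1 & idx <= nq & q < edges[length(edges)]
    if (!any(keep)) next
    v <- corrected$values[, , k][am$mask][keep]
    vv <- corrected$sd[, , k][am$mask][keep]^2
    f <- factor(idx[keep], levels = seq_len(nq))
    n <- as.integer(table(f))
    sums <- as.numeric(rowsum(v, f, na.rm = FALSE))
    vars <- as.numeric(rowsum(vv, f, na.rm = FALSE))
    has <- n > 0
    s[has, j] <- sums[has] / n[has]
    sdm[has, j] <- sqrt(vars[has]) / n[has]
    npx[, j] <- n
  }
  structure(list(s = s, sd = sdm, n_pixels = npx, q_grid = grid,
                 energies = egrid$centers[sel], energy_grid = egrid,
                 metadata = corrected$metadata),
            class = "spectral_profile")
}

#' Sum a spectral profile over energy bins
#'
#' Cell-wise sum of S(q) over the energy bins inside the band, skipping
#' missing cells; per-bin uncertainties combine in quadrature.  q bins with
#' no contribution in any energy bin stay `NA`.
#'
#' @param spectral A `spectral_profile` from [bin_to_q()].
#' @param band Length-2 energy band in keV; default the grid's analysis
#'   band (30-45 keV).
#' @return Object of class `ssaxs_profile`: `s`, `sd`, `n_pixels` vectors
#'   over q bins, `q_grid`, `provenance`.
#' @export
sum_energy <- function(spectral, band = NULL) {
  stopifnot(inherits(spectral, "spectral_profile"))
  if (is.null(band)) band <- spectral$energy_grid$analysis_band
  sel <- spectral$energies >= band[1] & spectral$energies <= band[2]
  if (!any(sel)) stop("empty energy band")
  s <- apply(spectral$s[, sel, drop = FALSE], 1,
             function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))
  sdv <- apply(spectral$sd[, sel, drop = FALSE], 1,
               function(x) if (all(is.na(x))) NA_real_ else sqrt(sum(x^2, na.rm = TRUE)))
  structure(list(s = s, sd = sdv,
                 n_pixels = rowSums(spectral$n_pixels[, sel, drop = FALSE]),
                 q_grid = spectral$q_grid,
                 provenance = spectral$metadata["phantom_id"],
                 metadata = spectral$metadata),
            class = "ssaxs_profile")
}

#' @export
print.ssaxs_profile <- function(x, ...) {
  cat(sprintf("<ssaxs_profile> %d q bins over [%.3g, %.3g] nm^-1\n",
              length(x$s), min(x$q_grid$bin_edges), max(x$q_grid$bin_edges)))
  invisible(x)
}

#' Full reduction of one measurement
#'
#' Composition of [transmission_correct()], [bin_to_q()] and
#' [sum_energy()]: detector stack + transmission scan in, energy-summed
#' S(q) profile out.
#'
#' @inheritParams transmission_correct
#' @inheritParams bin_to_q
#' @param band Optional energy band override for the summation, keV.
#' @return An `ssaxs_profile`.
#' @export
reduce_stack <- function(stack, scan, geometry = NULL, grid = q_grid(),
                         band = NULL, thickness = NULL) {
  corrected <- transmission_correct(stack, scan, thickness = thickness)
  spectral <- bin_to_q(corrected, geometry = geometry, grid = grid)
  sum_energy(spectral, band = band)
}

#' Convert a profile to a data frame
#'
#' @param x An `ssaxs_profile`.
#' @param ... Unused.
#' @return data.frame with `q_center`, `s`, `s_sd`, `n_pixels`.
#' @export
as.data.frame.ssaxs_profile <- function(x, ...) {
  data.frame(q_center = x$q_grid$centers, s = x$s, s_sd = x$sd,
             n_pixels = x$n_pixels)
}
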