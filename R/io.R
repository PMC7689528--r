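# Plain-text serialization of detector stacks, transmission scans, profiles
# and result tables.  Every file carries a '#'-prefixed YAML metadata header
# (geometry, seeds, package version) so outputs are self-describing.

.meta_header <- function(meta) {
  meta$ssaxs_version <- as.character(utils::packageVersion("ssaxs"))
  y <- strsplit(yaml::as.yaml(meta), "\n")[[1]]
  paste0("# ", y)
}

.read_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- yaml::yaml.load(paste(sub("^# ", "", lines[hdr]), collapse = "\n"))
  list(meta = meta, body_start = if (length(hdr)) max(hdr) + 1 else 1)
}

.geometry_meta <- function(geom) {
  list(n_pixels_x = geom$n_pixels_x, n_pixels_y = geom$n_pixels_y,
       pixel_pitch = geom$pixel_pitch, sdd = geom$sdd,
       beam_center = geom$beam_center, beamstop_radius = geom$beamstop_radius,
       pinhole_diameters = geom$pinhole_diameters,
       pinhole_separation = geom$pinhole_separation)
}

#' Write / read a detector stack as plain text
#'
#' Format: a YAML metadata header in `#` comment lines (geometry, energy bin
#' edges, exposure, phantom id, seed), followed by a whitespace-separated
#' count matrix with one row per pixel (x fastest, 0-based order) and one
#' column per energy bin.
#'
#' @param stack A `detector_stack`.
#' @param path Output file path.
#' @return `write_stack` returns the path invisibly; `read_stack` a
#'   `detector_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "detector_stack"))
  md <- stack$metadata
  meta <- list(kind = "detector_stack",
               geometry = .geometry_meta(md$geometry),
               energy_edges = stack$energy_grid$bin_edges,
               analysis_band = stack$energy_grid$analysis_band,
               exposure = md$exposure, phantom_id = md$phantom_id,
               thickness = md$thickness, mode = md$mode, seed = md$seed)
  d <- dim(stack$counts)
  m <- matrix(stack$counts, d[1] * d[2], d[3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(meta), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  h <- .read_meta(path)
  meta <- h$meta
  stopifnot(identical(meta$kind, "detector_stack"))
  g <- meta$geometry
  geom <- instrument_geometry(g$n_pixels_x, g$n_pixels_y, g$pixel_pitch,
                              g$sdd, unlist(g$beam_center), g$beamstop_radius,
                              unlist(g$pinhole_diameters), g$pinhole_separation)
  egrid <- energy_grid(unlist(meta$energy_edges), unlist(meta$analysis_band))
  m <- as.matrix(utils::read.table(path, skip = h$body_start - 1))
  counts <- array(m, dim = c(g$n_pixels_x, g$n_pixels_y, ncol(m)))
  structure(list(counts = counts, energy_grid = egrid,
                 metadata = list(geometry = geom, exposure = meta$exposure,
                                 phantom_id = meta$phantom_id,
                                 thickness = meta$thickness,
                                 mode = meta$mode, seed = meta$seed)),
            class = "detector_stack")
}

#' Write / read a transmission scan as plain text
#'
#' @param scan A `transmission_scan`.
#' @param path File path.
#' @export
write_transmission <- function(scan, path) {
  stopifnot(inherits(scan, "transmission_scan"))
  meta <- list(kind = "transmission_scan",
               energy_edges = scan$energy_grid$bin_edges,
               analysis_band = scan$energy_grid$analysis_band,
               exposure = scan$metadata$exposure, mode = scan$metadata$mode,
               phantom_id = scan$metadata$phantom_id,
               seed = scan$metadata$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(meta), con)
  utils::write.table(
    data.frame(energy = scan$energy_grid$centers,
               with_sample = scan$with_sample,
               without_sample = scan$without_sample),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transmission
#' @export
read_transmission <- function(path) {
  h <- .read_meta(path)
  meta <- h$meta
  stopifnot(identical(meta$kind, "transmission_scan"))
  d <- utils::read.table(path, skip = h$body_start - 1, header = TRUE)
  structure(list(with_sample = d$with_sample,
                 without_sample = d$without_sample,
                 energy_grid = energy_grid(unlist(meta$energy_edges),
                                           unlist(meta$analysis_band)),
                 metadata = list(exposure = meta$exposure, mode = meta$mode,
                                 phantom_id = meta$phantom_id,
                                 seed = meta$seed)),
            class = "transmission_scan")
}

#' Write / read an energy-summed profile as CSV
#'
#' Columns `q_center`, `s`, `s_sd`, `n_pixels` after a `#`-prefixed YAML
#' metadata header.
#'
#' @param profile An `ssaxs_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ssaxs_profile"))
  meta <- list(kind = "ssaxs_profile",
               q_edges = profile$q_grid$bin_edges,
               aup_window = profile$q_grid$aup_window,
               provenance = profile$provenance)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(meta), con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  h <- .read_meta(path)
  meta <- h$meta
  stopifnot(identical(meta$kind, "ssaxs_profile"))
  d <- utils::read.csv(path, skip = h$body_start - 1, header = TRUE)
  qe <- unlist(meta$q_edges)
  structure(list(s = d$s, sd = d$s_sd, n_pixels = d$n_pixels,
                 q_grid = q_grid(qe, unlist(meta$aup_window)),
                 provenance = meta$provenance, metadata = meta),
            class = "ssaxs_profile")
}

#' Write a result table as CSV with a metadata header
#'
#' @param df A data.frame.
#' @param path File path.
#' @param meta Named list of provenance metadata.
#' @export
write_result_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(c(list(kind = "result_table"), meta)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
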