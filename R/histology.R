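# Synthetic Thioflavin-S fluorescence sections and the percent-area amyloid
# load quantification used as the reference standard.

#' Fluorescence image container
#'
#' @param intensity Non-negative numeric matrix (arbitrary fluorescence
#'   units).
#' @param pixel_size Pixel size in um.
#' @param metadata Optional list (animal, hemisphere, lateral distance...).
#' @return Object of class `fluorescence_image`.
#' @export
fluorescence_image <- function(intensity, pixel_size, metadata = list()) {
  stopifnot(is.matrix(intensity), pixel_size > 0)
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 metadata = metadata), class = "fluorescence_image")
}

#' Circular region of interest
#'
#' A circular ROI in physical (um) coordinates; the default 1-mm diameter
#' matches the X-ray beam so sSAXS and histology interrogate the same area.
#' A pixel belongs to the ROI when its centre lies inside the circle
#' (pixel centres at `(i + 0.5) * pixel_size` for 0-based index `i`).
#'
#' @param center Length-2 centre in um.
#' @param diameter Diameter in um (default 1000).
#' @return Object of class `circular_roi`.
#' @export
circular_roi <- function(center, diameter = 1000) {
  stopifnot(length(center) == 2, diameter > 0)
  structure(list(center = as.numeric(center), diameter = diameter),
            class = "circular_roi")
}

# lognormal disk-radius model shared by the generator and its oracle
.plaque_radius_moments <- function(meanlog, sdlog) {
  list(mean_r = exp(meanlog + sdlog^2 / 2),
       mean_area = pi * exp(2 * meanlog + 2 * sdlog^2))
}

#' Simulate a Thioflavin-S-like stained section
#'
#' Boolean-disk model of a plaque-bearing fluorescence section: a noisy
#' background field plus bright disks with Poisson-distributed count and
#' lognormal radii.  The disk-germ intensity is set to
#' `lambda = -log(1 - f) / E[disk area]` so the expected covered area
#' fraction inside any window equals the target `f` exactly, including the
#' overlap correction of the Boolean model.  The target fraction is coupled
#' to the burden scale as `f = load_slope * plaque_density / 100`, i.e. a
#' plaque density of 1 corresponds to an 8% amyloid load by default.
#'
#' @param plaque_density Dimensionless burden scalar (>= 0).
#' @param size Image size in pixels (length-2).
#' @param pixel_size Pixel size, um.
#' @param background Mean background fluorescence level.
#' @param background_sd Gaussian background noise sd.
#' @param plaque_intensity Added intensity inside plaques.
#' @param meanlog,sdlog Lognormal parameters of the plaque radius (um).
#' @param load_slope Percent area per unit plaque density (default 8).
#' @param seed Integer RNG seed (same seed, same image).
#' @return A [fluorescence_image()]; `metadata$target_fraction` records the
#'   expected covered fraction.
#' @export
simulate_section <- function(plaque_density, size = c(320, 320),
                             pixel_size = 4, background = 100,
                             background_sd = 5, plaque_intensity = 1000,
                             meanlog = log(15), sdlog = 0.3,
                             load_slope = 8, seed = NULL) {
  if (plaque_density < 0) stop("plaque_density must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  nx <- size[1]; ny <- size[2]
  img <- matrix(pmax(0, stats::rnorm(nx * ny, background, background_sd)),
                nx, ny)
  f <- load_slope * plaque_density / 100
  if (f >= 1) stop("plaque density implies full coverage; reduce it")
  if (f > 0) {
    mom <- .plaque_radius_moments(meanlog, sdlog)
    lambda <- -log(1 - f) / mom$mean_area          # germs per um^2
    margin <- stats::qlnorm(0.999, meanlog, sdlog)  # keep edge statistics stationary
    w <- nx * pixel_size + 2 * margin
    h <- ny * pixel_size + 2 * margin
    n_plaques <- stats::rpois(1, lambda * w * h)
    if (n_plaques > 0) {
      px <- stats::runif(n_plaques, -margin, nx * pixel_size + margin)
      py <- stats::runif(n_plaques, -margin, ny * pixel_size + margin)
      pr <- stats::rlnorm(n_plaques, meanlog, sdlog)
      cx <- (seq_len(nx) - 0.5) * pixel_size
      cy <- (seq_len(ny) - 0.5) * pixel_size
      covered <- matrix(FALSE, nx, ny)
      for (p in seq_len(n_plaques)) {
        ix <- which(abs(cx - px[p]) <= pr[p])
        iy <- which(abs(cy - py[p]) <= pr[p])
        if (!length(ix) || !length(iy)) next
        d2 <- outer((cx[ix] - px[p])^2, (cy[iy] - py[p])^2, `+`)
        covered[ix, iy] <- covered[ix, iy] | (d2 <= pr[p]^2)
      }
      img[covered] <- img[covered] + plaque_intensity
    }
  }
  fluorescence_image(img, pixel_size,
                     metadata = list(plaque_density = plaque_density,
                                     target_fraction = f, seed = seed))
}

# robust estimate of the plaque-free background pixels
.background_pixels <- function(intensity) {
  med <- stats::median(intensity)
  madv <- stats::mad(intensity)
  intensity <= med + 3 * max(madv, .Machine$double.eps)
}

#' Background-subtract a fluorescence image
#'
#' Shifts the image so that the mean of the plaque-free region equals the
#' given reference level, clipping negatives to zero — this matches average
#' pixel values across sections (e.g. wild-type vs diseased) in regions
#' without plaques before thresholding.  Plaque-free pixels are identified
#' robustly as those within 3 MAD of the median.
#'
#' @param image A [fluorescence_image()].
#' @param reference_level Target mean of the plaque-free region (>= 0).
#' @return A [fluorescence_image()].
#' @export
background_subtract <- function(image, reference_level = 0) {
  stopifnot(inherits(image, "fluorescence_image"), reference_level >= 0)
  bg <- .background_pixels(image$intensity)
  offset <- mean(image$intensity[bg]) - reference_level
  out <- pmax(image$intensity - offset, 0)
  fluorescence_image(out, image$pixel_size, image$metadata)
}

#' Default plaque threshold
#'
#' Mean + 3 sd of the plaque-free region — the package's documented default
#' for Thioflavin-S positivity; load values depend on this choice, and a
#' fixed threshold can be supplied instead wherever one is accepted.
#'
#' @param image A [fluorescence_image()] (after background subtraction).
#' @return Scalar threshold.
#' @export
default_threshold <- function(image) {
  bg <- .background_pixels(image$intensity)
  mean(image$intensity[bg]) + 3 * stats::sd(image$intensity[bg])
}

#' Percent area covered by plaques inside a circular ROI
#'
#' `100 * (# ROI pixels with intensity > threshold) / (# ROI pixels)`.
#'
#' @param image A [fluorescence_image()].
#' @param roi A [circular_roi()]; must lie fully inside the image.  `NULL`
#'   centres a 1-mm ROI on the image.
#' @param threshold Intensity threshold; `NULL` for [default_threshold()].
#' @return Percent area in `[0, 100]`.
#' @export
percent_area <- function(image, roi = NULL, threshold = NULL) {
  stopifnot(inherits(image, "fluorescence_image"))
  dims <- dim(image$intensity)
  if (is.null(roi))
    roi <- circular_roi(center = dims * image$pixel_size / 2)
  stopifnot(inherits(roi, "circular_roi"))
  rr <- roi$diameter / 2
  if (any(roi$center - rr < 0) ||
      any(roi$center + rr > dims * image$pixel_size))
    stop("ROI extends outside the image")
  if (is.null(threshold)) threshold <- default_threshold(image)
  cx <- (seq_len(dims[1]) - 0.5) * image$pixel_size
  cy <- (seq_len(dims[2]) - 0.5) * image$pixel_size
  inside <- outer((cx - roi$center[1])^2, (cy - roi$center[2])^2, `+`) <= rr^2
  vals <- image$intensity[inside]
  100 * sum(vals > threshold) / length(vals)
}

#' Amyloid load at one location from four brain slices
#'
#' Percent area per slice (two slices per hemisphere at 1 and 2 mm lateral
#' distance in the reference protocol), reported as the mean and sample sd
#' over the slices.  Fewer than four slices is allowed with a warning.
#'
#' @param images List of [fluorescence_image()]s (ideally 4).
#' @param roi A [circular_roi()] or `NULL` (centred 1-mm circle).
#' @param threshold Scalar threshold or `NULL` (per-slice
#'   [default_threshold()]).
#' @return List with `per_slice` (percent per slice), `mean`, `sd`, `n`.
#' @export
load_per_location <- function(images, roi = NULL, threshold = NULL) {
  if (length(images) == 0) stop("need at least one slice image")
  if (length(images) != 4)
    warning(sprintf("expected 4 slices per location, got %d", length(images)))
  per <- vapply(images, percent_area, numeric(1), roi = roi,
                threshold = threshold)
  list(per_slice = unname(per), mean = mean(per),
       sd = if (length(per) > 1) stats::sd(per) else 0, n = length(per))
}

#' Read/write fluorescence images as 16-bit grayscale TIFF
#'
#' Intensities are scaled by `scale` into the 16-bit range on write and
#' unscaled on read.
#'
#' @param image A [fluorescence_image()].
#' @param path File path.
#' @param pixel_size Pixel size (um) to attach on read.
#' @param scale Intensity units per 16-bit full scale (default 65535, i.e.
#'   unit intensities map to the full range).
#' @return `write_tiff_image` returns the path; `read_tiff_image` a
#'   [fluorescence_image()].
#' @export
write_tiff_image <- function(image, path, scale = 65535) {
  stopifnot(inherits(image, "fluorescence_image"))
  m <- pmin(pmax(image$intensity / scale, 0), 1)
  tiff::writeTIFF(t(m), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_tiff_image
#' @export
read_tiff_image <- function(path, pixel_size, scale = 65535) {
  m <- tiff::readTIFF(path)
  fluorescence_image(t(m) * scale, pixel_size)
}
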