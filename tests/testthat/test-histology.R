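test_that("percent_area counts thresholded pixels inside the circular ROI", {
  blank <- fluorescence_image(matrix(0, 100, 100), pixel_size = 10)
  expect_equal(percent_area(blank, threshold = 50), 0)
  bright <- fluorescence_image(matrix(100, 100, 100), pixel_size = 10)
  expect_equal(percent_area(bright, threshold = 50), 100)
  # a centred disk of known radius against the rasterized pixel-count oracle
  n <- 200; px <- 5
  cx <- (seq_len(n) - 0.5) * px
  ctr <- c(500, 500); rad <- 180
  d2 <- outer((cx - ctr[1])^2, (cx - ctr[2])^2, `+`)
  img <- fluorescence_image(ifelse(d2 <= rad^2, 1000, 0), pixel_size = px)
  roi <- circular_roi(ctr, diameter = 800)
  inside <- d2 <= 400^2
  oracle <- 100 * sum(d2 <= rad^2 & inside) / sum(inside)
  expect_equal(percent_area(img, roi, threshold = 500), oracle)
  expect_error(percent_area(img, circular_roi(c(10, 10), 800), 500), "outside")
})

test_that("percent_area is monotone non-increasing in the threshold", {
  img <- simulate_section(0.8, seed = 21)
  ths <- seq(0, 1500, by = 100)
  pa <- vapply(ths, function(t) percent_area(img, threshold = t), numeric(1))
  expect_true(all(diff(pa) <= 0))
})

test_that("synthetic sections are reproducible and match the target area fraction", {
  a <- simulate_section(0.7, seed = 9)
  b <- simulate_section(0.7, seed = 9)
  expect_identical(a$intensity, b$intensity)
  # density 0: background only, load ~ 0 under a fixed threshold
  wt <- simulate_section(0, seed = 10)
  expect_equal(percent_area(wt, threshold = 500), 0)
  # Boolean-model bookkeeping: mean covered fraction over many sections
  # equals the analytic target within Monte Carlo error
  loads <- vapply(1:100, function(s)
    percent_area(simulate_section(0.5, seed = s), threshold = 500),
    numeric(1))
  truth <- 8 * 0.5  # load_slope * density, percent
  se <- sd(loads) / sqrt(length(loads))
  expect_lt(abs(mean(loads) - truth), 2 * max(se, 0.02 * truth))
})

test_that("background subtraction matches plaque-free means across sections", {
  img <- simulate_section(0.6, background = 140, seed = 31)
  ref <- 100
  out <- background_subtract(img, ref)
  bg <- ssaxs:::.background_pixels(out$intensity)
  expect_equal(mean(out$intensity[bg]), ref, tolerance = 0.02)
  # already at the reference: unchanged off plaques
  again <- background_subtract(out, ref)
  expect_equal(again$intensity[bg], out$intensity[bg], tolerance = 0.02)
  # a constant offset round-trips off the plaques
  shifted <- fluorescence_image(img$intensity + 50, img$pixel_size)
  rec <- background_subtract(shifted, ref)
  expect_equal(mean(rec$intensity[bg]), ref, tolerance = 0.02)
  # WT and AD pairs share the off-plaque mean after the operation
  wt <- background_subtract(simulate_section(0, background = 90, seed = 32), ref)
  ad <- background_subtract(simulate_section(1.0, background = 150, seed = 33), ref)
  bg_wt <- ssaxs:::.background_pixels(wt$intensity)
  bg_ad <- ssaxs:::.background_pixels(ad$intensity)
  expect_equal(mean(wt$intensity[bg_wt]), mean(ad$intensity[bg_ad]),
               tolerance = 0.02)
})

test_that("per-location load averages four slices with sample sd", {
  mk <- function(pct) {
    # image whose ROI percent area is exactly pct under threshold 500
    n <- 250; px <- 4
    cx <- (seq_len(n) - 0.5) * px
    ctr <- c(500, 500)
    d2 <- outer((cx - ctr[1])^2, (cx - ctr[2])^2, `+`)
    inside <- d2 <= 500^2
    idx <- which(inside)[seq_len(round(pct / 100 * sum(inside)))]
    m <- matrix(0, n, n); m[idx] <- 1000
    fluorescence_image(m, pixel_size = px)
  }
  roi <- circular_roi(c(500, 500), 1000)
  four <- lapply(c(0, 0, 2.8, 2.8), mk)
  lr <- load_per_location(four, roi, threshold = 500)
  expect_equal(lr$mean, 1.4, tolerance = 0.01)
  expect_equal(lr$sd, 1.6166, tolerance = 0.01)
  ident <- load_per_location(lapply(rep(2.8, 4), mk), roi, threshold = 500)
  expect_equal(ident$sd, 0)
  blank <- load_per_location(lapply(rep(0, 4), mk), roi, threshold = 500)
  expect_equal(c(blank$mean, blank$sd), c(0, 0))
  expect_warning(load_per_location(four[1:3], roi, threshold = 500), "4 slices")
  expect_error(load_per_location(list()), "at least one")
})

test_that("fluorescence images survive a 16-bit TIFF round trip", {
  img <- simulate_section(0.5, seed = 41)
  path <- tempfile(fileext = ".tiff")
  write_tiff_image(img, path)
  back <- read_tiff_image(path, pixel_size = img$pixel_size)
  expect_equal(dim(back$intensity), dim(img$intensity))
  # 16-bit quantization: at most one intensity step on the 65535 scale
  expect_lt(max(abs(back$intensity - img$intensity)), 1.001)
})
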