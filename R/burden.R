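# Amyloid-burden statistics: area under the cross-beta peak (AUP), the
# wild-type-normalized excess Delta-AUP, repeat summaries, peak detection
# and the correlation against histology.

#' Area under the peak (AUP)
#'
#' Trapezoidal integral of the energy-summed S(q) profile over the
#' amyloid-sensitive window (default 3.6-8.4 nm^-1, around the 6 nm^-1
#' inter-sheet reflection).  The profile is treated as piecewise linear
#' through the bin centres; window endpoints that fall between centres are
#' included by linear interpolation.  No baseline is subtracted: the
#' tissue background common to diseased and control animals cancels in the
#' wild-type-normalized Delta-AUP.
#'
#' @param profile An `ssaxs_profile` (or a list with `s` and a `q_grid`).
#' @param window Length-2 integration window, nm^-1; defaults to the
#'   profile's `aup_window`.
#' @return The area (relative cross-section x nm^-1).
#' @export
aup <- function(profile, window = NULL) {
  qc <- profile$q_grid$centers
  s <- profile$s
  if (is.null(window)) window <- profile$q_grid$aup_window
  if (window[1] >= window[2]) stop("window must be increasing")
  if (window[1] < min(qc) || window[2] > max(qc))
    stop("AUP window lies outside the q grid")
  ok <- !is.na(s)
  inner <- qc[ok][qc[ok] > window[1] & qc[ok] < window[2]]
  xs <- c(window[1], inner, window[2])
  ys <- stats::approx(qc[ok], s[ok], xout = xs)$y
  pracma::trapz(xs, ys)
}

#' Wild-type reference AUP
#'
#' Builds the reference mean AUP from the wild-type measurements of a study
#' table.  Default mode `"per_roi"`: the reference for each ROI is the mean
#' over all wild-type measurements at that (location-matched) ROI.  Mode
#' `"pooled"`: a single mean over all wild-type ROIs.
#'
#' @param aup_table data.frame with columns `animal`, `genotype`, `roi`,
#'   `aup` (one row per measurement).
#' @param mode `"per_roi"` or `"pooled"`.
#' @return Object of class `wt_reference`: named vector `mean_aup` (per ROI,
#'   or single element `"pooled"`), plus contributing animal ids.
#' @export
wt_reference <- function(aup_table, mode = c("per_roi", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(all(c("animal", "genotype", "roi", "aup") %in% names(aup_table)))
  wt <- aup_table[aup_table$genotype == "WT", , drop = FALSE]
  if (nrow(wt) == 0) stop("no wild-type rows to build a reference from")
  m <- if (mode == "per_roi") {
    c(tapply(wt$aup, wt$roi, mean))  # named vector, not a 1-d array
  } else c(pooled = mean(wt$aup))
  if (any(m <= 0)) stop("non-positive wild-type reference mean (corrupt WT set)")
  structure(list(mean_aup = m, mode = mode,
                 animals = unique(wt$animal)), class = "wt_reference")
}

#' Delta-AUP: fractional excess area over the wild-type reference
#'
#' `(AUP_i - mean(AUP_WT)) / mean(AUP_WT)`.  Zero is the theoretical
#' wild-type level; negative values (no amyloid signal) are allowed; the
#' maximum is unbounded.
#'
#' @param aup_i AUP of the measurement(s) under investigation (vector ok).
#' @param reference A `wt_reference`, or a positive scalar reference mean.
#' @param roi ROI label(s) used to pick the per-ROI reference (ignored for
#'   scalar or pooled references).
#' @return Delta-AUP fraction(s).
#' @export
delta_aup <- function(aup_i, reference, roi = NULL) {
  ref <- if (inherits(reference, "wt_reference")) {
    if (reference$mode == "pooled" || is.null(roi)) {
      rep(mean(reference$mean_aup), length(aup_i))
    } else {
      as.numeric(reference$mean_aup[as.character(roi)])
    }
  } else as.numeric(reference)
  if (any(!is.finite(ref)) ) stop("reference has no value for the given ROI")
  if (any(ref <= 0)) stop("wild-type reference mean must be positive")
  (aup_i - ref) / ref
}

#' Mean and standard deviation over repeated measurements
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-repeat values at one location; with a single repeat the sd is 0 and
#' a note is emitted.
#'
#' @param x Numeric vector of per-repeat values (length >= 1).
#' @return Named vector `c(mean, sd, n)`.
#' @export
summarize_repeats <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || any(is.na(x))) stop("need at least one non-missing repeat")
  s <- if (length(x) == 1) {
    message("single repeat: sd reported as 0")
    0
  } else stats::sd(x)
  c(mean = mean(x), sd = s, n = length(x))
}

#' Detect peaks in an S(q) profile
#'
#' Local maxima above a prominence floor, with the centroid refined by a
#' three-point parabolic fit through the maximum bin and its neighbours.
#' The default floor is 3x a robust noise scale estimated from successive
#' differences of the profile (`sd(diff(s)) / sqrt(2)`); the amyloid window
#' itself is fixed in this pipeline, so peak detection serves validation
#' (e.g. recovering the 6.04 and 13.24 nm^-1 BSA reflections).
#'
#' @param profile An `ssaxs_profile`.
#' @param prominence_floor Minimum peak prominence; `NULL` for the default.
#' @return data.frame with columns `q`, `height`, `prominence` (possibly
#'   zero rows).
#' @export
find_peaks <- function(profile, prominence_floor = NULL) {
  qc <- profile$q_grid$centers
  s <- profile$s
  ok <- !is.na(s)
  qc <- qc[ok]; s <- s[ok]
  if (length(s) < 3) stop("profile must have at least 3 points")
  if (is.null(prominence_floor)) {
    noise <- stats::sd(diff(s)) / sqrt(2)
    prominence_floor <- 3 * noise
  }
  empty <- data.frame(q = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (max(s) - min(s) <= 0) return(empty)
  pk <- pracma::findpeaks(s, minpeakheight = -Inf, nups = 1, ndowns = 1)
  if (is.null(pk)) return(empty)
  res <- lapply(seq_len(nrow(pk)), function(r) {
    i <- pk[r, 2]
    # prominence: height above the higher of the two flanking minima
    left <- if (i > 1) min(s[1:(i - 1)]) else s[i]
    right <- if (i < length(s)) min(s[(i + 1):length(s)]) else s[i]
    prom <- s[i] - max(left, right)
    if (prom < prominence_floor) return(NULL)
    # 3-point parabolic centroid refinement
    qhat <- qc[i]
    if (i > 1 && i < length(s)) {
      denom <- s[i - 1] - 2 * s[i] + s[i + 1]
      if (denom < 0) {
        dq <- (qc[i + 1] - qc[i - 1]) / 2
        qhat <- qc[i] + 0.5 * (s[i - 1] - s[i + 1]) / denom * dq
      }
    }
    data.frame(q = qhat, height = s[i], prominence = prom)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty else out[order(out$q), , drop = FALSE]
}

#' Pearson correlation between burden estimates and histology load
#'
#' Sample Pearson correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom (via [stats::cor.test()]).  With zero
#' variance in either variable the correlation is undefined and reported as
#' `NA`.
#'
#' @param delta_aups Numeric vector of Delta-AUP values.
#' @param histology_loads Paired, location-matched amyloid loads (percent).
#' @return List with `r`, `p`, `n`.
#' @export
correlate_burden <- function(delta_aups, histology_loads) {
  stopifnot(length(delta_aups) == length(histology_loads))
  if (length(delta_aups) < 3) stop("need at least 3 paired records")
  if (stats::sd(delta_aups) == 0 || stats::sd(histology_loads) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(delta_aups)))
  ct <- stats::cor.test(delta_aups, histology_loads, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(delta_aups))
}

#' Burden table from per-measurement AUP values
#'
#' Attaches Delta-AUP to every measurement using a wild-type reference built
#' from the same table, and summarizes repeats per animal x ROI.
#'
#' @param aup_table data.frame with columns `animal`, `genotype`, `roi`,
#'   `rep`, `aup`.
#' @param reference_mode Passed to [wt_reference()].
#' @return List with `measurements` (input + `delta_aup` column), `summary`
#'   (per animal x ROI: `delta_aup_mean`, `delta_aup_sd`, `n_repeats`), and
#'   the `reference`.
#' @export
burden_table <- function(aup_table, reference_mode = c("per_roi", "pooled")) {
  reference_mode <- match.arg(reference_mode)
  ref <- wt_reference(aup_table, mode = reference_mode)
  aup_table$delta_aup <- delta_aup(aup_table$aup, ref, roi = aup_table$roi)
  key <- interaction(aup_table$animal, aup_table$roi, drop = TRUE)
  summ <- do.call(rbind, lapply(split(aup_table, key), function(d) {
    s <- summarize_repeats(d$delta_aup)
    data.frame(animal = d$animal[1], genotype = d$genotype[1], roi = d$roi[1],
               aup_mean = mean(d$aup), delta_aup_mean = s[["mean"]],
               delta_aup_sd = s[["sd"]], n_repeats = as.integer(s[["n"]]))
  }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$animal, summ$roi), ]
  list(measurements = aup_table, summary = summ, reference = ref)
}
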