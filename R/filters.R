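# Conservative denoising cascade applied to detected peaks, in fixed order:
#   1. whole-TII rejection (uniformly noisy images),
#   2. local total-intensity rejection (Irect < lambda2 * sigma),
#   3. strip-region rejection (vertical / horizontal noise bands).
# DBSCAN's discarding of non-core noise pixels acts as an implicit zeroth
# filter upstream of this cascade. Each stage only removes peaks.

#' Filter parameters
#'
#' @param tii_nonzero_max_fraction Whole-image rejection: discard a TII (and
#'   all its peaks) when the nonzero-pixel fraction of the thresholded image
#'   strictly exceeds this value. Default 0.10.
#' @param lambda2 Local intensity rejection: discard peaks with
#'   `irect < lambda2 * sigma`. Default 100.
#' @param strip_ratio_thresholds Named list with elements `vertical` and
#'   `horizontal`: a peak is discarded when the nonzero-pixel ratio of the
#'   full-height column band (respectively full-width row band) centred on
#'   its apex strictly exceeds the threshold. Bands are one pixel dilated by
#'   `strip_band_halfwidth` on each side. Defaults 0.5; the originally
#'   calibrated per-region values are not public, so these are deliberately
#'   permissive and configurable.
#' @param strip_band_halfwidth Band half-width in pixels (default 5,
#'   matching the DBSCAN eps).
#' @return A `filter_params` list.
#' @export
filter_params <- function(tii_nonzero_max_fraction = 0.10, lambda2 = 100,
                          strip_ratio_thresholds = list(vertical = 0.5, horizontal = 0.5),
                          strip_band_halfwidth = 5) {
  if (!is.numeric(tii_nonzero_max_fraction) || tii_nonzero_max_fraction <= 0 ||
      tii_nonzero_max_fraction > 1) {
    stopf("tii_nonzero_max_fraction must be in (0, 1]")
  }
  if (!is.numeric(lambda2) || lambda2 <= 0) stopf("lambda2 must be positive")
  if (!is.list(strip_ratio_thresholds) ||
      !all(c("vertical", "horizontal") %in% names(strip_ratio_thresholds))) {
    stopf("strip_ratio_thresholds must name 'vertical' and 'horizontal'")
  }
  structure(list(tii_nonzero_max_fraction = tii_nonzero_max_fraction,
                 lambda2 = lambda2,
                 strip_ratio_thresholds = strip_ratio_thresholds,
                 strip_band_halfwidth = as.integer(strip_band_halfwidth)),
            class = "filter_params")
}

#' Whole-TII keep/discard decision
#'
#' An image whose thresholded nonzero-pixel fraction strictly exceeds the
#' configured maximum is treated as uniformly distributed noise and all its
#' peaks are discarded.
#'
#' @param grid A thresholded `tii_grid`.
#' @param params A [filter_params()] list.
#' @return TRUE to keep the TII, FALSE to discard it.
#' @export
filter_overall_tii <- function(grid, params = filter_params()) {
  stopifnot(inherits(grid, "tii_grid"))
  frac <- mean(grid$values > 0)
  frac <= params$tii_nonzero_max_fraction
}

#' Local total-intensity filter
#'
#' Keeps peaks with `irect >= lambda2 * sigma`, where sigma is the original
#' (pre-threshold) image standard deviation.
#'
#' @param peaks Peak table from [detect_peaks()].
#' @param sigma Image sigma of the peaks' TII.
#' @param lambda2 Multiplier (default 100).
#' @return The surviving subset of `peaks`.
#' @export
filter_local_intensity <- function(peaks, sigma, lambda2 = 100) {
  stopifnot(sigma >= 0, lambda2 > 0)
  peaks[peaks$irect >= lambda2 * sigma, ]
}

#' Strip-region filter
#'
#' Vertical and horizontal stripes of dense nonzero pixels on a TII are
#' instrument noise (e.g. column bleed). For each peak, the full-height
#' column band and full-width row band centred on its apex (half-width
#' `strip_band_halfwidth` pixels) are scored by their nonzero-pixel ratio;
#' the peak is discarded when either ratio strictly exceeds its configured
#' threshold.
#'
#' @param grid The thresholded `tii_grid` the peaks came from.
#' @param peaks Peak table from [detect_peaks()].
#' @param params A [filter_params()] list.
#' @return The surviving subset of `peaks`.
#' @export
filter_strip_regions <- function(grid, peaks, params = filter_params()) {
  stopifnot(inherits(grid, "tii_grid"))
  thr <- params$strip_ratio_thresholds
  if (is.null(thr$vertical) || is.null(thr$horizontal)) {
    stopf("strip_ratio_thresholds must provide 'vertical' and 'horizontal'")
  }
  if (nrow(peaks) == 0L) return(peaks)
  peaks[strip_keep_flags(grid, peaks, params), ]
}

# Logical keep-flag per peak for the strip filter; shared with the
# calibration grid search, which needs flags rather than a subset.
strip_keep_flags <- function(grid, peaks, params = filter_params()) {
  if (nrow(peaks) == 0L) return(logical(0))
  thr <- params$strip_ratio_thresholds
  v <- grid$values > 0
  hw <- params$strip_band_halfwidth
  nr <- nrow(v); nc <- ncol(v)
  apex_col <- snap_to_axis(peaks$apex_rt1, grid$rt1_axis[1L],
                           grid$rt1_axis[2L] - grid$rt1_axis[1L], nc)
  apex_row <- snap_to_axis(peaks$apex_rt2, grid$rt2_axis[1L],
                           grid$rt2_axis[2L] - grid$rt2_axis[1L], nr)
  vapply(seq_len(nrow(peaks)), function(i) {
    cset <- max(1L, apex_col[i] - hw):min(nc, apex_col[i] + hw)
    rset <- max(1L, apex_row[i] - hw):min(nr, apex_row[i] + hw)
    mean(v[, cset]) <= thr$vertical && mean(v[rset, ]) <= thr$horizontal
  }, logical(1))
}

#' Run the full denoising cascade for one TII
#'
#' @param grid The thresholded `tii_grid`.
#' @param peaks Peaks detected on `grid`.
#' @param sigma Original image sigma.
#' @param params A [filter_params()] list.
#' @return List with `peaks` (survivors) and `counts` (per-stage survivor
#'   counts, for the filter report).
#' @export
filter_cascade <- function(grid, peaks, sigma, params = filter_params()) {
  n0 <- nrow(peaks)
  if (!filter_overall_tii(grid, params)) {
    return(list(peaks = peaks[0L, ],
                counts = c(detected = n0, after_tii = 0L, after_irect = 0L,
                           after_strip = 0L)))
  }
  p1 <- filter_local_intensity(peaks, sigma, params$lambda2)
  p2 <- filter_strip_regions(grid, p1, params)
  list(peaks = p2,
       counts = c(detected = n0, after_tii = n0, after_irect = nrow(p1),
                  after_strip = nrow(p2)))
}
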