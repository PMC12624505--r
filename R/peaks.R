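# Peak detection on a TII: sigma-thresholding, density-based clustering of
# the surviving pixels (DBSCAN on integer pixel coordinates), bounding-box
# extraction, and recursive midpoint splitting of boxes that exceed the
# per-dimension retention-time limits.

#' Detection parameters
#'
#' @param lambda1 Threshold multiplier: pixels with intensity > lambda1 *
#'   sigma(TII) survive. Default 5.
#' @param dbscan_min_samples Minimum neighbourhood size (the point itself
#'   included) for a core pixel. Default 20.
#' @param dbscan_eps Neighbourhood radius in pixel units (Euclidean distance
#'   on (row, column) indices). Default 5.
#' @param split_rt1_max,split_rt2_max Maximum allowed bounding-box extent in
#'   seconds along RT1 (default 50) and RT2 (default 1); larger boxes are
#'   bisected recursively at the midpoint of the offending axis.
#' @return A `detection_params` list.
#' @export
detection_params <- function(lambda1 = 5, dbscan_min_samples = 20,
                             dbscan_eps = 5, split_rt1_max = 50,
                             split_rt2_max = 1) {
  p <- list(lambda1 = lambda1, dbscan_min_samples = as.integer(dbscan_min_samples),
            dbscan_eps = dbscan_eps, split_rt1_max = split_rt1_max,
            split_rt2_max = split_rt2_max)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L || x <= 0, logical(1)))) {
    stopf("all detection parameters must be single positive numbers")
  }
  structure(p, class = "detection_params")
}

#' Population standard deviation of a TII
#'
#' Computed over all grid cells, zeros included: real TIIs are dominated by
#' zero cells and the threshold is meant relative to the whole image.
#'
#' @param grid A `tii_grid`.
#' @return sigma in intensity units (0 for an all-zero grid).
#' @export
tii_sigma <- function(grid) {
  stopifnot(inherits(grid, "tii_grid"))
  v <- grid$values
  sqrt(mean((v - mean(v))^2))
}

#' Threshold a TII at lambda1 * sigma
#'
#' Pixels with intensity strictly greater than `lambda1 * sigma` are kept;
#' all others are set to zero. Idempotent for fixed `lambda1 * sigma`.
#'
#' @param grid A `tii_grid`.
#' @param lambda1 Threshold multiplier.
#' @param sigma Image standard deviation; defaults to [tii_sigma()] of `grid`.
#' @return The thresholded `tii_grid`.
#' @export
threshold_tii <- function(grid, lambda1, sigma = tii_sigma(grid)) {
  stopifnot(inherits(grid, "tii_grid"), sigma >= 0)
  v <- grid$values
  v[v <= lambda1 * sigma] <- 0
  grid$values <- v
  grid
}

# DBSCAN on integer pixel coordinates (rows of `coords`: row, col).
# Euclidean metric; a point's eps-neighbourhood includes itself, so a core
# point needs >= min_samples points (self included) within eps. Returns an
# integer label per point: 0 = noise, 1..k = cluster.
dbscan_pixels <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  # bucket pixels into cells of side eps; neighbours live in the 3x3 cell block
  cell_r <- coords[, 1L] %/% eps
  cell_c <- coords[, 2L] %/% eps
  key <- paste(cell_r, cell_c)
  buckets <- split(seq_len(n), key)
  eps2 <- eps * eps
  neighbours_of <- function(i) {
    r <- cell_r[i]; cc <- cell_c[i]
    cand_keys <- paste(rep((r - 1L):(r + 1L), each = 3L), (cc - 1L):(cc + 1L))
    cand <- unlist(buckets[cand_keys], use.names = FALSE)
    d2 <- (coords[cand, 1L] - coords[i, 1L])^2 + (coords[cand, 2L] - coords[i, 2L])^2
    cand[d2 <= eps2]
  }
  labels <- integer(n)           # 0 unassigned/noise
  visited <- logical(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours_of(i)
    if (length(nb) < min_samples) next      # noise (may be claimed later)
    k <- k + 1L
    labels[i] <- k
    queue <- setdiff(nb, i)
    while (length(queue) > 0L) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      if (labels[j] == 0L) labels[j] <- k   # border or core, claimed by k
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbours_of(j)
        if (length(nbj) >= min_samples) {
          queue <- c(queue, nbj[!visited[nbj] | labels[nbj] == 0L])
        }
      }
    }
  }
  labels
}

# Recursively bisect a pixel set whose bounding box exceeds the RT limits.
# Splits at the geometric midpoint of the offending axis (RT1 checked
# first); each half strictly shrinks, so recursion terminates. Returns a
# list of integer index vectors into the pixel set.
split_oversized <- function(rows, cols, rt1_axis, rt2_axis, rt1_max, rt2_max) {
  recurse <- function(idx) {
    r1 <- rt1_axis[cols[idx]]
    r2 <- rt2_axis[rows[idx]]
    w1 <- max(r1) - min(r1)
    w2 <- max(r2) - min(r2)
    if (w1 > rt1_max) {
      mid <- (max(r1) + min(r1)) / 2
      left <- idx[r1 <= mid]
      right <- idx[r1 > mid]
      return(c(recurse(left), recurse(right)))
    }
    if (w2 > rt2_max) {
      mid <- (max(r2) + min(r2)) / 2
      lower <- idx[r2 <= mid]
      upper <- idx[r2 > mid]
      return(c(recurse(lower), recurse(upper)))
    }
    list(idx)
  }
  recurse(seq_along(rows))
}

#' Detect peaks on a TII
#'
#' Thresholds the image at `lambda1 * sigma`, clusters surviving pixels with
#' DBSCAN (noise pixels discarded), recursively splits clusters whose
#' bounding boxes exceed the per-dimension RT limits, and reports one peak
#' per terminal cluster: its bounding rectangle, apex (maximum-intensity
#' pixel) and `irect`, the intensity sum over the rectangle on the
#' thresholded grid.
#'
#' @param grid A `tii_grid` (raw; thresholding is applied internally).
#' @param params A [detection_params()] list.
#' @param sigma Optional pre-computed image sigma (defaults to
#'   [tii_sigma()] of the raw grid).
#' @return data.table of peaks: sample_id, mz_bin, rt1_min/max, rt2_min/max,
#'   apex_rt1, apex_rt2, apex_intensity, irect, n_pixels.
#' @export
detect_peaks <- function(grid, params = detection_params(), sigma = tii_sigma(grid)) {
  stopifnot(inherits(grid, "tii_grid"), inherits(params, "detection_params"))
  thr <- threshold_tii(grid, params$lambda1, sigma)
  v <- thr$values
  nz <- which(v > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(empty_peak_table())

  labels <- dbscan_pixels(nz, params$dbscan_eps, params$dbscan_min_samples)
  out <- vector("list", 0L)
  for (k in seq_len(max(labels, 0L))) {
    sel <- which(labels == k)
    if (length(sel) == 0L) next
    rows <- nz[sel, 1L]
    cols <- nz[sel, 2L]
    parts <- split_oversized(rows, cols, thr$rt1_axis, thr$rt2_axis,
                             params$split_rt1_max, params$split_rt2_max)
    for (idx in parts) {
      pr <- rows[idx]; pc <- cols[idx]
      rmin <- min(pr); rmax <- max(pr)
      cmin <- min(pc); cmax <- max(pc)
      rect <- v[rmin:rmax, cmin:cmax, drop = FALSE]
      vals <- v[cbind(pr, pc)]
      apex <- idx[which.max(vals)]
      out[[length(out) + 1L]] <- data.table::data.table(
        sample_id = grid$sample_id, mz_bin = as.integer(grid$mz_bin),
        rt1_min = thr$rt1_axis[cmin], rt1_max = thr$rt1_axis[cmax],
        rt2_min = thr$rt2_axis[rmin], rt2_max = thr$rt2_axis[rmax],
        apex_rt1 = thr$rt1_axis[cols[apex]], apex_rt2 = thr$rt2_axis[rows[apex]],
        apex_intensity = max(vals), irect = sum(rect),
        n_pixels = length(idx))
    }
  }
  if (length(out) == 0L) return(empty_peak_table())
  res <- data.table::rbindlist(out)
  data.table::setorder(res, rt1_min, rt2_min)
  res
}

# zero-row peak table with the full column contract
empty_peak_table <- function() {
  data.table::data.table(
    sample_id = character(), mz_bin = integer(),
    rt1_min = numeric(), rt1_max = numeric(),
    rt2_min = numeric(), rt2_max = numeric(),
    apex_rt1 = numeric(), apex_rt2 = numeric(),
    apex_intensity = numeric(), irect = numeric(), n_pixels = integer())
}
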