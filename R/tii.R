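# Total ion images (TIIs): quantization of scans into integer m/z bins and
# accumulation onto a fixed (RT2 x RT1) grid, one image per (sample, bin).
#
# The grid is the same for every sample and bin: RT1 from 2200 s in 3.5 s
# steps, RT2 from 0 s in 8 ms steps. The inclusive RT1 range yields 2646
# columns; the instrument vendor reports 2643, a discrepancy that cannot be
# reproduced from the stated range and step. Nothing downstream depends on
# the exact column count, only on the spacing, so the full inclusive grid is
# used.

TII_RT1_ORIGIN <- 2200
TII_RT1_STEP   <- 3.5
TII_RT1_MAX    <- 11457.568
TII_RT2_ORIGIN <- 0
TII_RT2_STEP   <- 0.008
TII_RT2_MAX    <- 3.504
TII_MZ_BINS    <- 30:700

#' Fixed TII retention-time axes
#'
#' @return List with `rt1` (2646 points, 3.5 s spacing from 2200 s) and
#'   `rt2` (439 points, 8 ms spacing from 0 s), both in seconds.
#' @export
tii_axes <- function() {
  n1 <- floor((TII_RT1_MAX - TII_RT1_ORIGIN) / TII_RT1_STEP) + 1L
  n2 <- floor(TII_RT2_MAX / TII_RT2_STEP + 1e-9) + 1L
  list(rt1 = TII_RT1_ORIGIN + TII_RT1_STEP * (seq_len(n1) - 1L),
       rt2 = TII_RT2_ORIGIN + TII_RT2_STEP * (seq_len(n2) - 1L))
}

#' Quantize scans into one integer m/z bin
#'
#' Retains scans with m/z in the half-open window `[v - 0.5, v + 0.5)` for
#' bin value `v` and sums areas of scans sharing identical (RT1, RT2). The
#' half-open window makes adjacent bins a partition of the m/z axis, so no
#' scan is counted twice.
#'
#' @param raw A `raw_scan_table`.
#' @param mz_bin Integer bin value in 30..700.
#' @return data.table with columns `rt1`, `rt2`, `area` (summed); possibly
#'   zero rows.
#' @export
quantize_scans <- function(raw, mz_bin) {
  stopifnot(inherits(raw, "raw_scan_table"))
  if (!is_count(mz_bin) || mz_bin < min(TII_MZ_BINS) || mz_bin > max(TII_MZ_BINS)) {
    stopf("mz_bin must be an integer in [%d, %d]", min(TII_MZ_BINS), max(TII_MZ_BINS))
  }
  s <- raw$scans
  sel <- s[mz >= mz_bin - 0.5 & mz < mz_bin + 0.5]
  if (nrow(sel) == 0L) {
    return(data.table::data.table(rt1 = numeric(), rt2 = numeric(), area = numeric()))
  }
  sel[, .(area = sum(area)), by = .(rt1, rt2)]
}

# Low-level constructor; used by build_tii and by tests that need small
# non-standard grids.
new_tii <- function(values, rt1_axis, rt2_axis, sample_id = "synthetic", mz_bin = NA_integer_) {
  stopifnot(is.matrix(values),
            nrow(values) == length(rt2_axis),
            ncol(values) == length(rt1_axis))
  structure(list(sample_id = sample_id, mz_bin = mz_bin, values = values,
                 rt1_axis = rt1_axis, rt2_axis = rt2_axis),
            class = "tii_grid")
}

#' @export
print.tii_grid <- function(x, ...) {
  cat(sprintf("<tii_grid> sample %s, m/z bin %s: %d x %d (RT2 x RT1), %d nonzero cells\n",
              x$sample_id, x$mz_bin, nrow(x$values), ncol(x$values),
              sum(x$values > 0)))
  invisible(x)
}

#' Build a total ion image from quantized entries
#'
#' Snaps each (RT1, RT2) entry to the nearest fixed-axis point (ties toward
#' the lower index), accumulating areas that land in the same cell. Cells,
#' rows and columns with no entry are zero-imputed; entries outside the grid
#' are dropped with a warning.
#'
#' @param entries data.table from [quantize_scans()].
#' @param sample_id,mz_bin Identity of the image.
#' @return A `tii_grid`: 439 x 2646 intensity matrix (RT2 rows, RT1 columns)
#'   with axis metadata.
#' @export
build_tii <- function(entries, sample_id, mz_bin) {
  ax <- tii_axes()
  vals <- matrix(0, nrow = length(ax$rt2), ncol = length(ax$rt1))
  if (nrow(entries) > 0L) {
    col <- snap_to_axis(entries$rt1, TII_RT1_ORIGIN, TII_RT1_STEP, length(ax$rt1))
    row <- snap_to_axis(entries$rt2, TII_RT2_ORIGIN, TII_RT2_STEP, length(ax$rt2))
    ok <- !is.na(col) & !is.na(row)
    if (any(!ok)) {
      warnf("%s bin %s: dropped %d entries outside the fixed RT grid",
            sample_id, mz_bin, sum(!ok))
    }
    if (any(ok)) {
      lin <- (col[ok] - 1L) * length(ax$rt2) + row[ok]
      acc <- rowsum(entries$area[ok], group = lin)
      vals[as.integer(rownames(acc))] <- acc[, 1L]
    }
  }
  new_tii(vals, ax$rt1, ax$rt2, sample_id = sample_id, mz_bin = mz_bin)
}

#' Lazily materialized stack of TIIs for one sample
#'
#' One image per integer m/z bin (default 30..700, 671 bins). Quantized
#' entries are pre-split per bin at construction; grids are built on first
#' access through [tii_get()] so that the (mostly empty) full stack is never
#' held in memory at once.
#'
#' @param raw A `raw_scan_table`.
#' @param mz_bins Integer bins to cover (default the full 30..700 range).
#' @return A `tii_stack` with `$bins`, `$sample_id` and accessor [tii_get()].
#' @export
tii_stack <- function(raw, mz_bins = TII_MZ_BINS) {
  stopifnot(inherits(raw, "raw_scan_table"))
  mz_bins <- as.integer(mz_bins)
  s <- raw$scans
  # half-open windows [v-0.5, v+0.5) partition the axis: bin = round(mz)
  # with half-up rounding
  bin_of <- as.integer(floor(s$mz + 0.5))
  keep <- bin_of %in% mz_bins
  agg <- if (any(keep)) {
    data.table::data.table(bin = bin_of[keep], rt1 = s$rt1[keep],
                           rt2 = s$rt2[keep], area = s$area[keep])[
      , .(area = sum(area)), by = .(bin, rt1, rt2)]
  } else {
    data.table::data.table(bin = integer(), rt1 = numeric(),
                           rt2 = numeric(), area = numeric())
  }
  structure(list(sample_id = raw$sample_id, bins = mz_bins,
                 entries = split(agg, by = "bin", keep.by = FALSE)),
            class = "tii_stack")
}

#' Materialize one TII from a stack
#'
#' @param stack A `tii_stack`.
#' @param mz_bin Bin value covered by the stack.
#' @return A `tii_grid` (all-zero if the bin holds no scans).
#' @export
tii_get <- function(stack, mz_bin) {
  stopifnot(inherits(stack, "tii_stack"))
  if (!mz_bin %in% stack$bins) stopf("bin %s is not covered by this stack", mz_bin)
  entries <- stack$entries[[as.character(mz_bin)]] %||%
    data.table::data.table(rt1 = numeric(), rt2 = numeric(), area = numeric())
  build_tii(entries, stack$sample_id, as.integer(mz_bin))
}

#' Bins of a stack that contain at least one scan
#'
#' @param stack A `tii_stack`.
#' @return Integer vector of non-empty bins (sorted).
#' @export
tii_nonempty_bins <- function(stack) {
  stopifnot(inherits(stack, "tii_stack"))
  sort(as.integer(names(stack$entries)))
}
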