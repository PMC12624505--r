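# Automatic parameter calibration: grid search over (lambda1, lambda2)
# scored by recovery of an expert-verified reference compound list, and
# dispersion-based derivation of the retention-time clustering thresholds.

#' Construct a reference compound set
#'
#' @param df data.frame with one row per expected (compound, sample)
#'   presence: columns `name`, `mz_bin`, `sample_id`, `rt1`, `rt2`
#'   (expected apex retention times in seconds).
#' @return A `reference_set` (data.table).
#' @export
reference_set <- function(df) {
  req <- c("name", "mz_bin", "sample_id", "rt1", "rt2")
  if (!all(req %in% names(df))) {
    stopf("reference set needs columns: %s", paste(req, collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("reference set is empty")
  structure(data.table::as.data.table(df), class = c("reference_set", class(data.table::data.table())))
}

# Match each expected (compound, sample) presence to the surviving peak with
# the same m/z bin and apex within the tolerance window; several candidates
# resolve to the highest irect. Returns the reference table with matched
# apex columns (NA where unrecovered).
match_references <- function(refs, peaks, rt1_tol = 50, rt2_tol = 1) {
  refs <- data.table::as.data.table(refs)
  pk <- data.table::as.data.table(peaks)
  matched_rt1 <- rep(NA_real_, nrow(refs))
  matched_rt2 <- rep(NA_real_, nrow(refs))
  for (i in seq_len(nrow(refs))) {
    cand <- pk[pk$sample_id == refs$sample_id[i] & pk$mz_bin == refs$mz_bin[i] &
               abs(pk$apex_rt1 - refs$rt1[i]) <= rt1_tol &
               abs(pk$apex_rt2 - refs$rt2[i]) <= rt2_tol, ]
    if (nrow(cand) > 0L) {
      j <- which.max(cand$irect)
      matched_rt1[i] <- cand$apex_rt1[j]
      matched_rt2[i] <- cand$apex_rt2[j]
    }
  }
  refs$matched_rt1 <- matched_rt1
  refs$matched_rt2 <- matched_rt2
  refs
}

#' Reference-recovery accuracy of a peak table
#'
#' Fraction of expected (compound, sample) presences for which a surviving
#' peak exists with the same m/z bin and apex within the tolerance window
#' (defaults +/-50 s RT1, +/-1 s RT2).
#'
#' @param refs A [reference_set()].
#' @param peaks Surviving peak table (pooled over samples).
#' @param rt1_tol,rt2_tol Tolerance half-windows in seconds.
#' @return Recovery fraction in \[0, 1\].
#' @export
recovery_accuracy <- function(refs, peaks, rt1_tol = 50, rt2_tol = 1) {
  if (nrow(refs) == 0L) stopf("reference set is empty")
  m <- match_references(refs, peaks, rt1_tol, rt2_tol)
  mean(!is.na(m$matched_rt1))
}

#' Grid-search the (lambda1, lambda2) accuracy surface
#'
#' For every lambda1, peak detection runs once per (sample, m/z bin of a
#' reference compound); the lambda2 axis then only re-applies the Irect
#' filter, which makes the exhaustive 20 x 21 grid tractable. The whole-TII
#' and strip filters (lambda1-dependent only) are applied throughout. The
#' surface is deterministic.
#'
#' @param refs A [reference_set()].
#' @param raws Named list of `raw_scan_table`s covering the reference
#'   samples.
#' @param lambda1s,lambda2s Grid axes (defaults 1..20 and 1, 10, 20, ..., 200).
#' @param rt1_tol,rt2_tol Recovery tolerance half-windows in seconds.
#' @param filter_params_base [filter_params()] supplying the non-lambda2
#'   filter settings.
#' @return data.table with columns lambda1, lambda2, accuracy.
#' @export
calibration_surface <- function(refs, raws, lambda1s = 1:20,
                                lambda2s = c(1, seq(10, 200, by = 10)),
                                rt1_tol = 50, rt2_tol = 1,
                                filter_params_base = filter_params()) {
  if (nrow(refs) == 0L) stopf("reference set is empty")
  sample_ids <- unique(refs$sample_id)
  missing <- setdiff(sample_ids, names(raws))
  if (length(missing)) stopf("raw tables missing for sample(s): %s", paste(missing, collapse = ", "))
  bins_by_sample <- split(unique(data.table::as.data.table(refs)[, .(sample_id, mz_bin)]),
                          by = "sample_id")
  stacks <- lapply(raws[sample_ids], tii_stack)

  out <- vector("list", length(lambda1s))
  for (li in seq_along(lambda1s)) {
    l1 <- lambda1s[li]
    # per-peak record: irect, sigma, tii/strip keep flags
    recs <- vector("list", 0L)
    for (sid in sample_ids) {
      for (b in unique(bins_by_sample[[sid]]$mz_bin)) {
        grid <- tii_get(stacks[[sid]], b)
        sig <- tii_sigma(grid)
        dpar <- detection_params(lambda1 = l1)
        pk <- detect_peaks(grid, dpar, sigma = sig)
        if (nrow(pk) == 0L) next
        thr <- threshold_tii(grid, l1, sig)
        tii_keep <- filter_overall_tii(thr, filter_params_base)
        pk$sigma <- sig
        pk$base_keep <- tii_keep & strip_keep_flags(thr, pk, filter_params_base)
        recs[[length(recs) + 1L]] <- pk
      }
    }
    allpk <- if (length(recs)) data.table::rbindlist(recs) else NULL
    acc <- vapply(lambda2s, function(l2) {
      if (is.null(allpk)) return(0)
      surv <- allpk[allpk$base_keep & allpk$irect >= l2 * allpk$sigma, ]
      recovery_accuracy(refs, surv, rt1_tol, rt2_tol)
    }, numeric(1))
    out[[li]] <- data.table::data.table(lambda1 = l1, lambda2 = lambda2s, accuracy = acc)
  }
  data.table::rbindlist(out)
}

#' Select (lambda1*, lambda2*) from an accuracy surface
#'
#' Among grid cells with accuracy strictly greater than `min_accuracy`,
#' takes the largest lambda1 present (maximal noise rejection), then the
#' median of that lambda1's passing lambda2 values (lower of the two middle
#' values for even counts) to be neither too restrictive nor too permissive.
#'
#' @param surface data.table with columns lambda1, lambda2, accuracy.
#' @param min_accuracy Strict lower bound on accuracy (default 0.90).
#' @return List with `lambda1` and `lambda2`.
#' @export
select_params <- function(surface, min_accuracy = 0.90) {
  surface <- data.table::as.data.table(surface)
  pass <- surface[surface$accuracy > min_accuracy, ]
  if (nrow(pass) == 0L) {
    stopf("calibration failed: no (lambda1, lambda2) cell exceeds accuracy %.2f (best %.3f)",
          min_accuracy, max(surface$accuracy))
  }
  l1 <- max(pass$lambda1)
  l2s <- sort(pass$lambda2[pass$lambda1 == l1])
  l2 <- l2s[ceiling(length(l2s) / 2)]    # lower median for even counts
  list(lambda1 = l1, lambda2 = l2)
}

#' Derive the RT clustering thresholds from reference dispersions
#'
#' For each reference compound matched in at least two samples, the
#' dispersion is the max minus min of its matched apex RT1 (and RT2) across
#' samples. The thresholds are the maximum dispersion over compounds, RT1
#' rounded up to the whole second and RT2 rounded (half-even) to 0.1 s, with
#' floors of 1 s and 0.1 s for degenerate zero-dispersion input. Compounds
#' matched in fewer than two samples are excluded with a warning.
#'
#' @param refs A [reference_set()].
#' @param peaks Surviving peak table used for matching.
#' @param rt1_tol,rt2_tol Matching tolerance half-windows in seconds.
#' @return List with `rt1_thrsh` and `rt2_thrsh` in seconds.
#' @export
derive_rt_thresholds <- function(refs, peaks, rt1_tol = 50, rt2_tol = 1) {
  m <- match_references(refs, peaks, rt1_tol, rt2_tol)
  m <- m[!is.na(m$matched_rt1), ]
  counts <- table(m$name)
  few <- names(counts)[counts < 2L]
  if (length(few)) {
    warnf("excluding compound(s) matched in < 2 samples: %s", paste(few, collapse = ", "))
    m <- m[!m$name %in% few, ]
  }
  if (nrow(m) == 0L) stopf("no reference compound matched in >= 2 samples")
  disp <- m[, .(d1 = max(matched_rt1) - min(matched_rt1),
                d2 = max(matched_rt2) - min(matched_rt2)), by = "name"]
  list(rt1_thrsh = max(1, ceiling(max(disp$d1))),
       rt2_thrsh = max(0.1, round(max(disp$d2), 1)))
}
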