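# Cross-sample feature construction: filtered peaks sharing an m/z bin and
# proximal retention times are one feature (a proxy for one fragment-ion
# species), and features x samples form a binary presence/absence matrix.

#' Cluster filtered peaks into features
#'
#' Deterministic greedy clustering. Peaks are sorted by descending `irect`
#' (then rt1, rt2, sample_id as tie-breaks) so the most intense occurrence
#' of a compound defines the feature position. Each peak is compared to the
#' seed apex of every existing feature with the same m/z bin; it joins a
#' feature when both |dRT1| <= `rt1_thrsh` and |dRT2| <= `rt2_thrsh`. When
#' several features qualify, the one with the smallest combined normalized
#' distance (|dRT1|/rt1_thrsh + |dRT2|/rt2_thrsh, ties to the lower
#' feature id) wins; otherwise the peak seeds a new feature.
#'
#' @param all_peaks Peak table pooled over samples (needs columns sample_id,
#'   mz_bin, apex_rt1, apex_rt2, irect).
#' @param rt1_thrsh,rt2_thrsh Retention-time tolerances in seconds
#'   (defaults 50 and 0.8, the calibrated values).
#' @return A `feature_set`: list with `features` (data.table: feature_id,
#'   mz_bin, rt1_center, rt2_center, n_peaks) and `members` (data.table
#'   mapping feature_id to member peaks).
#' @export
cluster_peaks <- function(all_peaks, rt1_thrsh = 50, rt2_thrsh = 0.8) {
  stopifnot(rt1_thrsh > 0, rt2_thrsh > 0)
  pk <- data.table::as.data.table(all_peaks)
  req <- c("sample_id", "mz_bin", "apex_rt1", "apex_rt2", "irect")
  if (!all(req %in% names(pk))) {
    stopf("peak table must have columns: %s", paste(req, collapse = ", "))
  }
  if (nrow(pk) == 0L) {
    return(structure(list(
      features = data.table::data.table(feature_id = integer(), mz_bin = integer(),
                                        rt1_center = numeric(), rt2_center = numeric(),
                                        n_peaks = integer()),
      members = data.table::data.table(feature_id = integer(), sample_id = character(),
                                       mz_bin = integer(), apex_rt1 = numeric(),
                                       apex_rt2 = numeric(), irect = numeric()),
      rt1_thrsh = rt1_thrsh, rt2_thrsh = rt2_thrsh), class = "feature_set"))
  }
  ord <- order(-pk$irect, pk$apex_rt1, pk$apex_rt2, pk$sample_id)
  pk <- pk[ord]

  # seeds per m/z bin, grown in place
  seed_rt1 <- numeric(0); seed_rt2 <- numeric(0); seed_bin <- integer(0)
  assign <- integer(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    b <- pk$mz_bin[i]
    cand <- which(seed_bin == b &
                  abs(seed_rt1 - pk$apex_rt1[i]) <= rt1_thrsh &
                  abs(seed_rt2 - pk$apex_rt2[i]) <= rt2_thrsh)
    if (length(cand) == 0L) {
      seed_bin <- c(seed_bin, b)
      seed_rt1 <- c(seed_rt1, pk$apex_rt1[i])
      seed_rt2 <- c(seed_rt2, pk$apex_rt2[i])
      assign[i] <- length(seed_bin)
    } else {
      d <- abs(seed_rt1[cand] - pk$apex_rt1[i]) / rt1_thrsh +
           abs(seed_rt2[cand] - pk$apex_rt2[i]) / rt2_thrsh
      assign[i] <- cand[order(d, cand)[1L]]
    }
  }
  members <- data.table::data.table(feature_id = assign, pk)
  features <- members[, .(mz_bin = mz_bin[1L]), by = feature_id]
  features$rt1_center <- seed_rt1[features$feature_id]
  features$rt2_center <- seed_rt2[features$feature_id]
  features$n_peaks <- as.integer(table(assign)[as.character(features$feature_id)])
  data.table::setorder(features, feature_id)
  structure(list(features = features, members = members,
                 rt1_thrsh = rt1_thrsh, rt2_thrsh = rt2_thrsh),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features from %d peaks across %d samples\n",
              nrow(x$features), nrow(x$members),
              length(unique(x$members$sample_id))))
  invisible(x)
}

#' Build the binary presence/absence feature matrix
#'
#' @param fset A `feature_set` from [cluster_peaks()].
#' @param manifest A `sample_manifest`; every sample occurring in the
#'   features must be listed (columns follow the manifest order, so samples
#'   with no surviving peak get an all-zero column).
#' @return A `feature_matrix`: list with `matrix` (features x samples, 0/1),
#'   `features` (the feature index) and `labels` (named factor per column).
#' @export
build_matrix <- function(fset, manifest) {
  stopifnot(inherits(fset, "feature_set"))
  manifest <- as_sample_manifest(manifest)
  extra <- setdiff(unique(fset$members$sample_id), manifest$sample_id)
  if (length(extra)) {
    stopf("sample(s) in features but not in manifest: %s", paste(extra, collapse = ", "))
  }
  m <- matrix(0L, nrow = nrow(fset$features), ncol = nrow(manifest),
              dimnames = list(as.character(fset$features$feature_id),
                              manifest$sample_id))
  if (nrow(fset$members) > 0L) {
    ri <- match(fset$members$feature_id, fset$features$feature_id)
    ci <- match(fset$members$sample_id, manifest$sample_id)
    m[cbind(ri, ci)] <- 1L
  }
  labels <- stats::setNames(manifest$label, manifest$sample_id)
  structure(list(matrix = m, features = fset$features, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples (%d abiotic, %d biotic)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$labels == "abiotic"), sum(x$labels == "biotic")))
  invisible(x)
}
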