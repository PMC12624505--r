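# Feature groups: coefficient-ranked features collapsed across m/z by
# retention-time proximity. Coeluting fragment ions of one parent compound
# share (RT1, RT2) but differ in m/z, so a group is a proxy for one analyte.

#' Collapse coefficient-ranked features into feature groups
#'
#' Anchor-greedy procedure: repeatedly take the unassigned feature with the
#' highest absolute coefficient (ties to the lower feature id) as the
#' anchor/representative, gather every unassigned feature within
#' `rt1_thrsh` and `rt2_thrsh` of it regardless of m/z into one group, and
#' remove them. Chains are deliberately not merged transitively: membership
#' is always measured from the anchor. Groups are ranked by their
#' representative's |coefficient|.
#'
#' @param features data.frame with columns `feature_id`, `rt1_center`,
#'   `rt2_center`, `coefficient` (and any others, carried through).
#' @param rt1_thrsh,rt2_thrsh Proximity tolerances in seconds (defaults 50
#'   and 0.8).
#' @return A `feature_groups` object: data.table with one row per group
#'   (group_id = rank, representative feature columns, `n_members`) plus a
#'   `members` attribute mapping group_id to feature ids.
#' @export
group_features <- function(features, rt1_thrsh = 50, rt2_thrsh = 0.8) {
  f <- data.table::as.data.table(features)
  req <- c("feature_id", "rt1_center", "rt2_center", "coefficient")
  if (!all(req %in% names(f))) {
    stopf("features need columns: %s", paste(req, collapse = ", "))
  }
  n <- nrow(f)
  unassigned <- rep(TRUE, n)
  ord <- order(-abs(f$coefficient), f$feature_id)
  groups <- list(); members <- list()
  gid <- 0L
  for (i in ord) {
    if (!unassigned[i]) next
    gid <- gid + 1L
    near <- unassigned &
      abs(f$rt1_center - f$rt1_center[i]) <= rt1_thrsh &
      abs(f$rt2_center - f$rt2_center[i]) <= rt2_thrsh
    members[[gid]] <- f$feature_id[near]
    unassigned[near] <- FALSE
    groups[[gid]] <- data.table::data.table(
      group_id = gid,
      representative = f$feature_id[i],
      mz_bin = if ("mz_bin" %in% names(f)) f$mz_bin[i] else NA_integer_,
      rt1_center = f$rt1_center[i], rt2_center = f$rt2_center[i],
      coefficient = f$coefficient[i],
      direction = if (f$coefficient[i] >= 0) "abiotic" else "biotic",
      n_members = sum(near))
  }
  out <- data.table::rbindlist(groups)
  attr(out, "members") <- members
  class(out) <- c("feature_groups", class(out))
  out
}

#' Keep groups whose representative is shared across enough samples
#'
#' @param groups A `feature_groups` object.
#' @param fm The `feature_matrix` the coefficients came from.
#' @param min_samples Minimum number of samples containing the
#'   representative feature (default 2).
#' @return The surviving subset (members attribute subset accordingly),
#'   with a `n_samples_shared` column added.
#' @export
filter_shared_groups <- function(groups, fm, min_samples = 2L) {
  stopifnot(inherits(groups, "feature_groups"), inherits(fm, "feature_matrix"))
  counts <- rowSums(fm$matrix)
  shared <- counts[as.character(groups$representative)]
  keep <- !is.na(shared) & shared >= min_samples
  out <- groups[keep, ]
  out$n_samples_shared <- as.integer(shared[keep])
  attr(out, "members") <- attr(groups, "members")[groups$group_id[keep]]
  class(out) <- c("feature_groups", class(data.table::data.table()))
  out
}

#' Artifact-zeroing robustness check
#'
#' Sets the coefficients of every member feature of the flagged groups to
#' zero in a fitted linear classifier, re-scores all samples, and reports
#' the classification accuracy before and after. If the model does not rely
#' on the artifact features, the accuracy delta is zero.
#'
#' @param fitted A linear `fitted_classifier` (coefficients available).
#' @param groups The `feature_groups` the flags refer to.
#' @param artifact_group_ids Group ids to zero (may be empty).
#' @param fm The labelled `feature_matrix` to score.
#' @return List with `accuracy_before`, `accuracy_after`, `delta` and the
#'   `zeroed` feature ids.
#' @export
zero_artifact_groups <- function(fitted, groups, artifact_group_ids, fm) {
  stopifnot(inherits(fitted, "fitted_classifier"), inherits(fm, "feature_matrix"))
  if (is.null(fitted$coefficients)) {
    stopf("artifact zeroing needs a linear classifier with explicit coefficients")
  }
  unknown <- setdiff(artifact_group_ids, groups$group_id)
  if (length(unknown)) {
    stopf("unknown group id(s): %s", paste(unknown, collapse = ", "))
  }
  members <- attr(groups, "members")
  zeroed <- unique(unlist(members[match(artifact_group_ids, groups$group_id)]))
  y <- as.integer(fm$labels == "abiotic")
  acc_of <- function(clf) {
    mean(as.integer(predict(clf, fm, type = "score") > 0) == y)
  }
  before <- acc_of(fitted)
  zapped <- fitted
  zapped$coefficients[as.character(zeroed)] <- 0
  after <- acc_of(zapped)
  list(accuracy_before = before, accuracy_after = after,
       delta = after - before, zeroed = zeroed)
}
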