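# End-to-end orchestration: ingest -> TII -> detect -> filter -> features ->
# classify -> groups -> stats, driven by a single config with the calibrated
# defaults, and a JSON-serializable run report of per-stage counts.

#' Pipeline configuration
#'
#' Defaults are the calibrated operating point: lambda1 = 5, lambda2 = 100,
#' RT1 threshold 50 s, RT2 threshold 0.8 s, DBSCAN eps = 5 / min_samples =
#' 20, whole-TII nonzero fraction 0.10, final L2 logistic regression with
#' C = 0.1. All randomness flows from the single root `seed`.
#'
#' @param manifest Path to a manifest file, or a `sample_manifest`.
#' @param raws Optional named list of in-memory `raw_scan_table`s (overrides
#'   per-sample paths in the manifest).
#' @param lambda1,lambda2,eps,min_samples,tii_max_frac Detection/filter
#'   parameters.
#' @param rt1_thrsh,rt2_thrsh Feature clustering tolerances in seconds.
#' @param C Inverse regularization strength of the final model.
#' @param cv_scheme `"ninefold_loo"`, `"stratified_6x5"` or `"none"`.
#' @param n_seeds CV repetitions.
#' @param min_shared Minimum samples sharing a group representative.
#' @param strip_ratio_thresholds Passed to [filter_params()].
#' @param out_dir Optional directory for artifacts (peak/feature/group
#'   tables and the JSON report).
#' @param seed Root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(manifest = NULL, raws = NULL, lambda1 = 5,
                            lambda2 = 100, eps = 5, min_samples = 20,
                            tii_max_frac = 0.10, rt1_thrsh = 50,
                            rt2_thrsh = 0.8, C = 0.1,
                            cv_scheme = "ninefold_loo", n_seeds = 10L,
                            min_shared = 2L,
                            strip_ratio_thresholds = list(vertical = 0.5, horizontal = 0.5),
                            out_dir = NULL, seed = 0L) {
  structure(list(manifest = manifest, raws = raws, lambda1 = lambda1,
                 lambda2 = lambda2, eps = eps, min_samples = min_samples,
                 tii_max_frac = tii_max_frac, rt1_thrsh = rt1_thrsh,
                 rt2_thrsh = rt2_thrsh, C = C, cv_scheme = cv_scheme,
                 n_seeds = as.integer(n_seeds), min_shared = as.integer(min_shared),
                 strip_ratio_thresholds = strip_ratio_thresholds,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  args <- doc[intersect(names(doc), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Detect and filter peaks for one sample
#'
#' Builds the TII stack, then for every non-empty m/z bin: image sigma,
#' thresholding + DBSCAN peak detection, and the three-stage denoising
#' cascade.
#'
#' @param raw A `raw_scan_table`.
#' @param det [detection_params()].
#' @param filt [filter_params()].
#' @param mz_bins Optional bin subset (default: all non-empty bins).
#' @return List with `peaks` (survivors), `n_detected`, and `counts`
#'   (per-stage totals).
#' @export
process_sample <- function(raw, det = detection_params(), filt = filter_params(),
                           mz_bins = NULL) {
  stack <- tii_stack(raw)
  bins <- mz_bins %||% tii_nonempty_bins(stack)
  out <- list(); total <- c(detected = 0L, after_tii = 0L, after_irect = 0L,
                            after_strip = 0L)
  for (b in bins) {
    grid <- tii_get(stack, b)
    sig <- tii_sigma(grid)
    pk <- detect_peaks(grid, det, sigma = sig)
    if (nrow(pk) == 0L) next
    thr <- threshold_tii(grid, det$lambda1, sig)
    res <- filter_cascade(thr, pk, sig, filt)
    total <- total + res$counts
    if (nrow(res$peaks) > 0L) out[[length(out) + 1L]] <- res$peaks
  }
  peaks <- if (length(out)) data.table::rbindlist(out) else empty_peak_table()
  list(peaks = peaks, n_detected = total[["detected"]], counts = total)
}

#' Run the full pipeline
#'
#' Executes ingest, TII construction, peak detection, the denoising cascade,
#' cross-sample feature clustering, the binary matrix, cross-validated
#' classification, the final model, feature grouping and peak-attribute
#' statistics. Writes delimited artifacts and a JSON report when
#' `config$out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list: stage counts, `cv` metrics, `fitted`,
#'   `groups`, `shared_groups`, `stats`, `matrix`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- config$manifest
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(manifest) && !is.null(config$raws)) {
    stopf("a manifest (with class labels) is required")
  }
  manifest <- as_sample_manifest(manifest)

  raws <- config$raws
  if (is.null(raws)) {
    raws <- lapply(seq_len(nrow(manifest)), function(i) {
      read_raw_scans(manifest$path[i], manifest$sample_id[i])
    })
    names(raws) <- manifest$sample_id
  }
  missing <- setdiff(manifest$sample_id, names(raws))
  if (length(missing)) stopf("no raw table for sample(s): %s", paste(missing, collapse = ", "))

  det <- detection_params(lambda1 = config$lambda1, dbscan_min_samples = config$min_samples,
                          dbscan_eps = config$eps)
  filt <- filter_params(tii_nonzero_max_fraction = config$tii_max_frac,
                        lambda2 = config$lambda2,
                        strip_ratio_thresholds = config$strip_ratio_thresholds)

  per_sample <- lapply(manifest$sample_id, function(sid) {
    process_sample(raws[[sid]], det, filt)
  })
  names(per_sample) <- manifest$sample_id
  peaks <- data.table::rbindlist(lapply(per_sample, `[[`, "peaks"))
  peak_counts <- vapply(per_sample, function(x) nrow(x$peaks), integer(1))

  fset <- cluster_peaks(peaks, config$rt1_thrsh, config$rt2_thrsh)
  fm <- build_matrix(fset, manifest)

  cv <- NULL
  fitted <- NULL; groups <- NULL; shared <- NULL
  if (nrow(fm$matrix) > 0L && length(unique(fm$labels)) == 2L) {
    check_both_classes(manifest)
    spec <- model_spec("logreg_l2")
    if (identical(config$cv_scheme, "ninefold_loo")) {
      cv <- ninefold_loo_cv(fm, spec, n_seeds = config$n_seeds)
    } else if (identical(config$cv_scheme, "stratified_6x5")) {
      cv <- stratified_nested_cv(fm, spec, n_seeds = config$n_seeds)
    }
    fitted <- fit_final(fm, spec, hyperparameters = data.frame(C = config$C),
                        seed = config$seed)
    feats <- data.table::as.data.table(fm$features)
    feats$coefficient <- unname(fitted$coefficients[as.character(feats$feature_id)])
    groups <- group_features(feats, config$rt1_thrsh, config$rt2_thrsh)
    shared <- filter_shared_groups(groups, fm, config$min_shared)
  }

  stats_tbl <- NULL
  if (nrow(peaks) > 0L) {
    lab <- stats::setNames(as.character(manifest$label), manifest$sample_id)
    pa <- peaks[lab[peaks$sample_id] == "abiotic", ]
    pb <- peaks[lab[peaks$sample_id] == "biotic", ]
    if (nrow(pa) > 0L && nrow(pb) > 0L) stats_tbl <- peak_attribute_stats(pa, pb)
  }

  report <- structure(list(
    n_samples = nrow(manifest),
    peaks_per_sample = peak_counts,
    n_peaks = nrow(peaks),
    n_features = nrow(fm$matrix),
    n_groups = if (!is.null(groups)) nrow(groups) else 0L,
    n_shared_groups = if (!is.null(shared)) nrow(shared) else 0L,
    cv = if (!is.null(cv)) list(scheme = cv$scheme, mean_accuracy = cv$mean_accuracy,
                                mean_auc = cv$mean_auc) else NULL,
    fitted = fitted, groups = groups, shared_groups = shared,
    stats = stats_tbl, matrix = fm, peaks = peaks, config = config),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) write_pipeline_artifacts(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d samples: %d peaks -> %d features -> %d groups (%d shared)\n",
              x$n_samples, x$n_peaks, x$n_features, x$n_groups, x$n_shared_groups))
  if (!is.null(x$cv)) {
    cat(sprintf("  CV (%s): accuracy %.3f, AUC %.3f\n",
                x$cv$scheme, x$cv$mean_accuracy, x$cv$mean_auc))
  }
  invisible(x)
}

write_pipeline_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$peaks, file.path(out_dir, "peaks.csv"))
  mat <- data.table::data.table(feature_id = rownames(report$matrix$matrix),
                                report$matrix$matrix)
  data.table::fwrite(mat, file.path(out_dir, "feature_matrix.csv"))
  data.table::fwrite(report$matrix$features, file.path(out_dir, "features.csv"))
  if (!is.null(report$groups)) {
    data.table::fwrite(report$groups, file.path(out_dir, "feature_groups.csv"))
  }
  if (!is.null(report$stats)) {
    data.table::fwrite(report$stats, file.path(out_dir, "peak_attribute_stats.csv"))
  }
  summary <- list(n_samples = report$n_samples, n_peaks = report$n_peaks,
                  peaks_per_sample = as.list(report$peaks_per_sample),
                  n_features = report$n_features, n_groups = report$n_groups,
                  n_shared_groups = report$n_shared_groups, cv = report$cv)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
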