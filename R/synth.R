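# Synthetic raw scan tables with known ground truth. The generator emits the
# same 7-column scan-table dialect the reader ingests and emulates the
# structures the pipeline must handle: planted compounds as coeluting
# fragment-ion sets (Gaussian intensity blobs sharing one jittered (RT1,
# RT2) centre across m/z bins), class-structured presence patterns, diffuse
# exponential background scans, and dense vertical/horizontal strip noise.

#' Define a planted compound
#'
#' @param name Compound label.
#' @param fragment_mzs Integer m/z bins of the coeluting fragment ions
#'   (non-empty; all share one retention-time centre).
#' @param rt1,rt2 Blob centre in seconds (inside the fixed grid).
#' @param amplitude Apex intensity of each fragment blob (default 1e5).
#' @param footprint_sd Isotropic Gaussian footprint in pixel units,
#'   truncated at 3 sd (default 1.5, roughly 60 surviving pixels).
#' @param class_affinity Named vector `c(abiotic = , biotic = )` of presence
#'   probabilities per class (default abiotic-only).
#' @return A `planted_compound` list.
#' @export
planted_compound <- function(name, fragment_mzs, rt1, rt2, amplitude = 1e5,
                             footprint_sd = 1.5,
                             class_affinity = c(abiotic = 1, biotic = 0)) {
  ax <- tii_axes()
  if (length(fragment_mzs) == 0L) stopf("compound %s has no fragment m/z", name)
  if (rt1 < min(ax$rt1) || rt1 > max(ax$rt1) || rt2 < min(ax$rt2) || rt2 > max(ax$rt2)) {
    stopf("compound %s retention times (%.1f, %.3f) lie outside the fixed grid", name, rt1, rt2)
  }
  if (!all(c("abiotic", "biotic") %in% names(class_affinity))) {
    stopf("class_affinity must name abiotic and biotic probabilities")
  }
  structure(list(name = name, fragment_mzs = as.integer(fragment_mzs),
                 rt1 = rt1, rt2 = rt2, amplitude = amplitude,
                 footprint_sd = footprint_sd, class_affinity = class_affinity),
            class = "planted_compound")
}

#' Deterministic layout of clean, well-separated compounds
#'
#' Places `n_compounds` compounds on a diagonal sweep of the retention plane
#' with pairwise RT1 separations far above the 50 s clustering threshold,
#' distinct m/z bins, and alternating class affinity (odd indices abiotic,
#' even biotic) unless overridden.
#'
#' @param n_compounds Number of compounds.
#' @param n_fragments Fragment ions per compound (default 1).
#' @param amplitude Blob apex intensity (default 1e5).
#' @param affinity Optional single affinity vector applied to all compounds.
#' @return List of [planted_compound()]s.
#' @export
synth_compound_layout <- function(n_compounds, n_fragments = 1L,
                                  amplitude = 1e5, affinity = NULL) {
  rt1s <- seq(3000, 10500, length.out = n_compounds)
  rt2s <- 0.8 + (seq_len(n_compounds) %% 5) * 0.4
  lapply(seq_len(n_compounds), function(i) {
    aff <- affinity %||%
      (if (i %% 2 == 1) c(abiotic = 1, biotic = 0) else c(abiotic = 0, biotic = 1))
    planted_compound(
      name = sprintf("cmpd%02d", i),
      fragment_mzs = 50L + (i - 1L) * n_fragments + seq_len(n_fragments) - 1L,
      rt1 = rt1s[i], rt2 = rt2s[i], amplitude = amplitude, class_affinity = aff)
  })
}

#' Synthetic dataset configuration
#'
#' Defaults state the emulated world: 8 abiotic and 10 biotic samples (the
#' study design), RT1 jitter sd 8 s and RT2 jitter sd 0.1 s (cross-sample
#' dispersions comfortably below the 50 s / 0.8 s clustering thresholds),
#' and 200 diffuse background scans per occupied m/z bin with exponential
#' mean intensity 30 so that default 5-sigma thresholding removes
#' essentially all of them.
#'
#' @param compounds List of [planted_compound()]s.
#' @param n_abiotic,n_biotic Sample counts per class.
#' @param rt1_jitter_sd,rt2_jitter_sd Per-(sample, compound) retention-time
#'   jitter standard deviations in seconds.
#' @param background_rate Background scans per (sample, occupied m/z bin).
#' @param background_mean Mean of the exponential background intensity.
#' @param strip_noise List of strips, each
#'   `list(mz_bin =, axis = "vertical"|"horizontal", position = seconds,
#'   density = fraction, width = pixels, intensity =)`.
#' @param seed Root RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(compounds, n_abiotic = 8L, n_biotic = 10L,
                         rt1_jitter_sd = 8, rt2_jitter_sd = 0.1,
                         background_rate = 200L, background_mean = 30,
                         strip_noise = list(), seed = 0L) {
  stopifnot(rt1_jitter_sd >= 0, rt2_jitter_sd >= 0,
            n_abiotic >= 0, n_biotic >= 0, background_rate >= 0)
  for (cp in compounds) stopifnot(inherits(cp, "planted_compound"))
  structure(list(compounds = compounds, n_abiotic = as.integer(n_abiotic),
                 n_biotic = as.integer(n_biotic), rt1_jitter_sd = rt1_jitter_sd,
                 rt2_jitter_sd = rt2_jitter_sd,
                 background_rate = as.integer(background_rate),
                 background_mean = background_mean,
                 strip_noise = strip_noise, seed = as.integer(seed)),
            class = "synth_config")
}

# scans for one Gaussian blob of one fragment, centred on a grid point
blob_scans <- function(mz_bin, centre_col, centre_row, amplitude, sd_px, ax) {
  r <- ceiling(3 * sd_px)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= (3 * sd_px)^2, ]
  rows <- centre_row + off$di
  cols <- centre_col + off$dj
  ok <- rows >= 1 & rows <= length(ax$rt2) & cols >= 1 & cols <= length(ax$rt1)
  off <- off[ok, ]; rows <- rows[ok]; cols <- cols[ok]
  data.table::data.table(
    rt1 = ax$rt1[cols], rt2 = ax$rt2[rows],
    mz = mz_bin + stats::runif(length(rows), -0.45, 0.45),
    area = amplitude * exp(-(off$di^2 + off$dj^2) / (2 * sd_px^2)))
}

#' Generate a synthetic dataset with ground truth
#'
#' For each sample and compound, presence is drawn from the class affinity;
#' a present compound emits one Gaussian scan blob per fragment m/z, all
#' fragments sharing one jittered (RT1, RT2) centre snapped to the fixed
#' grid. Background scans are uniform over the grid within each occupied
#' bin with exponential intensities; strip noise emits dense full-height
#' (or full-width) bands. Byte-reproducible for a fixed seed.
#'
#' @param config A [synth_config()].
#' @param seed Optional override of `config$seed`.
#' @return List with `raws` (named list of `raw_scan_table`s), `manifest`
#'   (a `sample_manifest`), `truth` (data.table: sample_id, compound,
#'   mz_bin, rt1, rt2 per planted fragment occurrence) and `config`.
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- seed %||% config$seed
  ax <- tii_axes()
  ids <- c(sprintf("A%02d", seq_len(config$n_abiotic)),
           sprintf("B%02d", seq_len(config$n_biotic)))
  labels <- c(rep("abiotic", config$n_abiotic), rep("biotic", config$n_biotic))
  manifest <- as_sample_manifest(data.frame(sample_id = ids, label = labels,
                                            path = NA_character_))
  occupied_bins <- unique(c(
    unlist(lapply(config$compounds, `[[`, "fragment_mzs")),
    vapply(config$strip_noise, function(s) as.integer(s$mz_bin), integer(1))))

  raws <- list(); truth <- list()
  withr::with_seed(seed, {
    for (si in seq_along(ids)) {
      sid <- ids[si]; cls <- labels[si]
      pieces <- list()
      for (cp in config$compounds) {
        if (stats::runif(1) >= cp$class_affinity[[cls]]) next
        c_rt1 <- cp$rt1 + stats::rnorm(1, sd = config$rt1_jitter_sd)
        c_rt2 <- cp$rt2 + stats::rnorm(1, sd = config$rt2_jitter_sd)
        col <- snap_to_axis(c_rt1, ax$rt1[1L], ax$rt1[2L] - ax$rt1[1L], length(ax$rt1))
        row <- snap_to_axis(c_rt2, ax$rt2[1L], ax$rt2[2L] - ax$rt2[1L], length(ax$rt2))
        if (is.na(col)) col <- if (c_rt1 < ax$rt1[1L]) 1L else length(ax$rt1)
        if (is.na(row)) row <- if (c_rt2 < ax$rt2[1L]) 1L else length(ax$rt2)
        for (fmz in cp$fragment_mzs) {
          pieces[[length(pieces) + 1L]] <-
            blob_scans(fmz, col, row, cp$amplitude, cp$footprint_sd, ax)
          truth[[length(truth) + 1L]] <- data.table::data.table(
            sample_id = sid, compound = cp$name, mz_bin = as.integer(fmz),
            rt1 = ax$rt1[col], rt2 = ax$rt2[row])
        }
      }
      if (config$background_rate > 0L && length(occupied_bins) > 0L) {
        for (b in occupied_bins) {
          nbg <- config$background_rate
          pieces[[length(pieces) + 1L]] <- data.table::data.table(
            rt1 = sample(ax$rt1, nbg, replace = TRUE),
            rt2 = sample(ax$rt2, nbg, replace = TRUE),
            mz = b + stats::runif(nbg, -0.45, 0.45),
            area = stats::rexp(nbg, rate = 1 / config$background_mean))
        }
      }
      for (strip in config$strip_noise) {
        pieces[[length(pieces) + 1L]] <- strip_scans(strip, ax)
      }
      scans <- if (length(pieces)) data.table::rbindlist(pieces) else
        data.table::data.table(rt1 = numeric(), rt2 = numeric(),
                               mz = numeric(), area = numeric())
      scans <- scans[scans$area > 0, ]
      full <- data.table::data.table(
        spectrum = seq_len(nrow(scans)) - 1L,
        rt1 = scans$rt1, rt2 = scans$rt2,
        tof = 117226.668 + (scans$mz - 30) / 670 * (478162.121 - 117226.668),
        mz = scans$mz, area = scans$area,
        resolution = rep(10000, nrow(scans)))
      raws[[sid]] <- new_raw_scan_table(sid, full)
    }
  })
  truth <- if (length(truth)) data.table::rbindlist(truth) else
    data.table::data.table(sample_id = character(), compound = character(),
                           mz_bin = integer(), rt1 = numeric(), rt2 = numeric())
  list(raws = raws, manifest = manifest, truth = truth, config = config)
}

# dense band of scans for one strip-noise entry
strip_scans <- function(strip, ax) {
  axis <- match.arg(strip$axis, c("vertical", "horizontal"))
  dens <- strip$density %||% 1
  width <- as.integer(strip$width %||% 6L)
  inten <- strip$intensity %||% 5e4
  if (axis == "vertical") {
    col0 <- snap_to_axis(strip$position, ax$rt1[1L], ax$rt1[2L] - ax$rt1[1L],
                         length(ax$rt1))
    if (is.na(col0)) stopf("strip position %.1f outside RT1 axis", strip$position)
    cols <- pmax(1L, pmin(length(ax$rt1), col0 + seq_len(width) - (width %/% 2L) - 1L))
    cells <- expand.grid(row = seq_along(ax$rt2), col = unique(cols))
  } else {
    row0 <- snap_to_axis(strip$position, ax$rt2[1L], ax$rt2[2L] - ax$rt2[1L],
                         length(ax$rt2))
    if (is.na(row0)) stopf("strip position %.3f outside RT2 axis", strip$position)
    rows <- pmax(1L, pmin(length(ax$rt2), row0 + seq_len(width) - (width %/% 2L) - 1L))
    cells <- expand.grid(row = unique(rows), col = seq_along(ax$rt1))
  }
  keep <- stats::runif(nrow(cells)) < dens
  cells <- cells[keep, ]
  data.table::data.table(
    rt1 = ax$rt1[cells$col], rt2 = ax$rt2[cells$row],
    mz = as.integer(strip$mz_bin) + stats::runif(nrow(cells), -0.45, 0.45),
    area = rep(inten, nrow(cells)))
}

#' Build a calibration reference set from ground truth
#'
#' Selects `k` planted compounds (those present in the most abiotic samples,
#' ties by name) and returns their realized abiotic occurrences as a
#' [reference_set()], mirroring an expert-verified list of known compounds
#' across the meteorite samples.
#'
#' @param dataset Output of [generate_dataset()].
#' @param k Number of reference compounds (default 6).
#' @return A [reference_set()] restricted to abiotic samples, one row per
#'   realized (compound, fragment, sample) occurrence.
#' @export
make_reference_set <- function(dataset, k = 6L) {
  truth <- dataset$truth
  abio <- dataset$manifest$sample_id[dataset$manifest$label == "abiotic"]
  tr <- truth[truth$sample_id %in% abio, ]
  if (nrow(tr) == 0L) stopf("no planted occurrences in abiotic samples")
  counts <- tr[, .(n = length(unique(sample_id))), by = "compound"]
  data.table::setorder(counts, -n, compound)
  if (nrow(counts) < k) {
    stopf("only %d planted compounds available, need k = %d", nrow(counts), k)
  }
  chosen <- counts$compound[seq_len(k)]
  sel <- tr[tr$compound %in% chosen, ]
  reference_set(data.frame(name = sel$compound, mz_bin = sel$mz_bin,
                           sample_id = sel$sample_id, rt1 = sel$rt1, rt2 = sel$rt2))
}
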