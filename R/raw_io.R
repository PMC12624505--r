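# Reading, validating and writing raw GCxGC-HRTOF-MS scan tables and the
# sample manifest.
#
# A raw scan table is long-format delimited text, one row per ionization
# scan, with seven named columns (an optional unnamed row index is ignored):
# spectrum, 1st time (s), 2nd time (s), TOF, m/z, area, resolution.
# Downstream analysis uses only (m/z, RT1, RT2, area).

# Documented value ranges observed on the instrument. Rows outside these are
# dropped with a warning (they are observed extremes, not guarantees).
RAW_RANGES <- list(
  rt1 = c(2200, 11457.568),
  rt2 = c(0, 3.504),
  mz  = c(29.99778, 700.02157)
)

# canonical column -> normalized header aliases
.RAW_ALIASES <- list(
  spectrum   = c("spectrum"),
  rt1        = c("1sttimes", "1sttime", "rt1", "firsttimes"),
  rt2        = c("2ndtimes", "2ndtime", "rt2", "secondtimes"),
  tof        = c("tof"),
  mz         = c("mz", "masscharge", "movrz"),
  area       = c("area", "intensity", "i"),
  resolution = c("resolution")
)

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a raw GCxGC-HRTOF-MS scan table
#'
#' Reads a delimited (comma or tab, auto-detected from the header line) scan
#' table, maps headers case/spacing-insensitively onto the seven documented
#' columns, and drops rows whose m/z, RT1 or RT2 fall outside the documented
#' instrument ranges (or whose area is not positive), with a warning giving
#' the dropped count.
#'
#' @param path Path to a delimited scan table.
#' @param sample_id Identifier attached to the returned table.
#' @return A `raw_scan_table`: list with `sample_id`, `scans` (a
#'   [data.table::data.table] with columns spectrum, rt1, rt2, tof, mz, area,
#'   resolution) and `n_dropped` (rows removed by range filtering).
#' @export
read_raw_scans <- function(path, sample_id) {
  if (!file.exists(path)) stopf("scan table not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) stopf("empty scan table: %s", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE)
  if (nrow(dt) == 0L) stopf("scan table has a header but no rows: %s", path)

  nms <- .norm_header(names(dt))
  idx <- vapply(names(.RAW_ALIASES), function(canon) {
    hit <- which(nms %in% .RAW_ALIASES[[canon]])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  missing <- names(idx)[is.na(idx)]
  if (length(missing)) {
    stopf("scan table %s is missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  dt <- dt[, idx, with = FALSE]
  data.table::setnames(dt, names(.RAW_ALIASES))
  for (col in names(dt)) {
    if (!is.numeric(dt[[col]])) dt[[col]] <- suppressWarnings(as.numeric(dt[[col]]))
  }

  keep <- dt$mz  >= RAW_RANGES$mz[1]  & dt$mz  <= RAW_RANGES$mz[2] &
          dt$rt1 >= RAW_RANGES$rt1[1] & dt$rt1 <= RAW_RANGES$rt1[2] &
          dt$rt2 >= RAW_RANGES$rt2[1] & dt$rt2 <= RAW_RANGES$rt2[2] &
          dt$area > 0 & !is.na(dt$mz) & !is.na(dt$rt1) & !is.na(dt$rt2)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warnf("%s: dropped %d of %d scans outside documented ranges",
          sample_id, n_dropped, nrow(dt))
  }
  out <- new_raw_scan_table(sample_id, dt[keep])
  out$n_dropped <- n_dropped
  out
}

new_raw_scan_table <- function(sample_id, scans) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  structure(list(sample_id = sample_id, scans = data.table::as.data.table(scans)),
            class = "raw_scan_table")
}

#' @export
print.raw_scan_table <- function(x, ...) {
  cat(sprintf("<raw_scan_table> sample %s: %d scans, m/z [%.3f, %.3f]\n",
              x$sample_id, nrow(x$scans),
              suppressWarnings(min(x$scans$mz)), suppressWarnings(max(x$scans$mz))))
  invisible(x)
}

#' Write a raw scan table in the instrument's delimited dialect
#'
#' Writes the seven named columns with their documented headers plus a
#' leading row index, using full-precision (round-trippable) numeric output.
#'
#' @param raw A `raw_scan_table`.
#' @param path Output file path; delimiter chosen from the extension
#'   (`.tsv`/`.tab` gives tab, anything else comma).
#' @return `path`, invisibly.
#' @export
write_raw_scans <- function(raw, path) {
  stopifnot(inherits(raw, "raw_scan_table"))
  sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  out <- data.table::copy(raw$scans)
  # 17 significant digits so doubles survive the text round trip bit-exactly
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  out <- cbind(data.table::data.table(`Row Index` = seq_len(nrow(out)) - 1L), out)
  data.table::setnames(out, c("Row Index", "Spectrum", "1st Time (s)", "2nd Time (s)",
                              "TOF", "m/z", "Area", "Resolution"))
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest lists the samples of a run with their class labels. Two
#' formats are accepted: YAML (a `samples:` list or a top-level list of
#' `{sample_id, label, path}` entries) and delimited text with columns
#' `sample_id,label,path`.
#'
#' @param path Manifest file; format chosen from the extension
#'   (`.yml`/`.yaml` versus delimited).
#' @return A `sample_manifest`: data.frame with columns `sample_id`, `label`
#'   (factor, levels `abiotic`/`biotic`) and `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    entries <- doc$samples %||% doc
    df <- data.frame(
      sample_id = vapply(entries, function(e) as.character(e$sample_id), character(1)),
      label     = vapply(entries, function(e) as.character(e$label), character(1)),
      path      = vapply(entries, function(e) as.character(e$path %||% NA_character_), character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- as.data.frame(data.table::fread(path, header = TRUE))
    if (!all(c("sample_id", "label") %in% names(df))) {
      stopf("manifest %s must have columns sample_id and label", path)
    }
    if (!"path" %in% names(df)) df$path <- NA_character_
  }
  as_sample_manifest(df)
}

#' Construct and validate a sample manifest from a data.frame
#'
#' @param df data.frame with columns `sample_id`, `label` and optionally `path`.
#' @return A validated `sample_manifest`.
#' @export
as_sample_manifest <- function(df) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) stopf("manifest is empty")
  if (anyDuplicated(df$sample_id)) {
    stopf("duplicate sample_id in manifest: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$label), c("abiotic", "biotic"))
  if (length(bad)) stopf("unknown label(s) in manifest: %s", paste(bad, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$label <- factor(df$label, levels = c("abiotic", "biotic"))
  if (!"path" %in% names(df)) df$path <- NA_character_
  rownames(df) <- NULL
  structure(df[, c("sample_id", "label", "path")],
            class = c("sample_manifest", "data.frame"))
}

# Both classes are needed before any classifier is trained.
check_both_classes <- function(manifest) {
  tab <- table(manifest$label)
  if (any(tab == 0L)) {
    stopf("classification requires both classes; counts: abiotic=%d, biotic=%d",
          tab[["abiotic"]], tab[["biotic"]])
  }
  invisible(manifest)
}
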