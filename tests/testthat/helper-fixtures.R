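# Shared fixture builders. Everything is generated in code; no data files.

# small TII with the standard axis spacings but an arbitrary shape
toy_grid <- function(values, sample_id = "S1", mz_bin = 100L) {
  nr <- nrow(values); nc <- ncol(values)
  lifetracer:::new_tii(values,
                       rt1_axis = 2200 + 3.5 * (seq_len(nc) - 1L),
                       rt2_axis = 0.008 * (seq_len(nr) - 1L),
                       sample_id = sample_id, mz_bin = mz_bin)
}

# solid rectangular blob painted onto a zero matrix
paint_block <- function(values, row0, col0, h, w, intensity = 100) {
  values[row0:(row0 + h - 1L), col0:(col0 + w - 1L)] <- intensity
  values
}

# in-memory raw scan table without touching disk
toy_raw <- function(df, sample_id = "S1") {
  cols <- list(spectrum = seq_len(nrow(df)) - 1L, rt1 = df$rt1, rt2 = df$rt2,
               tof = rep(2e5, nrow(df)), mz = df$mz, area = df$area,
               resolution = rep(1e4, nrow(df)))
  lifetracer:::new_raw_scan_table(sample_id, data.table::as.data.table(cols))
}

# write a scan-table CSV in the documented dialect
write_scan_csv <- function(df, path, headers = c("Row Index", "Spectrum", "1st Time (s)",
                                                 "2nd Time (s)", "TOF", "m/z", "Area",
                                                 "Resolution")) {
  full <- data.frame(idx = seq_len(nrow(df)) - 1L, spectrum = seq_len(nrow(df)) - 1L,
                     rt1 = df$rt1, rt2 = df$rt2, tof = rep(2e5, nrow(df)),
                     mz = df$mz, area = df$area, resolution = rep(1e4, nrow(df)))
  names(full) <- headers
  data.table::fwrite(full, path)
  path
}

# feature table for grouping tests
toy_features <- function(rt1, rt2, coef, mz_bin = NULL, id = seq_along(rt1)) {
  data.frame(feature_id = id, mz_bin = mz_bin %||% seq_along(rt1),
             rt1_center = rt1, rt2_center = rt2, coefficient = coef)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# separable 18-sample feature matrix: one feature equal to the class label
# plus `n_noise` random features
separable_matrix <- function(n_noise = 20L, seed = 42L, n_abiotic = 8L, n_biotic = 10L) {
  ids <- c(sprintf("A%02d", seq_len(n_abiotic)), sprintf("B%02d", seq_len(n_biotic)))
  labels <- factor(c(rep("abiotic", n_abiotic), rep("biotic", n_biotic)),
                   levels = c("abiotic", "biotic"))
  n <- length(ids)
  m <- withr::with_seed(seed, {
    rbind(matrix(as.integer(labels == "abiotic"), nrow = 1L),
          matrix(rbinom(n_noise * n, 1, 0.5), nrow = n_noise, ncol = n))
  })
  dimnames(m) <- list(as.character(seq_len(nrow(m))), ids)
  features <- data.table::data.table(
    feature_id = seq_len(nrow(m)), mz_bin = 100L + seq_len(nrow(m)),
    rt1_center = 3000 + 200 * seq_len(nrow(m)),
    rt2_center = rep(1, nrow(m)), n_peaks = rowSums(m))
  structure(list(matrix = m, features = features,
                 labels = stats::setNames(labels, ids)),
            class = "feature_matrix")
}
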