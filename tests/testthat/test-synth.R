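test_that("generation is reproducible and respects degenerate configs", {
  cfg <- synth_config(synth_compound_layout(3), n_abiotic = 2L, n_biotic = 2L,
                      background_rate = 20L, seed = 7L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$raws[["A01"]]$scans, d2$raws[["A01"]]$scans)

  # zero compounds and zero noise give empty tables
  empty <- generate_dataset(synth_config(list(), n_abiotic = 1L, n_biotic = 1L,
                                         background_rate = 0L, seed = 1L))
  expect_equal(nrow(empty$raws[["A01"]]$scans), 0L)
  expect_equal(nrow(empty$truth), 0L)

  # out-of-grid compound errors at construction
  expect_error(planted_compound("bad", 100L, rt1 = 100, rt2 = 1), "outside")
})

test_that("class affinities shape the presence pattern", {
  comps <- list(planted_compound("abio", 60L, 4000, 1.2,
                                 class_affinity = c(abiotic = 1, biotic = 0)),
                planted_compound("both", 70L, 6000, 1.8,
                                 class_affinity = c(abiotic = 1, biotic = 1)))
  cfg <- synth_config(comps, n_abiotic = 4L, n_biotic = 4L,
                      background_rate = 0L, seed = 3L)
  d <- generate_dataset(cfg)
  tr <- d$truth
  abio_ids <- d$manifest$sample_id[d$manifest$label == "abiotic"]
  expect_setequal(unique(tr$sample_id[tr$compound == "abio"]), abio_ids)
  expect_setequal(unique(tr$sample_id[tr$compound == "both"]), d$manifest$sample_id)
})

test_that("planted jitter keeps cross-sample dispersion within 6 sd", {
  cfg <- synth_config(synth_compound_layout(4, affinity = c(abiotic = 1, biotic = 0)),
                      n_abiotic = 8L, n_biotic = 0L, background_rate = 0L,
                      rt1_jitter_sd = 8, rt2_jitter_sd = 0.1, seed = 11L)
  d <- generate_dataset(cfg)
  disp <- d$truth[, .(d1 = max(rt1) - min(rt1), d2 = max(rt2) - min(rt2)),
                  by = "compound"]
  expect_true(all(disp$d1 <= 6 * 8))
  expect_true(all(disp$d2 <= 6 * 0.1 + 0.008))   # one grid step of snap slack
})

test_that("the emitted dialect round-trips through the reader", {
  cfg <- synth_config(synth_compound_layout(2), n_abiotic = 1L, n_biotic = 1L,
                      background_rate = 10L, seed = 5L)
  d <- generate_dataset(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_scans(d$raws[["A01"]], f)
  back <- read_raw_scans(f, "A01")
  expect_equal(nrow(back$scans), nrow(d$raws[["A01"]]$scans))
  expect_identical(back$scans$mz, d$raws[["A01"]]$scans$mz)
})

test_that("an abiotic-only compound is recovered end-to-end as one feature group", {
  comp <- planted_compound("target", c(60L, 61L, 62L), 5000, 1.5,
                           class_affinity = c(abiotic = 1, biotic = 0))
  cfg <- synth_config(list(comp), n_abiotic = 2L, n_biotic = 2L,
                      background_rate = 50L, seed = 2L)
  d <- generate_dataset(cfg)
  peaks <- data.table::rbindlist(lapply(d$manifest$sample_id, function(sid) {
    process_sample(d$raws[[sid]])$peaks
  }))
  fs <- cluster_peaks(peaks)
  # three fragments -> three features, present in the two abiotic samples only
  expect_equal(nrow(fs$features), 3L)
  expect_setequal(fs$features$mz_bin, c(60L, 61L, 62L))
  fm <- build_matrix(fs, d$manifest)
  expect_equal(unname(colSums(fm$matrix)), c(3, 3, 0, 0))
  # the fragments coelute, so grouping collapses them into one group
  feats <- as.data.frame(fm$features)
  feats$coefficient <- 1
  g <- group_features(feats)
  expect_equal(nrow(g), 1L)
  expect_setequal(fs$features$mz_bin[fs$features$feature_id %in% attr(g, "members")[[1]]],
                  c(60L, 61L, 62L))
})

test_that("make_reference_set selects k compounds with realized abiotic RTs", {
  cfg <- synth_config(synth_compound_layout(8, affinity = c(abiotic = 1, biotic = 0)),
                      n_abiotic = 3L, n_biotic = 1L, background_rate = 0L, seed = 9L)
  d <- generate_dataset(cfg)
  refs <- make_reference_set(d, k = 6L)
  expect_length(unique(refs$name), 6L)
  expect_true(all(refs$sample_id %in% c("A01", "A02", "A03")))
  expect_error(make_reference_set(d, k = 20L), "need k")
  r1 <- make_reference_set(d, k = 1L)
  expect_length(unique(r1$name), 1L)
})
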