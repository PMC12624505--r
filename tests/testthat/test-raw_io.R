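test_that("read_raw_scans passes valid rows through and maps headers", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(rt1 = c(3000, 4000, 5000), rt2 = c(1, 1.5, 2),
                   mz = c(100.2, 162.7, 300.1), area = c(10, 20, 30))
  write_scan_csv(df, f)
  raw <- read_raw_scans(f, "S1")
  expect_s3_class(raw, "raw_scan_table")
  expect_equal(nrow(raw$scans), 3L)
  expect_equal(raw$scans$mz, df$mz)
  expect_equal(raw$scans$area, df$area)
  expect_equal(raw$n_dropped, 0L)
})

test_that("out-of-range rows are dropped with a warning, in-range kept", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(rt1 = c(3000, 3000, 1000, 3000), rt2 = c(1, 1, 1, 5),
                   mz = c(100, 705, 100, 100), area = c(10, 10, 10, 10))
  write_scan_csv(df, f)
  expect_warning(raw <- read_raw_scans(f, "S1"), "dropped 3 of 4")
  expect_equal(nrow(raw$scans), 1L)
  expect_equal(raw$scans$mz, 100)
  # filtering is idempotent: re-reading what remains drops nothing
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_raw_scans(raw, f2)
  expect_no_warning(raw2 <- read_raw_scans(f2, "S1"))
  expect_equal(nrow(raw2$scans), 1L)
})

test_that("missing required column and empty file are format errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(rt1 = 3000, rt2 = 1, mz = 100, area = 10)
  write_scan_csv(df, f, headers = c("Row Index", "Spectrum", "1st Time (s)",
                                    "WRONG", "TOF", "m/z", "Area", "Resolution"))
  expect_error(read_raw_scans(f, "S1"), "rt2")

  f2 <- withr::local_tempfile(fileext = ".csv")
  file.create(f2)
  expect_error(read_raw_scans(f2, "S1"), "empty")
})

test_that("tab-delimited tables are detected from the header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- c("Row Index", "Spectrum", "1st Time (s)", "2nd Time (s)",
           "TOF", "m/z", "Area", "Resolution")
  writeLines(c(paste(hdr, collapse = "\t"),
               paste(c(0, 0, 3000, 1, 2e5, 100.5, 12.5, 1e4), collapse = "\t")), f)
  raw <- read_raw_scans(f, "S1")
  expect_equal(raw$scans$mz, 100.5)
})

test_that("round-trip preserves the four analysis fields bit-exactly", {
  set.seed(7)
  df <- data.frame(rt1 = runif(50, 2200, 11457), rt2 = runif(50, 0, 3.5),
                   mz = runif(50, 30, 700), area = rexp(50, 1e-3) + 1)
  raw <- toy_raw(df)
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_scans(raw, f)
  raw2 <- read_raw_scans(f, "S1")
  expect_identical(raw2$scans$rt1, raw$scans$rt1)
  expect_identical(raw2$scans$rt2, raw$scans$rt2)
  expect_identical(raw2$scans$mz, raw$scans$mz)
  expect_identical(raw2$scans$area, raw$scans$area)
})

test_that("manifest reading validates structure and labels", {
  # 18-entry manifest with the study's 8 abiotic / 10 biotic composition
  df <- data.frame(sample_id = c(sprintf("M%d", 1:8), sprintf("T%d", 1:10)),
                   label = c(rep("abiotic", 8), rep("biotic", 10)),
                   path = "x.csv")
  f <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(df, f)
  man <- read_manifest(f)
  expect_s3_class(man, "sample_manifest")
  expect_equal(as.vector(table(man$label)), c(8L, 10L))

  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(samples = lapply(seq_len(nrow(df)), function(i)
    list(sample_id = df$sample_id[i], label = df$label[i], path = df$path[i]))), fy)
  many <- read_manifest(fy)
  expect_equal(many$sample_id, man$sample_id)

  expect_error(as_sample_manifest(df[c(1, 1, 2), ]), "duplicate")
  expect_error(as_sample_manifest(df[0, ]), "empty")
  df$label[3] <- "martian"
  expect_error(as_sample_manifest(df), "unknown label")
})
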