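surface_from <- function(cells) {
  # cells: data.frame(lambda1, lambda2, accuracy); everything else fails
  grid <- expand.grid(lambda1 = 1:20, lambda2 = c(1, seq(10, 200, 10)))
  grid$accuracy <- 0.5
  for (i in seq_len(nrow(cells))) {
    hit <- grid$lambda1 == cells$lambda1[i] & grid$lambda2 == cells$lambda2[i]
    grid$accuracy[hit] <- cells$accuracy[i]
  }
  grid
}

test_that("select_params takes the largest passing lambda1 then the median lambda2", {
  surf <- surface_from(data.frame(lambda1 = c(4, 4, 5, 5, 5),
                                  lambda2 = c(50, 100, 50, 100, 150),
                                  accuracy = 0.95))
  expect_equal(select_params(surf), list(lambda1 = 5, lambda2 = 100))

  # a single passing cell is returned as-is
  surf1 <- surface_from(data.frame(lambda1 = 3, lambda2 = 20, accuracy = 0.91))
  expect_equal(select_params(surf1), list(lambda1 = 3, lambda2 = 20))

  # lower median for an even count of passing lambda2 values
  surf2 <- surface_from(data.frame(lambda1 = c(7, 7), lambda2 = c(10, 20),
                                   accuracy = 0.95))
  expect_equal(select_params(surf2), list(lambda1 = 7, lambda2 = 10))

  # strict > min_accuracy: exactly 0.90 does not pass
  surf3 <- surface_from(data.frame(lambda1 = 5, lambda2 = 100, accuracy = 0.90))
  expect_error(select_params(surf3), "calibration failed")
})

test_that("derive_rt_thresholds reproduces the printed rounding conventions", {
  # one compound seen in two samples with RT1 dispersion 49.056 s and RT2
  # dispersion 0.816 s: ceiling gives 50 s, half-even rounding gives 0.8 s
  refs <- reference_set(data.frame(name = "naph", mz_bin = 128L,
                                   sample_id = c("A", "B"),
                                   rt1 = c(3000, 3049.056), rt2 = c(1.0, 1.816)))
  peaks <- data.table::data.table(sample_id = c("A", "B"), mz_bin = 128L,
                                  apex_rt1 = c(3000, 3049.056),
                                  apex_rt2 = c(1.0, 1.816), irect = c(10, 10))
  thr <- derive_rt_thresholds(refs, peaks)
  expect_equal(thr$rt1_thrsh, 50)
  expect_equal(thr$rt2_thrsh, 0.8)

  # zero dispersion floors at the grid granularity
  peaks0 <- data.table::data.table(sample_id = c("A", "B"), mz_bin = 128L,
                                   apex_rt1 = 3000, apex_rt2 = 1.0, irect = 10)
  refs0 <- reference_set(data.frame(name = "x", mz_bin = 128L,
                                    sample_id = c("A", "B"), rt1 = 3000, rt2 = 1.0))
  expect_equal(derive_rt_thresholds(refs0, peaks0),
               list(rt1_thrsh = 1, rt2_thrsh = 0.1))

  # compounds matched in < 2 samples are excluded with a warning
  refs1 <- reference_set(data.frame(name = c("naph", "naph", "solo"),
                                    mz_bin = 128L,
                                    sample_id = c("A", "B", "A"),
                                    rt1 = c(3000, 3010, 9000), rt2 = 1))
  peaks1 <- rbind(peaks0,
                  data.table::data.table(sample_id = "A", mz_bin = 128L,
                                         apex_rt1 = 9000, apex_rt2 = 1, irect = 10))
  expect_warning(derive_rt_thresholds(refs1, peaks1), "solo")
})

test_that("recovery accuracy counts matched (compound, sample) pairs", {
  refs <- reference_set(data.frame(name = c("a", "a", "b"), mz_bin = c(100L, 100L, 200L),
                                   sample_id = c("S1", "S2", "S1"),
                                   rt1 = c(3000, 3000, 8000), rt2 = 1))
  peaks <- data.table::data.table(sample_id = c("S1", "S2"), mz_bin = 100L,
                                  apex_rt1 = c(3020, 2960), apex_rt2 = c(1.4, 0.2),
                                  irect = 10)
  # compound b never detected; compound a within +/-50 s / +/-1 s in both
  expect_equal(recovery_accuracy(refs, peaks), 2 / 3)
  # empty surviving peak set gives zero
  expect_equal(recovery_accuracy(refs, peaks[0, ]), 0)
})

test_that("calibration on planted clean compounds recovers a working operating point", {
  cfg <- synth_config(synth_compound_layout(8, amplitude = 1e5,
                                            affinity = c(abiotic = 1, biotic = 0)),
                      n_abiotic = 3L, n_biotic = 0L, background_rate = 50L,
                      seed = 4L)
  ds <- generate_dataset(cfg)
  refs <- make_reference_set(ds, k = 6L)
  surf <- calibration_surface(refs, ds$raws, lambda1s = c(2, 5, 10),
                              lambda2s = c(10, 100, 200))
  expect_true(all(surf$accuracy >= 0), all(surf$accuracy <= 1))
  # clean planted blobs are fully recovered at the default operating point
  expect_equal(surf$accuracy[surf$lambda1 == 5 & surf$lambda2 == 100], 1.0)
  # accuracy is non-increasing in lambda2 at fixed lambda1
  for (l1 in unique(surf$lambda1)) {
    s <- surf[surf$lambda1 == l1, ]
    expect_true(all(diff(s$accuracy[order(s$lambda2)]) <= 0))
  }
  # the surface is deterministic
  surf2 <- calibration_surface(refs, ds$raws, lambda1s = c(2, 5, 10),
                               lambda2s = c(10, 100, 200))
  expect_equal(surf, surf2)
})
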