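# independent oracle: literal transcription of the anchor-greedy procedure,
# kept deliberately simple (repeated scans of a working copy)
oracle_groups <- function(f, rt1_thrsh = 50, rt2_thrsh = 0.8) {
  left <- f[order(-abs(f$coefficient), f$feature_id), ]
  out <- list()
  while (nrow(left) > 0L) {
    anchor <- left[1L, ]
    near <- abs(left$rt1_center - anchor$rt1_center) <= rt1_thrsh &
            abs(left$rt2_center - anchor$rt2_center) <= rt2_thrsh
    out[[length(out) + 1L]] <- list(representative = anchor$feature_id,
                                    members = sort(left$feature_id[near]))
    left <- left[!near, ]
  }
  out
}

test_that("coeluting features collapse into one group led by the top coefficient", {
  f <- toy_features(rt1 = c(5000, 5020, 5040), rt2 = c(1.0, 1.1, 1.2),
                    coef = c(2.0, -1.0, 0.5), mz_bin = c(100, 128, 162))
  g <- group_features(f)
  expect_equal(nrow(g), 1L)
  expect_equal(g$coefficient, 2.0)
  expect_equal(g$n_members, 3L)
  expect_equal(g$direction, "abiotic")
})

test_that("well-separated features form separate groups ordered by |coefficient|", {
  f <- toy_features(rt1 = c(3000, 9000), rt2 = c(1, 2), coef = c(-0.5, 1.5))
  g <- group_features(f)
  expect_equal(nrow(g), 2L)
  expect_equal(g$coefficient, c(1.5, -0.5))   # ranked by representative |coef|
  expect_equal(g$direction, c("abiotic", "biotic"))
})

test_that("chains are anchored, not transitively merged", {
  # B within tolerance of both A and C; A and C mutually out of tolerance;
  # |A| > |B| > |C| gives groups {A, B} then {C}
  f <- toy_features(rt1 = c(5000, 5040, 5080), rt2 = c(1, 1, 1),
                    coef = c(3, -2, 1), id = c(10L, 20L, 30L))
  g <- group_features(f)
  expect_equal(nrow(g), 2L)
  m <- attr(g, "members")
  expect_setequal(m[[1]], c(10L, 20L))
  expect_equal(m[[2]], 30L)
})

test_that("grouping matches the brute-force oracle and partitions the features", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    f <- toy_features(rt1 = runif(n, 2500, 11000), rt2 = runif(n, 0, 3.5),
                      coef = rnorm(n))
    g <- group_features(f)
    o <- oracle_groups(f)
    expect_equal(nrow(g), length(o))
    expect_equal(g$representative, vapply(o, `[[`, numeric(1), "representative"))
    m <- attr(g, "members")
    for (i in seq_along(o)) expect_equal(sort(m[[i]]), o[[i]]$members)
    # partition: every feature in exactly one group
    expect_equal(sort(unlist(m)), sort(f$feature_id))
    # representative |coef| is the group maximum
    for (i in seq_along(m)) {
      expect_equal(max(abs(f$coefficient[f$feature_id %in% m[[i]]])),
                   abs(g$coefficient[i]))
    }
  }
})

test_that("tie-breaking on equal coefficients anchors the lower feature id", {
  f <- toy_features(rt1 = c(3000, 9000), rt2 = c(1, 1), coef = c(1, 1),
                    id = c(7L, 2L))
  g <- group_features(f)
  expect_equal(g$representative, c(2L, 7L))
})

test_that("filter_shared_groups keeps representatives present in enough samples", {
  fm <- separable_matrix(n_noise = 3L)
  fm$matrix[2, ] <- c(1L, rep(0L, 17))     # feature 2 in a single sample
  f <- toy_features(rt1 = c(3000, 6000, 9000), rt2 = c(1, 2, 3),
                    coef = c(2, 1.5, 1), id = 1:3)
  g <- group_features(f)
  kept <- filter_shared_groups(g, fm, min_samples = 2L)
  expect_false(2L %in% kept$representative)
  expect_true(all(kept$n_samples_shared >= 2L))
  # min_samples = 1 is the identity
  expect_equal(nrow(filter_shared_groups(g, fm, 1L)), nrow(g))
})

test_that("artifact zeroing leaves accuracy unchanged when artifacts are inert", {
  # artifact features present in every sample (instrument-contaminant
  # pattern): the unpenalized intercept absorbs them, so their L2
  # coefficients are zero and zeroing them cannot move any decision score
  fm <- separable_matrix(n_noise = 6L, seed = 17L)
  fm$matrix[2:7, ] <- 1L
  clf <- fit_final(fm, hyperparameters = data.frame(C = 1))
  feats <- as.data.frame(fm$features)
  feats$coefficient <- unname(clf$coefficients[as.character(feats$feature_id)])
  g <- group_features(feats)
  # artifact groups: all groups not containing the signal feature
  sig_gid <- g$group_id[vapply(attr(g, "members"), function(m) 1L %in% m, logical(1))]
  art <- setdiff(g$group_id, sig_gid)
  res <- zero_artifact_groups(clf, g, art, fm)
  expect_equal(res$accuracy_before, 1.0)
  expect_equal(res$delta, 0)
  # zeroing nothing is a no-op
  res0 <- zero_artifact_groups(clf, g, integer(0), fm)
  expect_equal(res0$delta, 0)
  expect_length(res0$zeroed, 0)
  # unknown ids error
  expect_error(zero_artifact_groups(clf, g, 999L, fm), "unknown group")
})
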