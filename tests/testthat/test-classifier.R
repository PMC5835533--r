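test_that("z-scoring uses the population standard deviation and handles degenerate columns", {
  z <- zscore_features(matrix(c(1, 2, 3), 3, 1))
  expect_equal(drop(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)

  # idempotence on already-scaled data
  x <- matrix(rnorm(20), 10, 2)
  z1 <- zscore_features(x)
  expect_equal(zscore_features(z1), z1, tolerance = 1e-12)

  expect_warning(zc <- zscore_features(matrix(c(7, 7, 7, 1, 2, 3), 3, 2)),
                 "constant")
  expect_equal(zc[, 1], rep(0, 3))
})

test_that("leave-one-out accuracy behaves on separated, uninformative and degenerate data", {
  # far-separated clusters classify perfectly
  set.seed(1)
  x <- rbind(matrix(rnorm(8, -10, 0.1), 4, 2), matrix(rnorm(8, 10, 0.1), 4, 2))
  y <- rep(c("a", "b"), each = 4)
  expect_equal(loo_accuracy(x, y, C = 1), 1)

  # identical points carry no information
  x0 <- matrix(1, 8, 2)
  expect_lte(loo_accuracy(x0, y, C = 1), 0.5)

  expect_error(loo_accuracy(x, rep("a", 8), 1), "binary")
  expect_error(loo_accuracy(x, c("a", rep("b", 7)), 1), "per class")
  expect_error(loo_accuracy(x, y, -1), "positive")

  # complement symmetry: swapping all labels leaves accuracy unchanged
  y_swap <- ifelse(y == "a", "b", "a")
  for (C in c(0.01, 1, 100))
    expect_equal(loo_accuracy(x, y, C), loo_accuracy(x, y_swap, C))
})

test_that("single-class training folds predict the training label instead of crashing", {
  # 2 points per class: leaving one out can make a one-class fold only in
  # the permuted labelings, but force it directly here
  x <- matrix(c(0, 0, 1, 1, 10, 10), 3, 2)
  y <- c("a", "a", "b")
  # removing the only "b" leaves a one-class fold; must return a value
  expect_error(loo_accuracy(x, y, 1), "per class")  # guarded at entry
  p <- ieptask:::svm_predict(x[1:2, , drop = FALSE], c("a", "a"),
                             x[3, , drop = FALSE], 1)
  expect_identical(p, "a")
})

test_that("penalty selection uses the exact log grid and deterministic tie-breaking", {
  g <- default_c_grid()
  expect_length(g, 10)
  expect_identical(g[1], 1e-3)
  expect_identical(g[10], 1e3)
  expect_equal(log10(g), seq(-3, 3, length.out = 10))

  set.seed(2)
  x <- rbind(matrix(rnorm(12, -5, 0.5), 6, 2), matrix(rnorm(12, 5, 0.5), 6, 2))
  y <- rep(c("a", "b"), each = 6)
  sel <- select_C(x, y)
  expect_equal(max(sel$cv_by_c), 1)
  expect_equal(unname(sel$cv_by_c[which(g == sel$selected_C)]), 1)

  # flat accuracy profile -> smallest C
  xf <- matrix(0, 8, 2)
  yf <- rep(c("a", "b"), each = 4)
  self <- select_C(xf, yf)
  expect_equal(self$selected_C, 1e-3)
  expect_equal(length(unique(self$cv_by_c)), 1)
})

test_that("exhaustive permutation enumeration counts and bounds are correct", {
  set.seed(3)
  x <- matrix(rnorm(8), 4, 2)
  y <- c("a", "a", "b", "b")
  pt <- permutation_test(x, y, C = 1)
  expect_equal(pt$n_permutations, choose(4, 2))
  expect_true(pt$exhaustive)
  expect_gte(pt$p_value, 1 / pt$n_permutations)

  # identical features: labels carry no information, p is large
  x0 <- matrix(1, 8, 2)
  y8 <- rep(c("a", "b"), each = 4)
  pt0 <- permutation_test(x0, y8, C = 1)
  expect_gte(pt0$p_value, 0.5)

  expect_error(permutation_test(x, rep("a", 4), 1), "binary")
})

test_that("far-separated 6v6 clusters give p = 2/924 with only the true labeling and its complement perfect", {
  set.seed(4)
  x <- rbind(matrix(rnorm(12, -8, 0.3), 6, 2), matrix(rnorm(12, 8, 0.3), 6, 2))
  y <- rep(c("a", "b"), each = 6)
  pt <- permutation_test(zscore_features(x), y, C = 1)
  expect_equal(pt$n_permutations, 924)
  # any labeling that mixes the two tight, distant clusters must misclassify
  # at least one held-out point, so exactly the true labeling and its
  # complement reach accuracy 1
  expect_equal(sum(pt$perm_distribution == 1), 2)
  expect_equal(pt$p_value, 2 / 924)
})

test_that("Monte-Carlo fallback engages beyond the exhaustive cap and is seeded", {
  set.seed(5)
  x <- rbind(matrix(rnorm(12, -8, 0.3), 6, 2), matrix(rnorm(12, 8, 0.3), 6, 2))
  y <- rep(c("a", "b"), each = 6)
  p1 <- permutation_test(x, y, 1, exhaustive_cap = 100, n_mc = 50, seed = 42)
  p2 <- permutation_test(x, y, 1, exhaustive_cap = 100, n_mc = 50, seed = 42)
  expect_false(p1$exhaustive)
  expect_equal(p1$n_permutations, 50)
  expect_identical(p1$perm_distribution, p2$perm_distribution)
  expect_gte(p1$p_value, 1 / 51)
  expect_error(permutation_test(x, y, 1, exhaustive_cap = 100, n_mc = 50),
               "seed")
})

test_that("classify_electrodes wires the chain together and validates inputs", {
  d <- generate_dataset(left_config(seed = 101, trials = 20, fs = 256))
  f <- features_for_dataset(average_evoked(d$epochs), meta = d$meta)
  res <- classify_electrodes(f, d$meta, "L")
  expect_s3_class(res, "classification_result")
  expect_equal(res$n_permutations, 924)
  expect_equal(as.integer(res$n_per_class), c(6L, 6L))
  expect_true(any(abs(res$loo_accuracy - (0:12) / 12) < 1e-12))
  expect_gte(res$p_value, 1 / 924)
  expect_length(res$hyperplane$w, 2)
  expect_length(res$cv_by_c, 10)

  # too few electrodes in a class
  skinny <- d$meta[c(1, 7, 8), ]
  expect_error(classify_electrodes(f[f$electrode_id %in% skinny$electrode_id, ],
                                   skinny, "L"),
               "at least 2 electrodes")

  # fold-safe scaling variant runs and stays a valid accuracy
  res2 <- classify_electrodes(f, d$meta, "L", fold_safe_scaling = TRUE)
  expect_true(res2$loo_accuracy >= 0 && res2$loo_accuracy <= 1)
})

test_that("degenerate-denominator electrodes are excluded, not imputed", {
  d <- generate_dataset(left_config(seed = 13, n_ltc = 3, n_hipp = 3,
                                    trials = 6, fs = 256))
  f <- features_for_dataset(average_evoked(d$epochs), meta = d$meta)
  f$degenerate[1] <- TRUE
  res <- classify_electrodes(f, d$meta, "L")
  expect_false(f$electrode_id[1] %in% res$electrode_id)
  expect_equal(length(res$electrode_id), 5)
})
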