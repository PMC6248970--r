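test_that("wrapper search finds a perfectly separating feature among noise", {
  # one strong feature, 19 noise features, n = 40
  g <- generate_feature_table(n = 40, p = 20, k_informative = 1, d = 6,
                              seed = 5)
  sub <- wrapper_search(g$table, rf_params(100), seed = 5)
  expect_true(g$informative %in% sub)
})

test_that("wrapper search degenerates sensibly", {
  # a single candidate feature: returned iff it beats the majority baseline
  g <- generate_feature_table(n = 20, p = 1, k_informative = 1, d = 6,
                              seed = 2)
  sub <- wrapper_search(g$table, rf_params(100), seed = 2)
  expect_identical(sub, g$informative)

  # pure-noise single feature: empty subset
  g0 <- generate_feature_table(n = 20, p = 1, k_informative = 0, d = 0,
                               seed = 3)
  sub0 <- wrapper_search(g0$table, rf_params(100), seed = 3)
  expect_length(sub0, 0)

  # single-class training data is an error
  tab <- g$table
  tab$class <- "adaptive"
  expect_error(wrapper_search(tab, rf_params(100), seed = 1),
               "exactly 2 values|single class")
})

test_that("a duplicated feature column is never selected twice", {
  g <- generate_feature_table(n = 30, p = 5, k_informative = 1, d = 4,
                              seed = 7)
  tab <- g$table
  tab$dup_feature <- tab[[g$informative]]  # identical copy
  for (seed in c(1, 2, 3)) {
    sub <- wrapper_search(tab, rf_params(100), seed = seed)
    expect_lte(sum(sub %in% c(g$informative, "dup_feature")), 1)
  }
})

test_that("selection frequencies implement the 10%-of-folds rule", {
  # synthetic report arithmetic on a 12-row table: tau = 0.1 keeps features
  # chosen in ceiling(0.1 * 12) = 2+ folds
  g <- generate_feature_table(n = 12, p = 4, k_informative = 1, d = 5,
                              seed = 9)
  sel <- loo_wrapper_selection(g$table, rf_params(50), tau = 0.10, seed = 9)
  expect_s3_class(sel, "selection_report")
  expect_length(sel$per_fold_subsets, 12)
  expect_true(all(sel$frequencies$frequency >= 0 &
                  sel$frequencies$frequency <= 1))
  # signature = features at or above threshold
  expect_setequal(sel$signature,
                  sel$frequencies$feature[sel$frequencies$frequency >= 0.10])
  # the planted feature dominates the selection frequencies
  f_inf <- sel$frequencies$frequency[sel$frequencies$feature == g$informative]
  expect_gte(f_inf, 0.8)
  expect_equal(max(sel$frequencies$frequency), f_inf)

  # threshold arithmetic at the boundary: 10/91 retained, 8/91 excluded
  expect_gte(10 / 91, 0.10)
  freq <- tibble::tibble(feature = c("a", "b"), n_folds = c(10L, 8L),
                         frequency = c(10, 8) / 91)
  kept <- freq$feature[freq$frequency >= 0.10]
  expect_identical(kept, "a")
})

test_that("the signature is monotone in tau and ordered by frequency", {
  g <- generate_feature_table(n = 16, p = 6, k_informative = 2, d = 3,
                              seed = 13)
  sel1 <- loo_wrapper_selection(g$table, rf_params(50), tau = 0.10, seed = 13)
  # recompute signatures at higher thresholds from the same frequencies
  for (tau2 in c(0.3, 0.6, 1.0)) {
    sig2 <- sel1$frequencies$feature[sel1$frequencies$frequency >= tau2]
    expect_true(all(sig2 %in% sel1$signature))
  }
  freqs <- sel1$frequencies$frequency[match(sel1$signature,
                                            sel1$frequencies$feature)]
  expect_true(all(diff(freqs) <= 0))
})

test_that("selection is exactly reproducible for a fixed seed", {
  g <- generate_feature_table(n = 12, p = 5, k_informative = 1, d = 3,
                              seed = 17)
  s1 <- loo_wrapper_selection(g$table, rf_params(50), tau = 0.1, seed = 17)
  s2 <- loo_wrapper_selection(g$table, rf_params(50), tau = 0.1, seed = 17)
  expect_identical(s1$per_fold_subsets, s2$per_fold_subsets)
  expect_identical(s1$signature, s2$signature)
})

test_that("tidy and glance summarize a selection report", {
  g <- generate_feature_table(n = 10, p = 4, k_informative = 1, d = 4,
                              seed = 19)
  sel <- loo_wrapper_selection(g$table, rf_params(50), tau = 0.1, seed = 19)
  td <- tidy(sel)
  expect_named(td, c("feature", "n_folds", "frequency", "in_signature"))
  expect_equal(nrow(td), 4)
  gl <- glance(sel)
  expect_equal(gl$n_folds, 10)
  expect_equal(gl$n_signature, length(sel$signature))
  p <- autoplot(sel, min_frequency = 0)
  expect_s3_class(p, "ggplot")
})
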