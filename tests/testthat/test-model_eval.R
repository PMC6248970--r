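# Prediction set reconstructing the published confusion structure:
# 50 positives (42 correct), 41 negatives (29 correct)
table2_predictions <- function() {
  list(probs = c(rep(0.9, 42), rep(0.1, 8), rep(0.1, 29), rep(0.9, 12)),
       labels = rep(c("adaptive", "non-adaptive"), c(50, 41)))
}

test_that("prevalence-adjusted PPV/NPV reproduce the Bayes worked example", {
  p <- table2_predictions()
  rep <- compute_metrics(p$probs, p$labels, pi = 0.40)
  m <- function(name) rep$metrics$estimate[rep$metrics$metric == name]
  expect_equal(m("sensitivity"), 0.840, tolerance = 1e-3)
  expect_equal(m("specificity"), 29 / 41)
  expect_equal(round(m("ppv_adj"), 3), 0.657)
  expect_equal(round(m("npv_adj"), 3), 0.869)
  expect_equal(round(m("precision"), 3), 0.778)
  expect_equal(round(m("accuracy"), 3), 0.780)
})

test_that("Wald intervals use p +/- 1.96 sqrt(p(1-p)/n)", {
  p <- table2_predictions()
  rep <- compute_metrics(p$probs, p$labels)
  acc <- rep$metrics[rep$metrics$metric == "accuracy", ]
  p_hat <- 71 / 91
  expect_equal(acc$estimate, p_hat)
  expect_equal(acc$conf_low, p_hat - 1.96 * sqrt(p_hat * (1 - p_hat) / 91))
  expect_equal(acc$conf_high, p_hat + 1.96 * sqrt(p_hat * (1 - p_hat) / 91))
  # printed presentation: 69.5% to 86.5%
  expect_equal(round(100 * acc$conf_low, 1), 69.5)
  expect_equal(round(100 * acc$conf_high, 1), 86.5)
})

test_that("perfect predictions give unit metrics for any prevalence", {
  probs <- c(rep(1, 5), rep(0, 6))
  labels <- rep(c("adaptive", "non-adaptive"), c(5, 6))
  for (pi in c(0.1, 0.4, 0.9)) {
    rep <- compute_metrics(probs, labels, pi = pi)
    est <- rep$metrics$estimate
    expect_equal(est, rep(1, 7), tolerance = 1e-12)
  }
})

test_that("adjusted PPV at the sample prevalence equals raw precision", {
  # the Bayes identity, checked numerically on random confusion structures
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n1 <- sample(10:40, 1); n0 <- sample(10:40, 1)
      probs <- c(runif(n1), runif(n0))
      labels <- rep(c("adaptive", "non-adaptive"), c(n1, n0))
    })
    rep <- compute_metrics(probs, labels, pi = n1 / (n1 + n0))
    prec <- rep$metrics$estimate[rep$metrics$metric == "precision"]
    ppv <- rep$metrics$estimate[rep$metrics$metric == "ppv_adj"]
    if (!is.na(prec)) expect_equal(ppv, prec, tolerance = 1e-12)
  }
})

test_that("confusion counts satisfy their accounting identities", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 40
      probs <- runif(n)
      labels <- sample(rep(c("adaptive", "non-adaptive"), c(22, 18)))
    })
    rep <- compute_metrics(probs, labels)
    cm <- rep$confusion
    expect_equal(cm[["TP"]] + cm[["FN"]], 22)
    expect_equal(cm[["TN"]] + cm[["FP"]], 18)
    expect_equal(rep$metrics$estimate[rep$metrics$metric == "accuracy"],
                 (cm[["TP"]] + cm[["TN"]]) / 40)
    expect_equal(rep$auc, auc <- {
      # independent rank-sum AUC
      y <- labels == "adaptive"
      r <- rank(probs)
      (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
    })
    # metrics invariant under row permutation
    withr::with_seed(seed + 100, perm <- sample(n))
    rep2 <- compute_metrics(probs[perm], labels[perm])
    expect_equal(rep2$metrics, rep$metrics)
  }
})

test_that("a random predictor scores AUC near one half", {
  aucs <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      probs <- runif(60)
      labels <- rep(c("adaptive", "non-adaptive"), each = 30)
    })
    compute_metrics(probs, labels)$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("degenerate metric inputs are rejected", {
  expect_error(compute_metrics(runif(5), rep("adaptive", 5)), "two classes")
  expect_error(compute_metrics(runif(4), rep(c("a", "b"), 2), pi = 1.2),
               "0, 1")
  expect_error(compute_metrics(runif(3), rep("a", 4)), "aligned")
})

test_that("the .632+ aggregation matches an independent transcription", {
  # formula limits
  expect_equal(b632plus_combine(0.2, 0.2, 0.5),
               0.368 * 0.2 + 0.632 * 0.2)  # R = 0: classical .632
  w1 <- 0.632 / (1 - 0.368)
  expect_equal(b632plus_combine(0, 0.5, 0.5), w1 * 0.5)  # R = 1

  # 20 random prediction sets scored by both implementations
  for (i in 1:20) {
    withr::with_seed(i, {
      n <- 30
      y <- rbinom(n, 1, 0.5)
      resub <- ifelse(runif(n) < 0.9, y, 1 - y)       # optimistic on-train fit
      B <- 15
      err_cnt <- numeric(n); oob_cnt <- numeric(n)
      for (b in seq_len(B)) {
        oob <- which(runif(n) < exp(-1))
        wrong <- runif(length(oob)) < 0.4
        err_cnt[oob] <- err_cnt[oob] + wrong
        oob_cnt[oob] <- oob_cnt[oob] + 1
      }
    })
    err_bar <- mean(resub != y)
    cov <- oob_cnt > 0
    eps0 <- mean(err_cnt[cov] / oob_cnt[cov])
    p1 <- mean(y); q1 <- mean(resub)
    gamma <- p1 * (1 - q1) + (1 - p1) * q1
    expect_equal(b632plus_combine(err_bar, eps0, gamma),
                 oracle_632plus(err_bar, eps0, gamma), tolerance = 1e-12)
  }
})

test_that("leave-one-out predictions separate a well-separated cohort", {
  g <- generate_feature_table(n = 20, p = 4, k_informative = 2, d = 5,
                              seed = 31)
  preds <- loo_predict(g$table, table_feature_names(g$table),
                       rf_params(100, seed = 31))
  expect_equal(nrow(preds), 20)
  correct <- (preds$prob >= 0.5) == (preds$class == "adaptive")
  expect_gte(mean(correct), 0.9)

  # n = 3 minimal table returns exactly 3 probabilities
  g3 <- generate_feature_table(n = 4, p = 2, k_informative = 1, d = 4,
                               seed = 32)
  tab3 <- g3$table[1:3, ]
  if (length(unique(tab3$class)) == 2) {
    expect_equal(nrow(loo_predict(tab3, table_feature_names(tab3),
                                  rf_params(50))), 3)
  }

  expect_error(loo_predict(g$table, "no_such_feature", rf_params(50)),
               "not in the table")
})

test_that("label permutation destroys the pooled LOO signal", {
  g <- generate_feature_table(n = 30, p = 5, k_informative = 2, d = 4,
                              seed = 41)
  tab <- g$table
  withr::with_seed(41, tab$class <- sample(tab$class))
  preds <- loo_predict(tab, table_feature_names(tab), rf_params(100, seed = 41))
  auc <- compute_metrics(preds)$auc
  expect_gte(auc, 0.3)
  expect_lte(auc, 0.7)
})

test_that(".632+ bootstrap is small on separable data and resubstitution is optimistic", {
  g <- generate_feature_table(n = 24, p = 4, k_informative = 2, d = 5,
                              seed = 51)
  est <- bootstrap_632plus(g$table, table_feature_names(g$table),
                           rf_params(100, seed = 51), B = 30, seed = 51)
  expect_lt(as.numeric(est), 0.1)

  # err_bar <= eps0 in at least 8 of 10 seeds
  optimistic <- vapply(1:10, function(s) {
    g2 <- generate_feature_table(n = 16, p = 3, k_informative = 1, d = 2,
                                 seed = 60 + s)
    e <- bootstrap_632plus(g2$table, table_feature_names(g2$table),
                           rf_params(60, seed = s), B = 15, seed = s)
    attr(e, "err_bar") <= attr(e, "eps0")
  }, logical(1))
  expect_gte(sum(optimistic), 8)
})

test_that("evaluate_model assembles a full report", {
  g <- generate_feature_table(n = 16, p = 3, k_informative = 1, d = 4,
                              seed = 71)
  rep <- evaluate_model(g$table, table_feature_names(g$table),
                        rf_params(60, seed = 71), B = 10, seed = 71)
  expect_s3_class(rep, "evaluation_report")
  expect_true(is.numeric(rep$b632plus_error))
  expect_equal(rep$loo_error,
               1 - rep$metrics$estimate[rep$metrics$metric == "accuracy"])
  expect_named(tidy(rep), c("metric", "estimate", "conf_low", "conf_high"))
  expect_true(all(c("auc", "loo_error", "b632plus_error") %in%
                  names(glance(rep))))
  expect_s3_class(autoplot(rep), "ggplot")
})
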