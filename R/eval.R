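#' Pooled leave-one-out predictions
#'
#' For each of the n folds a Random Forest is trained on the remaining
#' n - 1 rows restricted to the signature features and scores the held-out
#' patient; the n out-of-fold probabilities are pooled into a single ROC.
#'
#' @param tab A feature table (n >= 3, both classes present).
#' @param signature Non-empty character vector of feature columns.
#' @param params [rf_params()] for the final model; fold i reseeds the
#'   forest with `params$seed + i`.
#' @param positive_class See [rf_predict()].
#' @return A tibble with `patient_id`, `class`, `prob` (out-of-fold
#'   positive-class probability), in table order.
#' @export
loo_predict <- function(tab, signature, params = rf_params(),
                        positive_class = NULL) {
  tab <- validate_feature_table(tab)
  n <- nrow(tab)
  if (n < 3L) abort("Leave-one-out evaluation needs at least 3 rows.")
  if (length(signature) == 0L) abort("`signature` must be non-empty.")
  missing_f <- setdiff(signature, table_feature_names(tab))
  if (length(missing_f)) {
    abort(sprintf("Signature names not in the table: %s",
                  paste(utils::head(missing_f, 5), collapse = ", ")))
  }
  pos <- positive_label(tab, positive_class)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    fold_params <- rf_params(params$n_trees, params$m, params$seed + i)
    probs[i] <- rf_predict(tab[-i, , drop = FALSE], tab[i, , drop = FALSE],
                           signature, fold_params, pos)
  }
  tibble(patient_id = tab$patient_id, class = as.character(tab$class),
         prob = probs)
}

#' Classification metrics with confidence intervals
#'
#' Computes the evaluation suite of the workflow from pooled out-of-fold
#' probabilities: AUC by the trapezoidal rule over the pooled ROC (ties
#' handled by midpoints, i.e. the Mann-Whitney statistic), the
#' threshold-0.5 confusion matrix, accuracy, precision (confusion-matrix
#' PPV), sensitivity and specificity, and prevalence-adjusted predictive
#' values at an assumed prevalence `pi`:
#' `ppv_adj = sens*pi / (sens*pi + (1-spec)*(1-pi))` and
#' `npv_adj = spec*(1-pi) / (spec*(1-pi) + (1-sens)*pi)`.
#' Proportion metrics get Wald 95% intervals `p +/- 1.96*sqrt(p(1-p)/n)`
#' with n the number of pooled predictions; the AUC interval uses the
#' Hanley-McNeil standard error.
#'
#' @param probs Numeric vector of positive-class probabilities (or the
#'   tibble returned by [loo_predict()], whose `prob`/`class` columns are
#'   used).
#' @param labels Character vector of true labels, aligned with `probs`.
#' @param positive_class Label counted as positive (default `"adaptive"`
#'   when present).
#' @param pi Assumed positive prevalence in (0, 1) for the adjusted
#'   predictive values (default 0.40, the literature rate of significant
#'   tumour reduction during chemoradiation).
#' @return An object of class `evaluation_report`: list with `confusion`
#'   (TP, FP, TN, FN), `metrics` (tibble: metric, estimate, conf_low,
#'   conf_high), `auc`, `roc` (tibble of ROC points), `prevalence`,
#'   `loo_error`, `n`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' probs <- c(rep(0.9, 42), rep(0.1, 8), rep(0.1, 29), rep(0.9, 12))
#' labels <- rep(c("adaptive", "non-adaptive"), c(50, 41))
#' compute_metrics(probs, labels)$metrics
#' @export
compute_metrics <- function(probs, labels = NULL, positive_class = NULL,
                            pi = 0.40) {
  if (is.data.frame(probs)) {
    labels <- probs$class
    probs <- probs$prob
  }
  if (length(probs) != length(labels)) {
    abort("`probs` and `labels` must be aligned.")
  }
  if (!(pi > 0 && pi < 1)) abort("`pi` must lie in (0, 1).")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) abort("Labels must contain exactly two classes.")
  pos <- if (!is.null(positive_class)) {
    if (!positive_class %in% classes) abort("`positive_class` not among labels.")
    positive_class
  } else if ("adaptive" %in% classes) "adaptive" else classes[1]
  y <- labels == pos
  n <- length(y)
  n1 <- sum(y)
  n0 <- n - n1

  pred <- probs >= 0.5
  TP <- sum(pred & y); FP <- sum(pred & !y)
  TN <- sum(!pred & !y); FN <- sum(!pred & y)
  accuracy <- (TP + TN) / n
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  sensitivity <- TP / (TP + FN)
  specificity <- TN / (TN + FP)
  ppv_adj <- sensitivity * pi / (sensitivity * pi + (1 - specificity) * (1 - pi))
  npv_adj <- specificity * (1 - pi) /
    (specificity * (1 - pi) + (1 - sensitivity) * pi)

  auc <- auc_mannwhitney(probs, y)
  auc_se <- hanley_mcneil_se(auc, n1, n0)
  wald <- function(p) {
    se <- sqrt(p * (1 - p) / n)
    c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
  }
  ci <- list(
    auc = c(max(0, auc - 1.96 * auc_se), min(1, auc + 1.96 * auc_se)),
    accuracy = wald(accuracy),
    precision = if (is.na(precision)) c(NA_real_, NA_real_) else wald(precision),
    sensitivity = wald(sensitivity),
    specificity = wald(specificity)
  )
  metrics <- tibble(
    metric = c("auc", "accuracy", "precision", "sensitivity", "specificity",
               "ppv_adj", "npv_adj"),
    estimate = c(auc, accuracy, precision, sensitivity, specificity,
                 ppv_adj, npv_adj),
    conf_low = c(ci$auc[1], ci$accuracy[1], ci$precision[1],
                 ci$sensitivity[1], ci$specificity[1], NA, NA),
    conf_high = c(ci$auc[2], ci$accuracy[2], ci$precision[2],
                  ci$sensitivity[2], ci$specificity[2], NA, NA)
  )
  structure(
    list(confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
         metrics = metrics, auc = auc,
         roc = roc_points(probs, y),
         prevalence = pi, positive_class = pos,
         probs = probs, labels = labels,
         loo_error = 1 - accuracy, n = n),
    class = "evaluation_report"
  )
}

# Trapezoidal AUC over the pooled ROC with midpoint tie handling, via the
# rank (Mann-Whitney) identity.
auc_mannwhitney <- function(probs, y) {
  r <- rank(probs, ties.method = "average")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes.")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

hanley_mcneil_se <- function(A, n1, n0) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n0 - 1) * (Q2 - A^2)) /
         (n1 * n0))
}

roc_points <- function(probs, y) {
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  pts <- vapply(thr, function(t) {
    c(fpr = sum(probs >= t & !y) / max(1, sum(!y)),
      tpr = sum(probs >= t & y) / max(1, sum(y)))
  }, numeric(2))
  tibble(threshold = thr, fpr = pts["fpr", ], tpr = pts["tpr", ])
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, positive class '%s'\n",
              x$n, x$positive_class))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    ci <- if (!is.na(m$conf_low[i])) {
      sprintf(" (95%% CI %.3f-%.3f)", m$conf_low[i], m$conf_high[i])
    } else ""
    cat(sprintf("  %-12s %.3f%s\n", m$metric[i], m$estimate[i], ci))
  }
  if (!is.null(x$b632plus_error)) {
    cat(sprintf("  %-12s %.3f\n", ".632+ error", x$b632plus_error))
  }
  invisible(x)
}

#' @rdname compute_metrics
#' @param x,object An `evaluation_report`.
#' @param ... Unused.
#' @export
tidy.evaluation_report <- function(x, ...) x$metrics

#' @rdname compute_metrics
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(n = x$n, auc = x$auc,
         accuracy = x$metrics$estimate[x$metrics$metric == "accuracy"],
         loo_error = x$loo_error,
         b632plus_error = x$b632plus_error %||% NA_real_,
         prevalence = x$prevalence)
}

#' The .632+ bootstrap error aggregation formula
#'
#' Blends the resubstitution error `err_bar` and the leave-one-out
#' bootstrap error `eps0` with the no-information error rate `gamma`:
#' relative overfitting `R = (eps0 - err_bar) / (gamma - err_bar)`, clipped
#' to `[0, 1]` and set to 0 when the denominator is non-positive; weight
#' `w = 0.632 / (1 - 0.368 R)`; estimate
#' `(1 - w) err_bar + w min(eps0, gamma)`. With `eps0 = err_bar` this
#' reduces to the classical .632 estimator.
#'
#' @param err_bar Resubstitution error in `[0, 1]`.
#' @param eps0 Leave-one-out bootstrap error in `[0, 1]`.
#' @param gamma No-information error rate in `[0, 1]`.
#' @return The .632+ error estimate.
#' @export
b632plus_combine <- function(err_bar, eps0, gamma) {
  denom <- gamma - err_bar
  R <- if (denom <= 0) 0 else (eps0 - err_bar) / denom
  R <- min(1, max(0, R))
  w <- 0.632 / (1 - 0.368 * R)
  (1 - w) * err_bar + w * min(eps0, gamma)
}

#' .632+ bootstrap error of the final classifier
#'
#' Estimates the prediction error of the Random Forest on the signature by
#' the .632+ rule: the resubstitution error is computed by training and
#' testing on the full table; the leave-one-out bootstrap error is, for
#' each row, the mean error over the bootstrap replicates in which the row
#' is out-of-bag (rows never out-of-bag are excluded); the no-information
#' rate is `gamma = sum_k phat_k (1 - qhat_k)` over classes, with observed
#' proportions `phat` and resubstitution-predicted proportions `qhat`;
#' the three are blended by [b632plus_combine()].
#'
#' @inheritParams loo_predict
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Seed for the bootstrap resampling; replicate b refits the
#'   forest with seed `seed + b`.
#' @return The scalar .632+ error estimate, with attributes `err_bar`,
#'   `eps0`, `gamma`.
#' @export
bootstrap_632plus <- function(tab, signature, params = rf_params(),
                              B = 200L, seed = 1L, positive_class = NULL) {
  tab <- validate_feature_table(tab)
  if (B < 2L) abort("`B` must be at least 2.")
  n <- nrow(tab)
  pos <- positive_label(tab, positive_class)
  y <- as.integer(as.character(tab$class) == pos)

  resub <- rf_predict(tab, tab, signature, params, pos) >= 0.5
  err_bar <- mean(resub != (y == 1L))

  q1 <- mean(resub)               # predicted positive proportion
  p1 <- mean(y)                   # observed positive proportion
  gamma <- p1 * (1 - q1) + (1 - p1) * q1

  err_cnt <- numeric(n)
  oob_cnt <- numeric(n)
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(oob) == 0L) next
      boot <- tab[idx, , drop = FALSE]
      if (length(unique(boot$class)) < 2L) next  # degenerate resample
      pr <- rf_predict(boot, tab[oob, , drop = FALSE], signature,
                       rf_params(params$n_trees, params$m, seed + b), pos)
      wrong <- (pr >= 0.5) != (y[oob] == 1L)
      err_cnt[oob] <- err_cnt[oob] + wrong
      oob_cnt[oob] <- oob_cnt[oob] + 1L
    }
  })
  covered <- oob_cnt > 0
  if (!any(covered)) abort("No row was ever out-of-bag; increase B.")
  eps0 <- mean(err_cnt[covered] / oob_cnt[covered])

  out <- b632plus_combine(err_bar, eps0, gamma)
  attr(out, "err_bar") <- err_bar
  attr(out, "eps0") <- eps0
  attr(out, "gamma") <- gamma
  out
}

#' Evaluate a signature end to end
#'
#' Convenience wrapper running [loo_predict()], [compute_metrics()] and
#' [bootstrap_632plus()] on one table + signature.
#'
#' @inheritParams loo_predict
#' @param pi Assumed prevalence for adjusted predictive values.
#' @param B Bootstrap replicates (`0` skips the .632+ estimate).
#' @param seed Seed for the bootstrap stage.
#' @return An `evaluation_report` with `b632plus_error` filled in (and the
#'   out-of-fold predictions in `$predictions`).
#' @export
evaluate_model <- function(tab, signature, params = rf_params(),
                           pi = 0.40, B = 200L, seed = 1L,
                           positive_class = NULL) {
  preds <- loo_predict(tab, signature, params, positive_class)
  rep <- compute_metrics(preds$prob, preds$class, positive_class, pi)
  rep$predictions <- preds
  rep$signature <- signature
  if (B >= 2L) {
    rep$b632plus_error <- as.numeric(
      bootstrap_632plus(tab, signature, params, B, seed, positive_class)
    )
  }
  rep
}
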