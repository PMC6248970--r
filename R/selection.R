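#' Wrapper feature-subset search on one training table
#'
#' Greedy forward best-first search whose objective is the classifier
#' itself: starting from the empty set, each step evaluates adding every
#' unused feature by the mean accuracy of a Random Forest over a
#' stratified 2-fold cross-validation of the training table, accepts the
#' best candidate, and stops after 5 consecutive expansions that fail to
#' improve on the best subset seen so far (best-first backtracking limit).
#' Ties break by table (registry) order. The baseline to beat is the
#' majority-class rate, so the returned subset may be empty on pure noise.
#'
#' @param train A feature table with at least 4 rows and both classes.
#' @param params [rf_params()] for the wrapper-internal forest (the
#'   protocol uses a cheaper forest here than in the final model).
#' @param seed Integer seed driving the fold split and all forest
#'   randomness; the search is deterministic given it.
#' @param features Candidate features (default: all feature columns).
#' @param positive_class See [rf_predict()].
#' @param backtrack Consecutive non-improving expansions tolerated.
#' @return Character vector of selected feature names (possibly empty).
#' @export
wrapper_search <- function(train, params = rf_params(n_trees = 100L),
                           seed = 1L, features = table_feature_names(train),
                           positive_class = NULL, backtrack = 5L) {
  train <- validate_feature_table(train)
  if (nrow(train) < 4L) abort("Wrapper search needs at least 4 training rows.")
  pos <- positive_label(train, positive_class)
  y <- as.integer(as.character(train$class) == pos)
  if (all(y == 0L) || all(y == 1L)) {
    abort("Training fold contains a single class; wrapper search undefined.")
  }

  fold <- stratified_2fold(y, seed)
  Xall <- as_feature_matrix(train, features)
  baseline <- max(mean(y), 1 - mean(y))

  cv_acc <- function(cols, step_seed) {
    acc <- 0
    for (f in 1:2) {
      tr <- fold != f
      te <- fold == f
      m <- resolve_mtry(NULL, length(cols))
      pr <- .rf_fit_predict(Xall[tr, cols, drop = FALSE], y[tr],
                            Xall[te, cols, drop = FALSE],
                            params$n_trees, m, as.double(step_seed))
      acc <- acc + sum((pr >= 0.5) == (y[te] == 1L))
    }
    acc / length(y)
  }

  current <- integer(0)
  best_subset <- integer(0)
  best_acc <- baseline
  no_improve <- 0L
  step <- 0L
  repeat {
    cand <- setdiff(seq_along(features), current)
    if (length(cand) == 0L || no_improve >= backtrack) break
    step <- step + 1L
    step_seed <- as.double(seed) * 131071 + step  # same forest seed for all candidates
    accs <- vapply(cand, function(j) cv_acc(c(current, j), step_seed),
                   numeric(1))
    pick <- cand[which.max(accs)]   # ties -> lowest index = registry order
    current <- c(current, pick)
    if (max(accs) > best_acc + 1e-12) {
      best_acc <- max(accs)
      best_subset <- current
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
  }
  features[best_subset]
}

# Deterministic stratified 2-fold assignment: within each class, a seeded
# permutation alternates fold labels.
stratified_2fold <- function(y, seed) {
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(1:2, length(idx))
    }
  })
  fold
}

#' Leave-one-out wrapped feature selection
#'
#' The signature-selection protocol: an outer leave-one-out loop removes
#' one patient at a time and runs [wrapper_search()] on the remaining
#' rows; the selection frequency of a feature is the fraction of the n
#' folds in which the wrapper chose it, and the final signature contains
#' every feature with frequency at least `tau` (default 10% of the LOO
#' iterations), ordered by frequency (descending), ties by registry
#' order.
#'
#' @param tab A feature table with n >= 3 rows and both classes.
#' @param params [rf_params()] for the wrapper-internal forest.
#' @param tau Selection-frequency threshold in (0, 1].
#' @param seed Master seed; fold i uses `seed + i`.
#' @param features Candidate features (default: all).
#' @param positive_class See [rf_predict()].
#' @return An object of class `selection_report`: list with
#'   `per_fold_subsets` (length n), `frequencies` (tibble: `feature`,
#'   `n_folds`, `frequency`), `signature`, `tau`, `seed`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
loo_wrapper_selection <- function(tab, params = rf_params(n_trees = 100L),
                                  tau = 0.10, seed = 1L,
                                  features = table_feature_names(tab),
                                  positive_class = NULL) {
  tab <- validate_feature_table(tab)
  n <- nrow(tab)
  if (n < 3L) abort("Leave-one-out selection needs at least 3 rows.")
  if (!(tau > 0 && tau <= 1)) abort("`tau` must lie in (0, 1].")

  per_fold <- vector("list", n)
  for (i in seq_len(n)) {
    per_fold[[i]] <- wrapper_search(tab[-i, , drop = FALSE], params,
                                    seed = seed + i, features = features,
                                    positive_class = positive_class)
  }
  counts <- table(factor(unlist(per_fold), levels = features))
  freq <- tibble(
    feature = features,
    n_folds = as.integer(counts),
    frequency = as.integer(counts) / n
  )
  sig <- freq %>%
    mutate(.ord = seq_len(nrow(freq))) %>%
    filter(.data$frequency >= tau) %>%
    arrange(desc(.data$frequency), .data$.ord)
  structure(
    list(per_fold_subsets = per_fold,
         frequencies = freq,
         signature = sig$feature,
         tau = tau, seed = as.integer(seed), n = n),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %d LOO folds, tau = %.2f -> signature of %d feature(s)\n",
    x$n, x$tau, length(x$signature)
  ))
  if (length(x$signature)) {
    cat(paste0("  ", utils::head(x$signature, 15), collapse = "\n"), "\n")
    if (length(x$signature) > 15) cat(sprintf("  ... and %d more\n", length(x$signature) - 15))
  }
  invisible(x)
}

#' @rdname loo_wrapper_selection
#' @param x,object A `selection_report`.
#' @param ... Unused.
#' @export
tidy.selection_report <- function(x, ...) {
  x$frequencies %>%
    mutate(in_signature = .data$feature %in% x$signature) %>%
    arrange(desc(.data$frequency))
}

#' @rdname loo_wrapper_selection
#' @export
glance.selection_report <- function(x, ...) {
  tibble(n_folds = x$n, tau = x$tau,
         n_signature = length(x$signature),
         mean_subset_size = mean(lengths(x$per_fold_subsets)),
         seed = x$seed)
}
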