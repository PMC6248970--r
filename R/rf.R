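#' Fit a Random Forest and predict positive-class probabilities
#'
#' The ensemble used throughout the pipeline: CART trees grown on
#' bootstrap samples, each split drawn from a random subset of m features
#' (m < p), class vote per tree; the predicted probability is the fraction
#' of trees voting positive. The implementation is self-contained and
#' deterministic for a given seed.
#'
#' @param train A feature table (the training rows).
#' @param test A feature table of rows to score (may equal `train`).
#' @param features Character vector of feature columns to use.
#' @param params An [rf_params()].
#' @param positive_class Label treated as positive; defaults to
#'   `"adaptive"` when present.
#' @return Numeric vector of positive-class probabilities, one per test
#'   row.
#' @export
rf_predict <- function(train, test, features, params = rf_params(),
                       positive_class = NULL) {
  pos <- positive_label(train, positive_class)
  missing_f <- setdiff(features, names(train))
  if (length(missing_f)) {
    abort(sprintf("Unknown feature(s): %s",
                  paste(utils::head(missing_f, 5), collapse = ", ")))
  }
  X <- as_feature_matrix(train, features)
  Xt <- as_feature_matrix(test, features)
  y <- as.integer(as.character(train$class) == pos)
  # single-class training (possible in extreme LOO folds) is allowed: every
  # tree is a root leaf voting the only observed class
  m <- resolve_mtry(params$m, length(features))
  .rf_fit_predict(X, y, Xt, params$n_trees, m, as.double(params$seed))
}

as_feature_matrix <- function(tab, features) {
  X <- as.matrix(as.data.frame(tab, check.names = FALSE)[, features, drop = FALSE])
  if (anyNA(X)) {
    # semantic unknowns arrive as NA only from tables built without
    # records; trees cannot route missing values, so code them as the
    # sentinel used for "unknown" categories
    X[is.na(X)] <- -1
  }
  storage.mode(X) <- "double"
  X
}
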