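#' Run selection and evaluation on a feature table
#'
#' Orchestrates the modelling half of the workflow: (optionally ablated)
#' leave-one-out wrapper selection at threshold `tau`, then evaluation of
#' the resulting signature by pooled leave-one-out ROC analysis and the
#' .632+ bootstrap. Ablations re-run the full selection with the named
#' feature family removed and the same threshold, mirroring the published
#' comparison rows (`no_semantic`, `no_glcm`, `no_lbp`, `only_semantic`).
#'
#' @param tab A feature table.
#' @param config A [run_config()].
#' @param ablate Which feature family to drop before selection.
#' @param positive_class See [rf_predict()].
#' @return An object of class `signature_run`: list with `selection` (a
#'   `selection_report`), `evaluation` (an `evaluation_report`),
#'   `signature`, `config`, `ablate` and a `manifest` (timing, sizes,
#'   seeds).
#' @export
run_signature_pipeline <- function(tab, config = run_config(),
                                   ablate = c("none", "no_semantic",
                                              "no_glcm", "no_lbp",
                                              "only_semantic"),
                                   positive_class = NULL) {
  ablate <- match.arg(ablate)
  tab <- validate_feature_table(tab)
  feats <- table_feature_names(tab)
  fam <- feature_family(feats)
  feats <- switch(ablate,
    none = feats,
    no_semantic = feats[fam != "semantic"],
    no_glcm = feats[fam != "glcm"],
    no_lbp = feats[fam != "lbptop"],
    only_semantic = feats[fam == "semantic"]
  )
  if (length(feats) == 0L) {
    abort(sprintf("Ablation '%s' removed every feature column.", ablate))
  }

  t0 <- Sys.time()
  sel <- loo_wrapper_selection(
    tab, rf_params(config$wrapper_trees, seed = config$seed),
    tau = config$tau, seed = config$seed, features = feats,
    positive_class = positive_class
  )
  t1 <- Sys.time()
  if (length(sel$signature) == 0L) {
    abort(sprintf(
      "No feature reached selection frequency tau = %.2f; nothing to evaluate.",
      config$tau))
  }
  eval <- evaluate_model(
    tab, sel$signature,
    rf_params(config$n_trees, config$m, config$seed),
    pi = config$prevalence, B = config$B, seed = config$seed,
    positive_class = positive_class
  )
  t2 <- Sys.time()

  structure(
    list(selection = sel, evaluation = eval, signature = sel$signature,
         config = config, ablate = ablate,
         manifest = list(
           n = nrow(tab), p = length(feats), seed = config$seed,
           selection_seconds = as.numeric(t1 - t0, units = "secs"),
           evaluation_seconds = as.numeric(t2 - t1, units = "secs")
         )),
    class = "signature_run"
  )
}

#' @export
print.signature_run <- function(x, ...) {
  cat(sprintf("<signature_run> ablation '%s', n = %d, p = %d\n",
              x$ablate, x$manifest$n, x$manifest$p))
  print(x$selection)
  print(x$evaluation)
  invisible(x)
}

#' @rdname run_signature_pipeline
#' @param x,object A `signature_run`.
#' @param ... Unused.
#' @export
glance.signature_run <- function(x, ...) {
  bind_cols(tibble(ablate = x$ablate), glance(x$evaluation),
            glance(x$selection)[c("n_signature", "tau")])
}

#' Serialize a run's reports to JSON
#'
#' Writes the selection report (per-fold subsets, frequencies, signature)
#' and the evaluation report (metrics, confusion counts, errors) plus the
#' resolved configuration to a JSON file.
#'
#' @param run A `signature_run`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "signature_run"))
  out <- list(
    config = unclass(run$config),
    ablate = run$ablate,
    selection = list(
      tau = run$selection$tau,
      seed = run$selection$seed,
      frequencies = run$selection$frequencies,
      per_fold_subsets = run$selection$per_fold_subsets,
      signature = run$selection$signature
    ),
    evaluation = list(
      n = run$evaluation$n,
      confusion = as.list(run$evaluation$confusion),
      metrics = run$evaluation$metrics,
      loo_error = run$evaluation$loo_error,
      b632plus_error = run$evaluation$b632plus_error,
      prevalence = run$evaluation$prevalence
    ),
    manifest = run$manifest
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Re-run selection and evaluation on a deposited ARFF dataset
#'
#' Optional validation path for an externally extracted feature dataset
#' (e.g. the deposited `.arff` supplement of the original study): reads
#' the table, runs the full selection + leave-one-out evaluation, and
#' returns the metrics for side-by-side inspection. No equality with the
#' published numbers is asserted -- the original forest hyperparameters
#' and search internals are unspecified and the classifier is stochastic.
#'
#' @param path Path to an ARFF (or CSV) feature table.
#' @param config A [run_config()].
#' @param positive_class Label counted as positive; defaults to
#'   `"adaptive"` if present, else the first level.
#' @return The `signature_run`.
#' @export
validate_external_arff <- function(path, config = run_config(),
                                   positive_class = NULL) {
  tab <- read_feature_table(path)
  run_signature_pipeline(tab, config, positive_class = positive_class)
}
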