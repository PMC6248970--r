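#!/usr/bin/env Rscript

# Optional validation against an externally deposited feature dataset
# (ARFF or CSV with a two-valued class attribute): re-runs the wrapper
# feature selection and the LOO + .632+ evaluation and prints the metric
# suite for side-by-side comparison with published values. No equality is
# asserted: the original forest hyperparameters and search internals are
# unspecified and the classifier is stochastic.
#
# Usage: Rscript scripts/s1_validation.R <dataset.arff> [--seed <int>]
#        [--tau <frac>] [--out <report.json>]

suppressMessages(library(radsig))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("Usage: Rscript scripts/s1_validation.R <dataset.arff> [--seed <int>] [--tau <frac>] [--out <path>]")
}
path <- args[1]
opt <- list(seed = 1L, tau = 0.10, out = NULL)
i <- 2L
while (i <= length(args)) {
  if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2L }
  else if (args[i] == "--tau") { opt$tau <- as.numeric(args[i + 1]); i <- i + 2L }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2L }
  else stop("Unknown argument: ", args[i])
}

cfg <- run_config(tau = opt$tau, seed = opt$seed)
run <- validate_external_arff(path, cfg)

cat("Signature (", length(run$signature), " features):\n", sep = "")
print(tidy(run$selection), n = 20)
cat("\nEvaluation:\n")
print(run$evaluation)

if (!is.null(opt$out)) {
  write_run_report(run, opt$out)
  cat("\nreport written to ", opt$out, "\n", sep = "")
}
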