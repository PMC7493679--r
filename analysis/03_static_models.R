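#!/usr/bin/env Rscript
# Non-biomimetic models (SVM kernels, random decision forest) on the two
# static representations: four first-order statistics per dimension, and
# the twelve clinical spatiotemporal gait metrics.

suppressPackageStartupMessages(library(gaitlab))

dataset <- load_dataset("scratch/data/manifest.csv")

res <- run_experiment(3, dataset, config = list(
  ks = c(1, 5, 10), replicates = 3, folds = 3, seed = 7
))
write.csv(res, "results/sweep_static.csv", row.names = FALSE)

s <- summarize_sweep(res)
print(s, n = Inf)

# duration sensitivity of the static families: slope of accuracy over k
cat("\nDuration sensitivity (slope of replicate accuracy on k):\n")
ra <- replicate_accuracy(res)
for (fam in unique(ra$family)) {
  d <- ra[ra$family == fam & ra$representation == "static4", ]
  fit <- summary(lm(accuracy ~ k, data = d))$coefficients
  cat(sprintf(
    "%-12s slope = %+.4f / k, p = %.3f\n", fam, fit["k", 1], fit["k", 4]
  ))
}
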