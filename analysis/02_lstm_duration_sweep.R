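#!/usr/bin/env Rscript
# LSTM exposure-duration sweep on 3D joint positions: does accuracy grow
# with the amount of gait observed, as it does for human observers?
#
# Desk scale: window lengths k in {1, 4, 7, 10} (10..100 frames), 3
# replicates x 3 subject-wise folds, a 32-unit cell trained for 25 epochs.

suppressPackageStartupMessages(library(gaitlab))

dataset <- load_dataset("scratch/data/manifest.csv")
cat(sprintf("loaded %d sequences\n", length(dataset)))

res <- run_experiment(2, dataset, config = list(
  ks = c(1, 4, 7, 10), replicates = 3, folds = 3, seed = 7,
  lstm = list(hidden_size = 32, epochs = 25)
))
write.csv(res, "results/sweep_lstm_position.csv", row.names = FALSE)

s <- summarize_sweep(res)
print(s)
cat("\nTrend: accuracy at the longest vs shortest exposure\n")
ra <- replicate_accuracy(res)
a1 <- ra$accuracy[ra$k == 1]
a10 <- ra$accuracy[ra$k == 10]
cat(sprintf(
  "k=1: %.3f  k=10: %.3f  (paired one-sided t, p = %.3g)\n",
  mean(a1), mean(a10), t.test(a10, a1, paired = TRUE, alternative = "greater")$p.value
))
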