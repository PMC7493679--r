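#!/usr/bin/env Rscript
# Velocity cues and coronal (2D) input: train the LSTM on temporal
# derivatives of the smoothed trajectories, and on 2D projections, to ask
# whether the sequence model shares the human preference for dynamic
# velocity-based cues and whether depth information matters.

suppressPackageStartupMessages(library(gaitlab))

dataset <- load_dataset("scratch/data/manifest.csv")

cfg <- list(
  cells = tibble::tibble(
    family = "lstm",
    representation = c("position3d", "velocity3d", "position2d", "velocity2d")
  ),
  ks = 5, replicates = 3, folds = 3, seed = 7,
  lstm = list(hidden_size = 32, epochs = 25)
)
res <- run_experiment(4, dataset, cfg)
write.csv(res, "results/sweep_velocity_2d.csv", row.names = FALSE)

s <- summarize_sweep(res)
print(s)

ra <- replicate_accuracy(res)
acc <- function(rep) ra$accuracy[ra$representation == rep]
cat(sprintf(
  "\nvelocity vs position (3D): %.3f vs %.3f; variance-ratio F: ",
  mean(acc("velocity3d")), mean(acc("position3d"))
))
print(ftest_between(acc("velocity3d"), acc("position3d")))
cat(sprintf(
  "2D vs 3D position: %.3f vs %.3f (two-sample t, p = %.3f)\n",
  mean(acc("position2d")), mean(acc("position3d")),
  t.test(acc("position2d"), acc("position3d"))$p.value
))
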