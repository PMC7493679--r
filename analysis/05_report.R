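#!/usr/bin/env Rscript
# Summary report: pooled tables, significance against chance, and the
# accuracy-versus-duration figure over every sweep computed so far.

suppressPackageStartupMessages({
  library(gaitlab)
  library(dplyr)
})

files <- Sys.glob("results/sweep_*.csv")
if (!length(files)) stop("no sweep results found; run analyses 02-04 first")

res <- bind_rows(lapply(files, read.csv)) |> tibble::as_tibble()
class(res) <- c("sweep_result", class(res))

summary <- summarize_sweep(res)
write.csv(summary, "results/summary.csv", row.names = FALSE)
print(summary, n = Inf)

tests <- sweep_tests(res)
write.csv(tests, "results/tests.csv", row.names = FALSE)
cat("\nCells significantly above chance (two-tailed t, p < 0.05):\n")
print(tests |> filter(p_value < 0.05) |> arrange(desc(mean_accuracy)), n = Inf)

gg <- plot_accuracy_vs_duration(summary)
ggplot2::ggsave("results/accuracy_vs_duration.png", gg, width = 7, height = 4.5, dpi = 150)
cat("\nwrote results/summary.csv, results/tests.csv, results/accuracy_vs_duration.png\n")
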