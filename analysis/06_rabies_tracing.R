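#!/usr/bin/env Rscript
# Quantification of the simulated rabies traced-cell table: brain-wide input
# fractions with the >1% reporting filter, starter-cell layer distribution,
# and V1 local inputs normalized across layers.

suppressPackageStartupMessages(library(calciumflow))
dir.create("results/tracing", recursive = TRUE, showWarnings = FALSE)
cells <- read.csv("results/traced_cells.csv")

fr <- input_fractions(cells)
data.table::fwrite(fr, "results/tracing/input_fractions.csv")
cat(sprintf("%d input cells across %d region-hemisphere entries (sum %.1f%%)\n",
            sum(fr$count), nrow(fr), sum(fr$percent)))
cat("Reported regions (>1% of inputs):\n")
rep_fr <- fr[fr$reported, ]
for (i in seq_len(nrow(rep_fr)))
  cat(sprintf("  %-6s %-6s %5.1f%%\n", rep_fr$region[i], rep_fr$hemisphere[i],
              rep_fr$percent[i]))

sl <- starter_layer_distribution(cells)
ll <- local_layer_fractions(cells)
write.csv(data.frame(layer = names(sl), starter_fraction = as.numeric(sl)),
          "results/tracing/starter_layers.csv", row.names = FALSE)
write.csv(data.frame(layer = names(ll), local_input_fraction = as.numeric(ll)),
          "results/tracing/local_layers.csv", row.names = FALSE)
cat("Starter layer distribution: ",
    paste(sprintf("%s %.0f%%", names(sl), 100 * sl), collapse = ", "), "\n")
cat("Local V1 input layers:      ",
    paste(sprintf("%s %.0f%%", names(ll), 100 * ll), collapse = ", "), "\n")
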