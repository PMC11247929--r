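#!/usr/bin/env Rscript
# Simulate the three session types the downstream analyses consume, plus a
# rabies traced-cell table.  Session containers (with their full fluorescence
# matrices) go under scratch/sessions; the traced-cell table, which is plain
# tabular data, goes under results/.

suppressPackageStartupMessages(library(calciumflow))
dir.create("scratch/sessions", recursive = TRUE, showWarnings = FALSE)
dir.create("results", recursive = TRUE, showWarnings = FALSE)

seed <- 20260930

cat("Spontaneous session: 20 locomotion-coupled + 20 uncoupled neurons, 730 s\n")
sp <- simulate_session("spontaneous",
                       neurons = gt_population_spontaneous(20, 20),
                       seed = seed)
write_session(sp, "scratch/sessions/spontaneous")
cat(sprintf("  %d neurons x %d frames; mouse ran %.0f%% of the time\n",
            nrow(sp$fluorescence$f_soma), ncol(sp$fluorescence$f_soma),
            100 * mean(sp$behavior$speed > 1)))

cat("Orientation session: 40 tuned + 40 non-visual neurons, 12 x 10 trials\n")
ori <- simulate_session("orientation",
                        neurons = gt_population_orientation(40, 40, seed = seed + 1),
                        seed = seed + 2)
write_session(ori, "scratch/sessions/orientation")
cat(sprintf("  %d trials over %.0f s\n", nrow(ori$schedule$trials),
            ori$schedule$duration_s))

cat("Contrast session: 50 increasing + 50 decreasing + 20 non-visual neurons\n")
con <- simulate_session("contrast",
                        neurons = gt_population_contrast(50, 50, 20,
                                                         seed = seed + 3),
                        seed = seed + 4)
write_session(con, "scratch/sessions/contrast")
cat(sprintf("  %d grating trials + %d blanks\n",
            sum(!con$schedule$trials$blank), sum(con$schedule$trials$blank)))

cat("Traced-cell table: 5000 inputs, 40 starters\n")
cells <- gen_traced_cells(default_tracing_spec(5000, 40), seed = seed + 5)
data.table::fwrite(cells, "results/traced_cells.csv")
cat(sprintf("  %d rows -> results/traced_cells.csv\n", nrow(cells)))
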