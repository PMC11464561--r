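#!/usr/bin/env Rscript
# Stage 1: generate the study landscape and occurrence records.
#
# Builds the default synthetic arid-mountain climate stack (240 x 240 cells
# at ~30 arc-sec), computes the true suitability surface, draws 164
# presence points proportional to it, and writes everything under
# results/: the stack as ASCII grids, the occurrences as CSV.

library(aridrange)

seed <- 42
dir.create("results", showWarnings = FALSE)

sc <- synthetic_scenario(seed = seed)
st <- make_stack(sc)
suit <- true_suitability(st, sc$coef)
occ <- sample_presences(st, suit, sc$n_occurrences, seed + 10L)

write_stack(st, "results/stack")
write_asc(suit, "results/stack/true_suitability.asc",
          st$xll, st$yll, st$cellsize)
utils::write.csv(as.data.frame(occ), "results/occurrences.csv",
                 row.names = FALSE)

ex <- extract_at_points(st, occ)
message(sprintf("landscape: %d x %d cells, %d occurrences drawn", st$nrow,
                st$ncol, nrow(occ)))
message(sprintf("climate at presences: MAP %.0f mm (range %.0f-%.0f), MAT %.1f C, P_cold %.0f mm, P_warm %.0f mm",
                mean(ex$MAP), min(ex$MAP), max(ex$MAP), mean(ex$MAT),
                mean(ex$P_cold), mean(ex$P_warm)))
message("wrote results/stack/ and results/occurrences.csv")
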