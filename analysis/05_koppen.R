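#!/usr/bin/env Rscript
# Stage 5: Koppen-Geiger arid-climate classification.
#
# Classifies every cell of the stack and every occurrence point into
# BWk / BSk / other (hot arid subtypes folded into "other"), writes the
# class raster with a legend, and the point-level class counts for both
# the full and the thinned occurrence sets.

library(aridrange)

layer_names <- c("MAT", "MAP", "P_cold", "P_warm", "P_winter", "P_summer",
                 "elevation")
st <- read_stack(setNames(
  file.path("results/stack", paste0(layer_names, ".asc")), layer_names))
occ <- read_points("results/occurrences.csv")
thinned <- read_points("results/thinned.csv")

cls <- classify_stack(st)
codes <- matrix(match(cls, c("BWk", "BWh", "BSk", "BSh", "other")),
                nrow(cls), ncol(cls))
write_asc(codes, "results/koppen_classes.asc", st$xll, st$yll, st$cellsize)
writeLines(c("code class", paste(1:5, c("BWk", "BWh", "BSk", "BSh", "other"))),
           "results/koppen_classes.asc.legend.txt")

for (set in list(list(name = "all", pts = occ),
                 list(name = "thinned", pts = thinned))) {
  res <- classify_points(st, set$pts)
  utils::write.csv(res$counts,
                   sprintf("results/koppen_counts_%s.csv", set$name),
                   row.names = FALSE)
  msg <- paste(sprintf("%s %d (%.0f%%)", res$counts$class, res$counts$n,
                       res$counts$pct), collapse = ", ")
  message(sprintf("%-7s occurrences: %s", set$name, msg))
}
message("wrote results/koppen_classes.asc and koppen_counts_*.csv")
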