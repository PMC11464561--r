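#!/usr/bin/env Rscript
# Stage 4: threshold and categorize the representative suitability maps.
#
# For the cold-desert representative model {MAT, MAP, P_cold}, the
# cold-steppe representative {MAT, MAP, P_warm}, and the AICc top model of
# the random partition: find the maximum-TSS threshold on cloglog output,
# carve the within-threshold value range into nested fringe / low /
# moderate / high bands (upper 90/70/30% retentions), write the category
# rasters, and tabulate all 164 occurrences per category with per-category
# climate summaries. Also writes the thinned-location climate summary.

library(aridrange)

layer_names <- c("MAT", "MAP", "P_cold", "P_warm", "P_winter", "P_summer",
                 "elevation")
st <- read_stack(setNames(
  file.path("results/stack", paste0(layer_names, ".asc")), layer_names))
occ <- read_points("results/occurrences.csv")
thinned <- read_points("results/thinned.csv")

region <- buffer_region(st, thinned, 400)
bg <- sample_background(st, region, 10000, seed = 1003)
pt <- partition(thinned, "random", seed = 1002)
rk <- rank_models(st, thinned, pt, bg)
models <- attr(rk, "models")

targets <- unique(c("MAT+MAP+P_cold", "MAT+MAP+P_warm", rk$model[1]))
ex_all <- extract_at_points(st, occ)
ex_all <- ex_all[ex_all$valid, ]

for (nm in targets) {
  m <- models[[nm]]
  fs <- m$features
  sc_pres <- predict_cloglog(m, feature_matrix(fs, ex_all))
  sc_bg <- predict_cloglog(m, feature_matrix(fs, bg$points))
  thr <- tss_threshold(sc_pres, sc_bg)
  surf <- predict_stack(m, st)
  cmap <- categorize(surf, thr$threshold)
  tag <- gsub("[+]", "_", nm)
  write_category_map(cmap, sprintf("results/categories_%s.asc", tag),
                     st$xll, st$yll, st$cellsize)
  tb <- category_counts_at_points(cmap, st, occ)
  utils::write.csv(tb$counts, sprintf("results/category_counts_%s.csv", tag),
                   row.names = FALSE)
  utils::write.csv(tb$stats, sprintf("results/category_stats_%s.csv", tag),
                   row.names = FALSE)
  hi <- tb$counts[tb$counts$class == "high", ]
  message(sprintf(
    "%-25s TSS threshold %.3f (TSS %.2f); %d/%d occurrences (%.0f%%) in 'high'",
    nm, thr$threshold, thr$tss, hi$n, sum(tb$counts$n), hi$pct))
}

# climate summary at the thinned locations
ex_th <- extract_at_points(st, thinned)
ex_th <- ex_th[ex_th$valid, ]
summ <- do.call(rbind, lapply(
  c("MAP", "MAT", "P_cold", "P_warm", "P_winter", "P_summer"),
  function(v) cbind(data.frame(variable = v),
                    as.data.frame(summarize_variable(ex_th[[v]])))))
utils::write.csv(summ, "results/variable_summary_thinned.csv",
                 row.names = FALSE)
message("wrote category rasters/tables and results/variable_summary_thinned.csv")
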