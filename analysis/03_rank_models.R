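#!/usr/bin/env Rscript
# Stage 3: fit and rank all 15 variable-subset suitability models.
#
# For each of the four train/test partitioning schemes (random 50/50,
# above-median elevation, median longitude, median latitude), fits a
# maximum-entropy model on the training presences for every non-empty
# subset of {MAT, MAP, P_cold, P_warm}, scores train/test AUC against one
# shared 10,000-point background sampled within 400 km of the thinned
# points, refits on all presences, and ranks by AICc. Writes one ranking
# table per scheme.

library(aridrange)

st <- read_stack(file.path("results/stack",
                           paste0(c("MAT", "MAP", "P_cold", "P_warm",
                                    "P_winter", "P_summer", "elevation"),
                                  ".asc")) |>
                   setNames(c("MAT", "MAP", "P_cold", "P_warm",
                              "P_winter", "P_summer", "elevation")))
thinned <- read_points("results/thinned.csv")

region <- buffer_region(st, thinned, 400)
bg <- sample_background(st, region, 10000, seed = 1003)
message(sprintf("background: %d points over %d buffered cells",
                bg$n, sum(region)))

for (scheme in c("random", "elevation", "longitude", "latitude")) {
  pt <- partition(thinned, scheme, seed = 1002)
  tab <- rank_models(st, thinned, pt, bg)
  utils::write.csv(tab, sprintf("results/ranking_%s.csv", scheme),
                   row.names = FALSE)
  top <- tab[1, ]
  message(sprintf(
    "%-9s top model %-25s AICc %.1f (train AUC %.3f, test AUC %.3f)",
    scheme, top$model, top$aicc, top$auc_train, top$auc_test))
}
message("wrote results/ranking_<scheme>.csv")
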