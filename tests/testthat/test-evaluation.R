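test_that("median-based partitions follow the stated side conventions", {
  pts <- occurrence_set(data.frame(
    id = paste0("p", 1:4),
    lon = c(77.0, 77.1, 77.2, 77.3),
    lat = c(34.0, 34.1, 34.2, 34.3),
    elev = c(100, 200, 300, 400)))
  # longitude: train = west side (<= median)
  pl <- partition(pts, "longitude")
  expect_setequal(pl$train$id, c("p1", "p2"))
  expect_setequal(pl$test$id, c("p3", "p4"))
  # latitude analogous
  pa <- partition(pts, "latitude")
  expect_setequal(pa$train$id, c("p1", "p2"))
  # elevation: strictly above the median trains; the median point tests
  pts5 <- occurrence_set(data.frame(
    id = paste0("e", 1:5), lon = 77 + (1:5) / 100, lat = 34,
    elev = c(100, 200, 300, 400, 500)))
  pe <- partition(pts5, "elevation")
  expect_setequal(pe$train$id, c("e4", "e5"))
  expect_true("e3" %in% pe$test$id)
  expect_equal(pe$split_stat, 300)
  # a point exactly at the median longitude goes to train
  pm <- partition(pts5, "longitude")
  expect_true("e3" %in% pm$train$id)
})

test_that("random partition is a seeded half-split with odd point to train", {
  pts <- random_point_set(7)
  p1 <- partition(pts, "random", seed = 5)
  expect_equal(nrow(p1$train), 4)
  expect_equal(nrow(p1$test), 3)
  expect_identical(partition(pts, "random", seed = 5)$train$id, p1$train$id)
  expect_false(identical(partition(pts, "random", seed = 6)$train$id,
                         p1$train$id))
  expect_setequal(c(p1$train$id, p1$test$id), pts$id)
  expect_length(intersect(p1$train$id, p1$test$id), 0)
})

test_that("partition input validation", {
  pts <- random_point_set(3)
  expect_error(partition(pts, "random", seed = 1), "at least 4")
  pts4 <- random_point_set(4)
  expect_error(partition(pts4, "elevation"), "elevation")
  expect_error(partition(pts4, "random"), "seed")
})

test_that("AUC handles separation, ties, and the worked example", {
  expect_equal(auc(c(3, 4), c(1, 2)), 1)
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.3, 0.1)), 5 / 6)
  expect_error(auc(numeric(0), 1), "empty")
})

test_that("rank-based AUC equals brute-force pair counting with ties", {
  for (s in random_score_sets(seed = 11, n_sets = 60)) {
    expect_equal(auc(s$pres, s$bg), brute_auc(s$pres, s$bg),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  for (s in random_score_sets(seed = 12, n_sets = 20)) {
    a0 <- auc(s$pres, s$bg)
    expect_equal(auc(exp(3 * s$pres), exp(3 * s$bg)), a0, tolerance = 1e-12)
    expect_equal(auc(-1 / (1 + s$pres), -1 / (1 + s$bg)), a0,
                 tolerance = 1e-12)
  }
})

test_that("TSS threshold maximizes and breaks ties toward the smallest t", {
  r <- tss_threshold(c(0.8, 0.6), c(0.7, 0.2))
  expect_equal(r$tss, 0.5)
  expect_equal(r$threshold, 0.6)
  # perfect separation: TSS 1 at the smallest presence score
  r2 <- tss_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(r2$tss, 1)
  expect_equal(r2$threshold, 0.8)
  # identical sets: no skill at any threshold
  r3 <- tss_threshold(c(0.3, 0.5), c(0.3, 0.5))
  expect_equal(r3$tss, 0)
  expect_equal(r3$threshold, 0.3)
  expect_equal(tss_threshold(c(1, 1), c(1, 1))$tss, 0)
})

test_that("TSS sweep equals the exhaustive oracle on random sets", {
  for (s in random_score_sets(seed = 13, n_sets = 60)) {
    got <- tss_threshold(s$pres, s$bg)
    want <- brute_tss(s$pres, s$bg)
    expect_equal(got$tss, want$tss, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-100, 5, 50), 210 + 60 / 44)
  expect_equal(aicc(-77.5, 0, 50), 155)
  expect_equal(aicc(-100, 5, 1e9), -2 * -100 + 2 * 5, tolerance = 1e-6)
  expect_true(is.na(aicc(-100, 5, 6)))   # n <= K + 1 unrankable
})

test_that("model ranking table satisfies its structural invariants", {
  sc <- small_scenario()
  st <- make_stack(sc)
  suit <- true_suitability(st, sc$coef)
  occ <- sample_presences(st, suit, 60, seed = 2)
  th <- thin(occ, 0.8, reps = 5, seed = 3)
  pt <- partition(th$retained, "random", seed = 4)
  bg <- sample_background(st, NULL, 400, seed = 5)
  tab <- rank_models(st, th$retained, pt, bg,
                     settings = list(n_knots = 6, max_iter = 250))
  expect_equal(nrow(tab), 15)
  expect_equal(sum(tab$delta_aicc == 0, na.rm = TRUE), 1)
  expect_true(all(diff(tab$aicc) >= 0, na.rm = TRUE))
  expect_true(all(tab$auc_train >= 0 & tab$auc_train <= 1, na.rm = TRUE))
  expect_true(all(tab$auc_test >= 0 & tab$auc_test <= 1, na.rm = TRUE))
  expect_true(all(tab$n - tab$K - 1 > 0, na.rm = TRUE))
  # model independence: a reduced candidate list reproduces the same rows
  tab2 <- rank_models(st, th$retained, pt, bg, vars = c("MAT", "MAP"),
                      settings = list(n_knots = 6, max_iter = 250))
  expect_equal(nrow(tab2), 3)
  for (nm in tab2$model) {
    expect_equal(tab2$aicc[tab2$model == nm], tab$aicc[tab$model == nm],
                 tolerance = 1e-12)
  }
})
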