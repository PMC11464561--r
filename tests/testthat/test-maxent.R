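test_that("feature construction scales, squares and hinges correctly", {
  bg <- data.frame(v = c(0, 10), u = c(1, 1))
  expect_warning(fs <- build_features(bg, c("v", "u"), n_knots = 4),
                 "constant variable")
  expect_equal(fs$vars, "v")
  X <- feature_matrix(fs, data.frame(v = 5))
  expect_equal(unname(X[1, 1]), 0.5)   # linear
  expect_equal(unname(X[1, 2]), 0.25)  # quadratic
  # hinge with knot 0.5 evaluated at scaled value 0.75 -> 0.5
  fs2 <- build_features(data.frame(v = c(0, 1)), "v",
                        classes = "hinge", n_knots = 2)
  expect_equal(fs2$defs$knot, c(0, 0.5))
  X2 <- feature_matrix(fs2, data.frame(v = 0.75))
  expect_equal(unname(X2[1, 2]), 0.5)
  # product features
  fs3 <- build_features(data.frame(a = 0:1, b = 0:1), c("a", "b"),
                        classes = c("linear", "product"))
  X3 <- feature_matrix(fs3, data.frame(a = 0.5, b = 0.4))
  expect_equal(unname(X3[1, 3]), 0.2)
})

test_that("infinite regularization drives all coefficients exactly to zero", {
  set.seed(4)
  X_bg <- matrix(runif(200), 100, 2)
  X_pr <- matrix(runif(20, 0.5, 1), 10, 2)
  m <- fit_maxent(X_pr, X_bg, beta = c(1e6, 1e6))
  expect_identical(unname(m$w), c(0, 0))
  expect_equal(m$H, log(100))
  expect_true(m$converged)
})

test_that("null presences drawn from the background shrink to uniform", {
  set.seed(5)
  bg <- data.frame(v = runif(400), u = runif(400))
  pres <- bg[sample(400, 80), ]
  fs <- build_features(bg, c("v", "u"), classes = c("linear", "quadratic"))
  m <- fit_maxent(feature_matrix(fs, pres), feature_matrix(fs, bg), fs = fs)
  expect_lt(max(abs(m$w)), 0.4)
  raw <- predict_raw(m, feature_matrix(fs, bg))
  expect_lt(max(raw) / min(raw), 1.6)  # near-uniform
  expect_gt(m$H, log(400) - 0.02)
})

test_that("1-D fit matches a fine grid search over the coefficient", {
  X_bg <- matrix(c(0, 0.5, 1), ncol = 1)
  X_pr <- matrix(c(0.8, 1), ncol = 1)
  beta <- 0.05
  m <- fit_maxent(X_pr, X_bg, beta = beta, tol = 1e-12, max_iter = 5000)
  obj <- function(w) {
    log(sum(exp(X_bg * w))) - log(3) - w * mean(X_pr) + beta * abs(w)
  }
  ws <- seq(-10, 10, by = 1e-4)
  objs <- vapply(ws, obj, numeric(1))
  expect_equal(m$objective, min(objs), tolerance = 1e-4)
  expect_equal(unname(m$w), ws[which.min(objs)], tolerance = 1e-3)
})

test_that("the objective trace is monotone non-increasing", {
  set.seed(6)
  bg <- data.frame(v = runif(300))
  pres <- data.frame(v = runif(50, 0.6, 1))
  fs <- build_features(bg, "v")
  m <- fit_maxent(feature_matrix(fs, pres), feature_matrix(fs, bg), fs = fs)
  expect_true(all(diff(m$trace) <= 1e-12))
  expect_true(m$converged)
})

test_that("raw predictions normalize and transform consistently", {
  set.seed(7)
  bg <- data.frame(v = runif(200), u = runif(200))
  pres <- data.frame(v = runif(30, 0.5, 1), u = runif(30))
  fs <- build_features(bg, c("v", "u"))
  X_bg <- feature_matrix(fs, bg)
  m <- fit_maxent(feature_matrix(fs, pres), X_bg, fs = fs)
  raw <- predict_raw(m, X_bg)
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  # zero-coefficient model is uniform raw and constant cloglog 1 - e^-1
  m0 <- fit_maxent(feature_matrix(fs, pres), X_bg, fs = fs,
                   beta = rep(1e9, ncol(X_bg)))
  expect_equal(predict_raw(m0, X_bg), rep(1 / 200, 200))
  expect_equal(predict_cloglog(m0, X_bg), rep(1 - exp(-1), 200))
  # doubling coefficients = squaring unnormalized weights, renormalized
  m2 <- m; m2$w <- 2 * m$w
  r2 <- exp(drop(X_bg %*% m2$w)); r2 <- r2 / sum(r2)
  rsq <- raw^2 / sum(raw^2)
  expect_equal(r2, rsq, tolerance = 1e-12)
  # cloglog is strictly increasing in raw
  cl <- predict_cloglog(m, X_bg)
  expect_true(all(diff(cl[order(raw)]) >= 0))
  expect_equal(order(cl), order(raw))
})

test_that("fits are invariant to affine rescaling of input variables", {
  set.seed(8)
  bg <- data.frame(v = runif(200, 10, 30))
  pres <- data.frame(v = runif(40, 20, 30))
  fs1 <- build_features(bg, "v")
  m1 <- fit_maxent(feature_matrix(fs1, pres), feature_matrix(fs1, bg),
                   fs = fs1, tol = 1e-12)
  bg2 <- data.frame(v = 5 * bg$v - 7)
  pres2 <- data.frame(v = 5 * pres$v - 7)
  fs2 <- build_features(bg2, "v")
  m2 <- fit_maxent(feature_matrix(fs2, pres2), feature_matrix(fs2, bg2),
                   fs = fs2, tol = 1e-12)
  expect_equal(m1$w, m2$w, tolerance = 1e-6)
  expect_equal(m1$H, m2$H, tolerance = 1e-8)
})

test_that("stack prediction aligns with point prediction", {
  sc <- small_scenario()
  st <- make_stack(sc)
  suit <- true_suitability(st, sc$coef)
  occ <- sample_presences(st, suit, 40, seed = 3)
  bg <- sample_background(st, NULL, 300, seed = 4)
  ex <- extract_at_points(st, occ)
  m <- fit_subset_model(ex, bg$points, c("MAT", "P_cold"),
                        settings = list(n_knots = 6, max_iter = 300))
  surf <- predict_stack(m, st)
  expect_true(all(surf >= 0 & surf <= 1, na.rm = TRUE))
  pt_pred <- predict_cloglog(m, feature_matrix(m$features, ex))
  expect_equal(surf[cbind(ex$row, ex$col)], pt_pred, tolerance = 1e-12)
  # raw over the full extent renormalizes to 1
  rawsurf <- predict_stack(m, st, transform = "raw")
  expect_equal(sum(rawsurf, na.rm = TRUE), 1, tolerance = 1e-9)
})
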