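test_that("climate_stack masks a cell everywhere when any layer has nodata", {
  st <- make_manual_stack(nr = 4, nc = 4)
  layers <- st$layers
  layers$MAP[2, 3] <- NA
  st2 <- climate_stack(layers, st$xll, st$yll, st$cellsize)
  expect_false(st2$mask[2, 3])
  expect_equal(sum(st2$mask), 15)
  # mask conservation: combined valid cells <= any single layer's
  expect_lte(sum(st2$mask), sum(is.finite(layers$MAP)))
})

test_that("stack invariant violations are rejected", {
  st <- make_manual_stack(nr = 4, nc = 4)
  bad <- st$layers
  bad$P_cold[1, 1] <- bad$MAP[1, 1] + 5
  expect_error(climate_stack(bad, st$xll, st$yll, st$cellsize),
               "exceeds annual")
  bad2 <- st$layers
  bad2$P_winter[1, 1] <- bad2$P_winter[1, 1] + 3
  expect_error(climate_stack(bad2, st$xll, st$yll, st$cellsize),
               "P_winter")
})

test_that("ASCII grid write -> read round-trips values and geometry", {
  st <- make_stack(synthetic_scenario())  # default 240 x 240
  dir <- withr::local_tempdir()
  paths <- write_stack(st, dir)
  st2 <- read_stack(paths)
  expect_equal(st2$nrow, st$nrow)
  expect_equal(st2$xll, st$xll, tolerance = 1e-9)
  expect_equal(st2$cellsize, st$cellsize, tolerance = 1e-9)
  for (nm in names(st$layers))
    expect_equal(st2$layers[[nm]], st$layers[[nm]], tolerance = 1e-6,
                 ignore_attr = TRUE)
  expect_equal(st2$mask, st$mask)
})

test_that("read_stack rejects incompatible geometry and missing layers", {
  st <- make_manual_stack(nr = 4, nc = 4)
  dir <- withr::local_tempdir()
  paths <- write_stack(st, dir)
  shifted <- file.path(dir, "MAT_shift.asc")
  write_asc(st$layers$MAT, shifted, st$xll + 0.5, st$yll, st$cellsize)
  paths2 <- paths
  paths2[["MAT"]] <- shifted
  expect_error(read_stack(paths2), "geometry incompatible")
  expect_error(read_stack(paths[-1]), "missing required layer")
})

test_that("extraction matches direct grid indexing at random interior points", {
  st <- make_stack(small_scenario())
  set.seed(101)
  n <- 100
  row <- sample(st$nrow, n, replace = TRUE)
  col <- sample(st$ncol, n, replace = TRUE)
  ymax <- st$yll + st$nrow * st$cellsize
  # random positions strictly inside each chosen cell
  lon <- st$xll + (col - runif(n, 0.05, 0.95)) * st$cellsize
  lat <- ymax - (row - runif(n, 0.05, 0.95)) * st$cellsize
  pts <- occurrence_set(data.frame(id = as.character(1:n), lon = lon, lat = lat))
  ex <- extract_at_points(st, pts)
  expect_true(all(ex$valid))
  expect_equal(ex$MAT, st$layers$MAT[cbind(row, col)])
  expect_equal(ex$elevation, st$layers$elevation[cbind(row, col)])
})

test_that("points on shared cell edges go to the east/south cell", {
  st <- make_manual_stack(nr = 4, nc = 4, cellsize = 0.01)
  ymax <- st$yll + 4 * 0.01
  # on the vertical edge between columns 2 and 3 -> east cell (col 3)
  rc <- point_to_cell(st, st$xll + 2 * 0.01, ymax - 0.015)
  expect_equal(unlist(rc), c(row = 2, col = 3))
  # on the horizontal edge between rows 1 and 2 -> south cell (row 2)
  rc <- point_to_cell(st, st$xll + 0.015, ymax - 0.01)
  expect_equal(unlist(rc), c(row = 2, col = 2))
  # outside the extent is flagged, not dropped
  out <- extract_at_points(st, occurrence_set(
    data.frame(id = "x", lon = st$xll - 1, lat = st$yll)))
  expect_false(out$valid)
  expect_equal(nrow(out), 1)
})

test_that("extraction is order-independent and idempotent", {
  st <- make_stack(small_scenario())
  suit <- true_suitability(st, small_scenario()$coef)
  pts <- sample_presences(st, suit, 30, seed = 5)
  ex1 <- extract_at_points(st, pts)
  perm <- sample(nrow(pts))
  ex2 <- extract_at_points(st, pts[perm, ])
  expect_equal(ex2[order(perm), ]$MAP, ex1$MAP)
  expect_equal(extract_at_points(st, pts), ex1)
})

test_that("buffer_region matches brute-force distances and is monotone", {
  st <- make_manual_stack(nr = 10, nc = 10, cellsize = 0.01)
  p <- occurrence_set(data.frame(id = "c", lon = 76.05, lat = 33.05))
  r_small <- 0.01 * 111.195  # about one cell width
  m1 <- buffer_region(st, p, r_small)
  # brute force: haversine from every cell centre
  lons <- st$xll + (seq_len(10) - 0.5) * 0.01
  ymax <- st$yll + 10 * 0.01
  lats <- ymax - (seq_len(10) - 0.5) * 0.01
  expected <- outer(seq_len(10), seq_len(10), function(i, j)
    great_circle_km(lons[j], lats[i], p$lon, p$lat) <= r_small)
  expect_equal(m1, expected)
  # monotone in radius; saturating radius keeps every valid cell
  m2 <- buffer_region(st, p, 2 * r_small)
  expect_true(all(m2[m1]))
  expect_equal(buffer_region(st, p, 1e4), st$mask)
  # union semantics for two distant points
  p2 <- occurrence_set(data.frame(id = c("a", "b"),
                                  lon = c(76.005, 76.095),
                                  lat = c(33.095, 33.005)))
  mu <- buffer_region(st, p2, r_small)
  ma <- buffer_region(st, p2[1, ], r_small)
  mb <- buffer_region(st, p2[2, ], r_small)
  expect_equal(mu, ma | mb)
  expect_error(buffer_region(st, p2[0, ], 10), "empty")
})

test_that("background sampling is seeded, in-region, and uniform", {
  st <- make_manual_stack(nr = 5, nc = 5, cellsize = 0.01)
  # single-cell region
  region <- matrix(FALSE, 5, 5); region[3, 3] <- TRUE
  bs <- sample_background(st, region, n = 5, seed = 1)
  expect_equal(nrow(bs$points), 5)
  expect_true(all(bs$points$row == 3 & bs$points$col == 3))
  # determinism
  b1 <- sample_background(st, NULL, 200, seed = 9)
  b2 <- sample_background(st, NULL, 200, seed = 9)
  expect_identical(b1$points, b2$points)
  # uniformity: chi-square goodness of fit over 25 cells, n = 10000
  b <- sample_background(st, NULL, 10000, seed = 4)
  counts <- table(factor(paste(b$points$row, b$points$col),
                         levels = as.vector(outer(1:5, 1:5, paste))))
  gof <- stats::chisq.test(as.vector(counts), p = rep(1 / 25, 25))
  expect_gt(gof$p.value, 0.01)
  expect_error(sample_background(st, matrix(FALSE, 5, 5), 1, seed = 1),
               "no valid cells")
})
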