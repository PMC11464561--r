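# Fixtures built in code: small stacks and score sets.

# A stack with hand-chosen constant or patterned layers; defaults give a
# physically consistent arid-mountain cell set.
make_manual_stack <- function(nr = 6, nc = 6, xll = 76, yll = 33,
                              cellsize = 0.01,
                              MAT = 3, MAP = 130, cold_frac = 0.55,
                              f_cold = 0.6, f_warm = 0.5, elev = 4000) {
  grid <- function(v) {
    if (is.matrix(v)) v else matrix(v, nr, nc)
  }
  MAPm <- grid(MAP)
  cf <- grid(cold_frac)
  climate_stack(list(
    MAT = grid(MAT), MAP = MAPm,
    P_cold = f_cold * cf * MAPm, P_warm = f_warm * (1 - cf) * MAPm,
    P_winter = cf * MAPm, P_summer = (1 - cf) * MAPm,
    elevation = grid(elev)),
    xll = xll, yll = yll, cellsize = cellsize)
}

# A small default-physics synthetic stack for integration-style tests.
small_scenario <- function(seed = 42, nrow = 60, ncol = 60, ...) {
  synthetic_scenario(nrow = nrow, ncol = ncol, seed = seed, ...)
}

# Random presence/background score sets with ties (values rounded to a
# coarse grid so duplicated scores are common).
random_score_sets <- function(seed, n_sets, max_m = 20, max_b = 30) {
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    m <- sample(2:max_m, 1); b <- sample(2:max_b, 1)
    list(pres = round(stats::runif(m), 2), bg = round(stats::runif(b), 2))
  })
}

# Random occurrence sets in a ~3 km box so 1-km conflicts are common.
random_point_set <- function(n, span_deg = 0.03) {
  occurrence_set(data.frame(
    id = paste0("p", seq_len(n)),
    lon = 77 + stats::runif(n, 0, span_deg),
    lat = 34 + stats::runif(n, 0, span_deg)))
}
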