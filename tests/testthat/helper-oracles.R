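# Independent oracles, deliberately written by brute force / enumeration
# so they share no code path with the implementation they check.

# AUC by explicit pair counting, ties 1/2.
brute_auc <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg) {
    if (p > b) wins <- wins + 1
    else if (p == b) wins <- wins + 0.5
  }
  wins / (length(pres) * length(bg))
}

# Maximum-TSS threshold by naive exhaustive sweep; ties -> smallest t.
brute_tss <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  best_t <- NA_real_; best_tss <- -Inf
  for (t in cand) {
    sens <- sum(pres >= t) / length(pres)
    spec <- sum(bg < t) / length(bg)
    tss <- sens + spec - 1
    if (tss > best_tss + 1e-15) { best_tss <- tss; best_t <- t }
  }
  list(threshold = best_t, tss = best_tss)
}

# Koppen-Geiger arid decision tree, hand-coded scalar form.
koppen_oracle <- function(mat, map, pwin, psum) {
  wf <- if (map > 0) pwin / map else 0.5
  sf <- if (map > 0) psum / map else 0.5
  pthr <- if (wf >= 0.7) 2 * mat else if (sf >= 0.7) 2 * mat + 28 else 2 * mat + 14
  if (pthr < 0) pthr <- 0
  if (!(map < 10 * pthr)) return("other")
  base <- if (map < 5 * pthr) "BW" else "BS"
  paste0(base, if (mat < 18) "k" else "h")
}

# Exact maximum retainable subset size under a pairwise min-distance
# constraint, by enumeration over all 2^n subsets (n <= 12 feasible).
brute_thin_max <- function(points, min_km) {
  n <- nrow(points)
  stopifnot(n <= 12)
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    great_circle_km(points$lon[i], points$lat[i], points$lon[j], points$lat[j]))
  conflicts <- which(d < min_km & upper.tri(d), arr.ind = TRUE)
  masks <- 0:(2^n - 1)
  feasible <- rep(TRUE, length(masks))
  for (k in seq_len(nrow(conflicts))) {
    bits <- bitwOr(bitwShiftL(1L, conflicts[k, 1] - 1L),
                   bitwShiftL(1L, conflicts[k, 2] - 1L))
    feasible <- feasible & bitwAnd(masks, bits) != bits
  }
  popcount <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L),
                     numeric(1))
  max(popcount[feasible])
}

# Two-pass central-moment summary used to cross-check summarize_variable.
twopass_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)),
       skewness = m3 / m2^1.5)
}
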