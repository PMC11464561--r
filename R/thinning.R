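# Spatial thinning of occurrence records.
#
# Removes points so that every retained pair is at least `min_km` apart
# (great-circle), trying to keep as many points as possible. The strategy
# is the classic greedy one: repeatedly delete a point with the greatest
# number of too-close neighbours, breaking ties at random, and repeat the
# whole procedure several times keeping the best repetition. A final
# re-insertion pass restores any removed point that no longer conflicts,
# which guarantees maximality of the retained set.

#' Spatially thin an occurrence set
#'
#' @param points An [occurrence_set()].
#' @param min_km Minimum pairwise great-circle distance to enforce (km).
#' @param reps Number of randomized repetitions (default 100); the
#'   repetition retaining the most points wins.
#' @param seed Integer seed for tie-breaking.
#' @return List of class `thinning_result`: `retained` (an
#'   [occurrence_set()]), `removed_ids`, `min_km`, `reps`, `seed`,
#'   `n_retained`.
#' @export
thin <- function(points, min_km, reps = 100, seed) {
  if (nrow(points) == 0) stop("empty input")
  stopifnot(min_km > 0, reps >= 1)
  n <- nrow(points)
  d <- pairwise_great_circle(points$lon, points$lat)
  adj <- d < min_km
  diag(adj) <- FALSE
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(reps)) {
      keep <- thin_once(adj)
      if (is.null(best) || sum(keep) > sum(best)) best <- keep
    }
  })
  retained <- points[best, , drop = FALSE]
  class(retained) <- class(points)
  structure(list(retained = retained,
                 removed_ids = points$id[!best],
                 min_km = min_km, reps = reps, seed = seed,
                 n_retained = sum(best)),
            class = "thinning_result")
}

# One greedy repetition over a logical conflict matrix; uses the current
# RNG stream for tie-breaking. Returns logical keep vector.
thin_once <- function(adj) {
  n <- nrow(adj)
  alive <- rep(TRUE, n)
  repeat {
    counts <- rowSums(adj[, alive, drop = FALSE]) * alive
    mx <- max(counts)
    if (mx == 0) break
    cand <- which(counts == mx)
    drop <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    alive[drop] <- FALSE
  }
  # maximality: re-add any removed point that no longer conflicts
  removed <- which(!alive)
  if (length(removed) > 1) removed <- removed[sample.int(length(removed))]
  for (i in removed) {
    if (!any(adj[i, alive])) alive[i] <- TRUE
  }
  alive
}

# Full pairwise haversine distance matrix (km).
pairwise_great_circle <- function(lon, lat) {
  n <- length(lon)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- great_circle_km(lon[i], lat[i], lon, lat)
  }
  (d + t(d)) / 2
}

#' @export
print.thinning_result <- function(x, ...) {
  cat(sprintf("thinning_result: %d retained / %d input (min %.3g km, %d reps)\n",
              x$n_retained, x$n_retained + length(x$removed_ids),
              x$min_km, x$reps))
  invisible(x)
}
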