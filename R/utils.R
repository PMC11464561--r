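# Shared numerical helpers.

# Mean Earth radius (km) used for all great-circle work in this package.
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points (haversine)
#'
#' Computes the haversine distance on a sphere of radius 6371.0088 km.
#' Inputs are recycled, so one point against many is allowed.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' great_circle_km(0, 0, 1, 0)  # ~111.195 km
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(is.numeric(lon1), is.numeric(lat1), is.numeric(lon2), is.numeric(lat2))
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  # clamp for antipodal rounding
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Run code under a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# Sample skewness g1 = m3 / m2^(3/2) with central moments over n.
skewness_g1 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}
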