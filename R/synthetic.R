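# Synthetic arid-mountain landscape and occurrence generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# rugged high-elevation terrain, temperature falling with elevation at a
# fixed lapse rate, a spatially smooth precipitation field with an
# orographic component, and a smooth "cold fraction" field that splits
# annual precipitation into 6-month winter (ONDJFM) and summer (AMJJAS)
# halves. Quarterly totals are fixed sub-fractions of the half-year sums
# (quarter within half-year), so P_cold <= P_winter and P_warm <= P_summer
# everywhere. Species presence is concentrated where the ratio of cold
# precipitation to annual precipitation is high.

# Smooth random field in [0, 1]: white noise low-pass filtered with a
# Gaussian kernel (periodic FFT convolution), then range-normalized.
smooth_field <- function(nr, nc, scale, seed) {
  noise <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  if (scale > 0) {
    fi <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
    fj <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
    gauss <- exp(-2 * pi^2 * scale^2 * outer(fi^2, fj^2, `+`))
    noise <- Re(stats::fft(stats::fft(noise) * gauss, inverse = TRUE)) / (nr * nc)
  }
  rng <- range(noise)
  if (diff(rng) == 0) return(matrix(0.5, nr, nc))
  (noise - rng[1]) / diff(rng)
}

#' Default synthetic scenario
#'
#' Parameters of the generated landscape and occurrence process. Defaults
#' describe a ~2 x 2 degree cold arid mountain region at 30 arc-second
#' resolution whose climate at sampled presences approximates a cold-steppe
#' to cold-desert transition zone (annual precipitation roughly 60-300 mm,
#' mean annual temperature around 3 degrees C).
#'
#' @param nrow,ncol Grid size in cells (default 240 x 240).
#' @param xll,yll Lower-left corner, degrees (default 76 E, 33 N).
#' @param cellsize Cell size in degrees (default 1/120, ~30 arc-sec).
#' @param seed Integer seed controlling every random field and draw.
#' @param elev_scale Low-pass filter scale (cells) of the elevation field.
#' @param elev_range Elevation range in metres, default c(2500, 6500).
#' @param lapse Temperature lapse rate, deg C per metre (default 0.0065).
#' @param t_sea Sea-level temperature intercept, deg C (default 30).
#' @param mat_noise_sd Spatial temperature noise sd, deg C.
#' @param map_base,map_range Base and gradient amplitude of annual
#'   precipitation, mm.
#' @param map_orographic Orographic precipitation gain, mm per km of
#'   elevation above the lower elevation bound.
#' @param map_scale Filter scale (cells) of the precipitation gradient.
#' @param cold_frac_range Range of the winter (cold) precipitation
#'   fraction field, default c(0.1, 0.9).
#' @param cold_frac_scale Filter scale (cells) of the cold-fraction field.
#' @param frac_cold_of_winter Mean quarter-to-half-year sub-fraction for
#'   the coldest quarter (default 0.6).
#' @param frac_warm_of_summer Mean sub-fraction for the warmest quarter
#'   (default 0.62).
#' @param frac_amplitude Half-range of the spatial variation of the two
#'   sub-fraction fields around their means (default 0.15). The
#'   sub-fractions vary smoothly in space, so the two quarterly layers are
#'   not deterministic mirrors of one another.
#' @param coef True-suitability coefficients, see [true_suitability()].
#' @param n_occurrences Number of presence points to draw (default 164).
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(nrow = 240, ncol = 240, xll = 76, yll = 33,
                               cellsize = 1 / 120, seed = 42,
                               elev_scale = 25, elev_range = c(2500, 6500),
                               lapse = 0.0065, t_sea = 33,
                               mat_noise_sd = 0.4,
                               map_base = 68, map_range = 130,
                               map_orographic = 10, map_scale = 45,
                               cold_frac_range = c(0.2, 0.8),
                               cold_frac_scale = 45,
                               frac_cold_of_winter = 0.6,
                               frac_warm_of_summer = 0.62,
                               frac_amplitude = 0.15,
                               coef = list(intercept = -3, cold_ratio = 5,
                                           warm_ratio = -6,
                                           mat_quad = -0.45, mat_opt = 2.8),
                               n_occurrences = 164) {
  if (nrow < 20 || ncol < 20) stop("degenerate extent: need >= 20 x 20 cells")
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Generate a synthetic climate stack
#'
#' Builds elevation, temperature and precipitation layers per the scenario:
#' elevation is a smoothed random field scaled to `elev_range`; MAT is
#' `t_sea - lapse * elevation` plus smooth noise; MAP is a smooth base
#' gradient plus an orographic term, clipped at 30 mm; a smooth cold
#' fraction c splits MAP into P_winter = c * MAP and
#' P_summer = (1 - c) * MAP, and the quarterly layers are fixed
#' sub-fractions of the half-year sums. Deterministic under the scenario
#' seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [climate_stack()].
#' @export
make_stack <- function(scenario) {
  s <- scenario
  nr <- s$nrow; nc <- s$ncol
  elev01 <- smooth_field(nr, nc, s$elev_scale, s$seed)
  elev <- s$elev_range[1] + diff(s$elev_range) * elev01
  mat_noise <- smooth_field(nr, nc, 10, s$seed + 1L)
  MAT <- s$t_sea - s$lapse * elev +
    s$mat_noise_sd * (mat_noise - 0.5) * 2
  g <- smooth_field(nr, nc, s$map_scale, s$seed + 2L)
  MAP <- s$map_base + s$map_range * g +
    s$map_orographic * (elev - s$elev_range[1]) / 1000
  MAP <- pmax(MAP, 30)
  cf <- smooth_field(nr, nc, s$cold_frac_scale, s$seed + 3L)
  cfrac <- s$cold_frac_range[1] + diff(s$cold_frac_range) * cf
  P_winter <- cfrac * MAP
  P_summer <- (1 - cfrac) * MAP
  # quarter-to-half-year sub-fractions vary smoothly and independently so
  # P_cold and P_warm carry information the opposite quarter cannot proxy
  f_cold <- s$frac_cold_of_winter +
    s$frac_amplitude * (2 * smooth_field(nr, nc, s$cold_frac_scale, s$seed + 4L) - 1)
  f_warm <- s$frac_warm_of_summer +
    s$frac_amplitude * (2 * smooth_field(nr, nc, s$cold_frac_scale, s$seed + 5L) - 1)
  f_cold <- pmin(pmax(f_cold, 0.05), 1)
  f_warm <- pmin(pmax(f_warm, 0.05), 1)
  climate_stack(
    list(MAT = MAT, MAP = MAP,
         P_cold = f_cold * P_winter,
         P_warm = f_warm * P_summer,
         P_winter = P_winter, P_summer = P_summer,
         elevation = elev),
    xll = s$xll, yll = s$yll, cellsize = s$cellsize)
}

#' True suitability surface of a synthetic landscape
#'
#' Inverse-logit of a linear-quadratic score in the cold-precipitation
#' ratio P_cold/MAP, the warm ratio P_warm/MAP, and MAT:
#' `plogis(b0 + b_c * P_cold/MAP + b_w * P_warm/MAP +
#'         b_q * (MAT - mat_opt)^2)`.
#' With the default signs (b_c > 0, b_w < 0, b_q < 0) suitability peaks at
#' a high cold ratio, a low warm ratio and MAT near `mat_opt`. All-zero
#' coefficients give a flat 0.5 surface.
#'
#' @param stack A [climate_stack()].
#' @param coef List with `intercept`, `cold_ratio`, `warm_ratio`,
#'   `mat_quad`, `mat_opt`.
#' @return Numeric matrix of suitabilities in [0, 1]; NA on masked cells
#'   and wherever MAP = 0.
#' @export
true_suitability <- function(stack, coef) {
  stopifnot(all(vapply(coef, is.finite, logical(1))))
  MAP <- stack$layers$MAP
  ok <- stack$mask & MAP > 0
  score <- coef$intercept +
    coef$cold_ratio * stack$layers$P_cold / MAP +
    coef$warm_ratio * stack$layers$P_warm / MAP +
    coef$mat_quad * (stack$layers$MAT - coef$mat_opt)^2
  out <- stats::plogis(score)
  out[!ok] <- NA_real_
  out
}

#' Sample presence points proportional to suitability
#'
#' Cells are drawn with probability proportional to suitability; each point
#' is then placed uniformly within its cell. The elevation attribute is
#' copied from the elevation layer.
#'
#' @param stack A [climate_stack()].
#' @param suitability Matrix from [true_suitability()] (NA cells excluded).
#' @param n Number of points.
#' @param seed Integer seed.
#' @return An [occurrence_set()] with columns id, lon, lat, elev.
#' @export
sample_presences <- function(stack, suitability, n, seed) {
  w <- suitability
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("all-zero suitability")
  cells <- seq_along(w)
  draw <- with_seed(seed, {
    idx <- sample(cells, n, replace = TRUE, prob = as.vector(w))
    jit_x <- stats::runif(n)
    jit_y <- stats::runif(n)
    list(idx = idx, jx = jit_x, jy = jit_y)
  })
  row <- ((draw$idx - 1L) %% stack$nrow) + 1L
  col <- ((draw$idx - 1L) %/% stack$nrow) + 1L
  ymax <- stack$yll + stack$nrow * stack$cellsize
  lon <- stack$xll + (col - 1L + draw$jx) * stack$cellsize
  lat <- ymax - (row - 1L + draw$jy) * stack$cellsize
  occurrence_set(data.frame(
    id = paste0("occ_", seq_len(n)), lon = lon, lat = lat,
    elev = stack$layers$elevation[draw$idx]))
}
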