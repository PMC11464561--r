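# Koppen-Geiger arid (B) climate classification.
#
# Arid climates are defined by comparing annual precipitation with a
# precipitation threshold P_thr that depends on mean annual temperature
# and on the seasonal concentration of precipitation:
#   >= 70% of MAP in the winter half-year (ONDJFM, northern hemisphere):
#       P_thr = 2 * MAT
#   >= 70% of MAP in the summer half-year (AMJJAS): P_thr = 2 * MAT + 28
#   otherwise:                                      P_thr = 2 * MAT + 14
# (floored at 0). A cell is arid (B) iff MAP < 10 * P_thr; desert (BW)
# iff MAP < 5 * P_thr, else steppe (BS); suffix k iff MAT < 18 deg C,
# else h. Non-arid cells fall into "other".

KOPPEN_LEVELS <- c("BWk", "BWh", "BSk", "BSh", "other")

#' Arid-climate precipitation threshold
#'
#' @param MAT Mean annual temperature, deg C.
#' @param MAP Mean annual precipitation, mm.
#' @param P_winter Precipitation of the winter half-year (ONDJFM), mm.
#' @param P_summer Precipitation of the summer half-year (AMJJAS), mm.
#' @param hemisphere `"north"` (default; ONDJFM is winter) or `"south"`
#'   (roles swapped).
#' @return P_thr in mm (vectorized, floored at 0). When MAP is 0 the
#'   seasonal fractions are undefined and the intermediate ("otherwise")
#'   branch is used.
#' @export
precipitation_threshold <- function(MAT, MAP, P_winter, P_summer,
                                    hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  if (hemisphere == "south") {
    tmp <- P_winter; P_winter <- P_summer; P_summer <- tmp
  }
  wfrac <- ifelse(MAP > 0, P_winter / MAP, 0.5)
  sfrac <- ifelse(MAP > 0, P_summer / MAP, 0.5)
  pthr <- ifelse(wfrac >= 0.7, 2 * MAT,
                 ifelse(sfrac >= 0.7, 2 * MAT + 28, 2 * MAT + 14))
  pmax(pthr, 0)
}

#' Classify climates into Koppen-Geiger arid classes
#'
#' @inheritParams precipitation_threshold
#' @return Character vector over {BWk, BWh, BSk, BSh, other}. Strict `<`
#'   at both arid boundaries: exactly MAP = 10 * P_thr is non-arid and
#'   exactly MAP = 5 * P_thr is steppe.
#' @examples
#' koppen_classify(MAT = 2.8, MAP = 133, P_winter = 75, P_summer = 57) # BSk
#' @export
koppen_classify <- function(MAT, MAP, P_winter, P_summer,
                            hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  if (any(MAP < 0 | P_winter < 0 | P_summer < 0, na.rm = TRUE))
    stop("negative precipitation input")
  pthr <- precipitation_threshold(MAT, MAP, P_winter, P_summer, hemisphere)
  cls <- rep("other", length(pthr))
  arid <- MAP < 10 * pthr
  desert <- arid & (MAP < 5 * pthr)
  cold <- MAT < 18
  cls[arid & desert & cold] <- "BWk"
  cls[arid & desert & !cold] <- "BWh"
  cls[arid & !desert & cold] <- "BSk"
  cls[arid & !desert & !cold] <- "BSh"
  cls[is.na(MAT) | is.na(MAP)] <- NA_character_
  cls
}

#' Classify occurrence points into Koppen-Geiger arid classes
#'
#' Extracts MAT/MAP/P_winter/P_summer at each point and classifies it.
#' Points on masked cells or outside the extent are flagged and excluded
#' from the percentage denominators (with a warning count in the result).
#'
#' @param stack A [climate_stack()].
#' @param points An [occurrence_set()].
#' @param fold_hot Fold BWh/BSh into "other" in the summary counts
#'   (default TRUE; cold-mountain study regions never reach MAT >= 18).
#' @return List: `per_point` (data.frame id, class, valid), `counts`
#'   (data.frame class, n, pct over valid points), `n_invalid`.
#' @export
classify_points <- function(stack, points, fold_hot = TRUE) {
  ex <- extract_at_points(stack, points)
  cls <- rep(NA_character_, nrow(ex))
  v <- ex$valid
  if (sum(v) > 0) {
    cls[v] <- koppen_classify(ex$MAT[v], ex$MAP[v],
                              ex$P_winter[v], ex$P_summer[v])
  }
  per_point <- data.frame(id = ex$id, class = cls, valid = v)
  grp <- cls[v]
  if (fold_hot) grp[grp %in% c("BWh", "BSh")] <- "other"
  lev <- if (fold_hot) c("BWk", "BSk", "other") else KOPPEN_LEVELS
  tab <- table(factor(grp, levels = lev))
  counts <- data.frame(class = names(tab), n = as.integer(tab),
                       pct = 100 * as.integer(tab) / max(1L, sum(v)))
  n_invalid <- sum(!v)
  if (n_invalid > 0)
    warning(n_invalid, " point(s) on masked cells or outside extent excluded")
  list(per_point = per_point, counts = counts, n_invalid = n_invalid)
}

#' Classify every cell of a stack
#'
#' @param stack A [climate_stack()].
#' @param hemisphere Passed to [koppen_classify()].
#' @return Character matrix of classes aligned to the stack (NA on masked
#'   cells).
#' @export
classify_stack <- function(stack, hemisphere = "north") {
  l <- stack$layers
  cls <- koppen_classify(as.vector(l$MAT), as.vector(l$MAP),
                         as.vector(l$P_winter), as.vector(l$P_summer),
                         hemisphere)
  cls[!stack$mask] <- NA_character_
  matrix(cls, stack$nrow, stack$ncol)
}
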