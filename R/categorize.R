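# Nested suitability categorization and variable summaries.
#
# Cells below the maximum-TSS threshold t are "unsuitable". Within the
# threshold, the suitability value range [t, v_max] is rescaled to [0, 1]
# (s = (v - t)/(v_max - t)) and carved into nested retention bands: the
# top 30% of the range is "high", the top 70% "moderate", the top 90%
# "low", and the remainder "fringe" -- reported as the exclusive bands
# fringe [0, 0.1), low [0.1, 0.3), moderate [0.3, 0.7), high [0.7, 1].

CATEGORY_LEVELS <- c("unsuitable", "fringe", "low", "moderate", "high")

#' Categorize a suitability surface
#'
#' @param suitability Numeric matrix (or vector) of suitabilities.
#' @param threshold Maximum-TSS threshold t; cells with value < t are
#'   unsuitable.
#' @param retention Nested retention fractions of the within-threshold
#'   range for high, moderate and low (default c(0.30, 0.70, 0.90)); must
#'   be strictly increasing in (0, 1).
#' @param mode `"range"` (default): bands are fractions of the suitability
#'   VALUE range between t and the surface maximum. `"quantile"`: bands
#'   are fractions of the within-threshold CELLS, upper tail by value.
#' @return Object of class `category_map`: `class` (factor matrix/vector
#'   over unsuitable < fringe < low < moderate < high), `threshold`,
#'   `v_max`, `retention`, `mode`. If the surface is flat at the threshold
#'   (v_max = t) all within-threshold cells are "high", with a warning.
#' @export
categorize <- function(suitability, threshold,
                       retention = c(0.30, 0.70, 0.90),
                       mode = c("range", "quantile")) {
  mode <- match.arg(mode)
  stopifnot(length(retention) == 3, all(diff(retention) > 0),
            all(retention > 0 & retention < 1))
  v <- suitability
  v_max <- suppressWarnings(max(v, na.rm = TRUE))
  cls <- rep(NA_character_, length(v))
  inside <- !is.na(v) & v >= threshold
  cls[!is.na(v) & v < threshold] <- "unsuitable"
  if (any(inside)) {
    if (v_max <= threshold) {
      warning("flat surface at threshold: all within-threshold cells 'high'")
      cls[inside] <- "high"
    } else if (mode == "range") {
      s <- (v[inside] - threshold) / (v_max - threshold)
      cls[inside] <- band_class(s, retention)
    } else {
      # upper-tail cell fractions: the top retention[1] of cells are high, etc.
      s <- 1 - (rank(v[inside], ties.method = "max") - 1) / sum(inside)
      cls[inside] <- ifelse(s <= retention[1], "high",
                     ifelse(s <= retention[2], "moderate",
                     ifelse(s <= retention[3], "low", "fringe")))
    }
  }
  cl <- factor(cls, levels = CATEGORY_LEVELS, ordered = TRUE)
  if (is.matrix(v)) dim(cl) <- dim(v)
  structure(list(class = cl, threshold = threshold, v_max = v_max,
                 retention = retention, mode = mode),
            class = "category_map")
}

# Band assignment on the rescaled [0, 1] value s: cut points are the
# complements of the retention fractions (0.9 -> 0.1, 0.7 -> 0.3, 0.3 -> 0.7).
band_class <- function(s, retention) {
  cuts <- 1 - rev(retention)  # e.g. 0.1, 0.3, 0.7
  ifelse(s >= cuts[3], "high",
  ifelse(s >= cuts[2], "moderate",
  ifelse(s >= cuts[1], "low", "fringe")))
}

#' Tabulate suitability categories at occurrence points
#'
#' Looks up each point's category from the map and (optionally) summarizes
#' climate variables per category, mirroring a per-class variable summary
#' table.
#'
#' @param map A [categorize()] result aligned to `stack`.
#' @param stack The [climate_stack()] the map was computed on.
#' @param points An [occurrence_set()].
#' @param vars Variables to summarize per class (default MAP, MAT, P_cold,
#'   P_warm).
#' @return List: `per_point` (id, class, valid), `counts` (class, n, pct),
#'   `stats` (per class x variable: [summarize_variable()] columns),
#'   `n_invalid`.
#' @export
category_counts_at_points <- function(map, stack, points,
                                      vars = c("MAP", "MAT", "P_cold",
                                               "P_warm")) {
  ex <- extract_at_points(stack, points)
  n <- nrow(ex)
  idx <- ifelse(ex$valid, (ex$col - 1L) * stack$nrow + ex$row, NA_integer_)
  cls <- rep(NA_character_, n)
  cls[ex$valid] <- as.character(map$class[idx[ex$valid]])
  valid <- ex$valid & !is.na(cls)
  per_point <- data.frame(id = ex$id, class = cls, valid = valid)
  tab <- table(factor(cls[valid], levels = CATEGORY_LEVELS))
  counts <- data.frame(class = names(tab), n = as.integer(tab),
                       pct = 100 * as.integer(tab) / max(1L, sum(valid)))
  stats <- do.call(rbind, lapply(CATEGORY_LEVELS, function(cl) {
    sel <- valid & cls == cl
    do.call(rbind, lapply(vars, function(v) {
      st <- summarize_variable(ex[[v]][sel])
      cbind(data.frame(class = cl, variable = v), as.data.frame(st))
    }))
  }))
  rownames(stats) <- NULL
  list(per_point = per_point, counts = counts, stats = stats,
       n_invalid = sum(!ex$valid))
}

#' Summary statistics for one variable
#'
#' Min, max, mean, median, sample sd (n - 1 denominator) and moment
#' skewness g1 = m3 / m2^(3/2) (central moments over n). Statistics whose
#' sample-size requirements are not met (sd needs 2 values, skewness 3)
#' are reported as NA, never as zero; constant samples have sd 0 and
#' undefined skewness.
#'
#' @param values Numeric vector (NAs dropped).
#' @return Named list: n, min, max, mean, median, sd, skewness.
#' @export
summarize_variable <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  list(n = n,
       min = if (n > 0) min(x) else NA_real_,
       max = if (n > 0) max(x) else NA_real_,
       mean = if (n > 0) mean(x) else NA_real_,
       median = if (n > 0) stats::median(x) else NA_real_,
       sd = if (n >= 2) stats::sd(x) else NA_real_,
       skewness = skewness_g1(x))
}

#' Write a category map as an integer-coded ASCII grid with a legend
#'
#' Codes: 0 unsuitable, 1 fringe, 2 low, 3 moderate, 4 high; NA cells are
#' nodata. A sidecar `<path>.legend.txt` documents the code table.
#'
#' @param map A [categorize()] result whose `class` is a matrix.
#' @param path Output `.asc` path.
#' @param xll,yll,cellsize Grid georeference.
#' @export
write_category_map <- function(map, path, xll, yll, cellsize) {
  stopifnot(is.matrix(map$class))
  codes <- matrix(as.integer(map$class) - 1L,
                  nrow(map$class), ncol(map$class))
  write_asc(codes, path, xll, yll, cellsize)
  writeLines(c("code class", paste(0:4, CATEGORY_LEVELS)),
             paste0(path, ".legend.txt"))
  invisible(path)
}
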