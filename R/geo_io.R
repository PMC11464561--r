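# Raster stack container and plain-text geospatial I/O.
#
# Rasters are ESRI ASCII grids (.asc): a 6-line header (ncols, nrows,
# xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of cell
# values from the northernmost row southward. All grids are geographic
# (WGS 84 longitude/latitude, decimal degrees).
#
# In-memory convention: each layer is a numeric matrix with row 1 the
# northernmost row and column 1 the westernmost column; NA marks nodata.

STACK_LAYERS <- c("MAT", "MAP", "P_cold", "P_warm", "P_winter", "P_summer",
                  "elevation")

#' Construct a climate stack
#'
#' Bundles co-registered climate and elevation layers on one geographic grid
#' with a shared validity mask. The mask is the intersection of per-layer
#' validity: a cell with nodata in any layer is invalid everywhere.
#'
#' @param layers Named list of numeric matrices (identical dimensions). Must
#'   include `MAT` (deg C), `MAP`, `P_cold`, `P_warm`, `P_winter`, `P_summer`
#'   (mm) and `elevation` (m).
#' @param xll,yll Longitude/latitude of the lower-left corner (degrees).
#' @param cellsize Cell size in degrees (square cells).
#' @return An object of class `climate_stack` with elements `layers`, `xll`,
#'   `yll`, `cellsize`, `nrow`, `ncol` and logical matrix `mask`.
#' @export
climate_stack <- function(layers, xll, yll, cellsize) {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  missing <- setdiff(STACK_LAYERS, names(layers))
  if (length(missing) > 0)
    stop("missing required layer(s): ", paste(missing, collapse = ", "))
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1)
    stop("all layers must share identical dimensions")
  mask <- Reduce(`&`, lapply(layers, function(m) is.finite(m)))
  x <- structure(
    list(layers = layers, xll = xll, yll = yll, cellsize = cellsize,
         nrow = nrow(layers[[1]]), ncol = ncol(layers[[1]]), mask = mask),
    class = "climate_stack")
  validate_stack(x)
  x
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: %d x %d cells @ %.6g deg, origin (%.4f, %.4f)\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  cat(sprintf("  layers: %s\n", paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  valid cells: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

# Check the physical invariants that make the layers a coherent set of
# co-registered annual/seasonal sums; errors on violation.
validate_stack <- function(stack, tol = 1e-6) {
  m <- stack$mask
  with(stack$layers, {
    if (any(MAP[m] < 0) || any(P_cold[m] < 0) || any(P_warm[m] < 0))
      stop("negative precipitation on valid cells")
    if (any(P_cold[m] > MAP[m] + tol) || any(P_warm[m] > MAP[m] + tol))
      stop("quarterly precipitation exceeds annual total")
    if (any(abs(P_winter[m] + P_summer[m] - MAP[m]) > pmax(tol, 1e-6 * MAP[m])))
      stop("P_winter + P_summer != MAP beyond tolerance")
  })
  invisible(TRUE)
}

# Cell-center coordinate vectors; row 1 is the northernmost row.
cell_lon <- function(stack) stack$xll + (seq_len(stack$ncol) - 0.5) * stack$cellsize
cell_lat <- function(stack) {
  ymax <- stack$yll + stack$nrow * stack$cellsize
  ymax - (seq_len(stack$nrow) - 0.5) * stack$cellsize
}

# Half-open cell assignment: cells cover [west, east) x (south-exclusive
# side handled by assigning edge points southward). Returns NA outside.
point_to_cell <- function(stack, lon, lat) {
  ymax <- stack$yll + stack$nrow * stack$cellsize
  # the 1e-9-cell guard keeps decimal edge coordinates (float-fuzzy by one
  # ulp) deterministically on the east/south side of a shared edge
  col <- floor((lon - stack$xll) / stack$cellsize + 1e-9) + 1L
  row <- floor((ymax - lat) / stack$cellsize + 1e-9) + 1L
  # the northern boundary itself belongs to the top row
  row[lat >= ymax] <- 1L
  out <- col < 1L | col > stack$ncol | row < 1L | row > stack$nrow
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Write a layer as an ESRI ASCII grid
#'
#' @param mat Numeric matrix, row 1 northernmost.
#' @param path Output file path.
#' @param xll,yll Lower-left corner (degrees).
#' @param cellsize Cell size (degrees).
#' @param nodata Value written for NA cells (default -9999).
#' @export
write_asc <- function(mat, path, xll, yll, cellsize, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)), con)
  m <- mat
  m[!is.finite(m)] <- nodata
  utils::write.table(format(m, digits = 9, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return List with `mat` (NA for nodata), `xll`, `yll`, `cellsize`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1])
  vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, skip = 6, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(body) != nr * nc) stop("grid body size mismatch in ", path)
  mat <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  mat[mat == nodata] <- NA_real_
  list(mat = mat, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
       cellsize = vals[["cellsize"]])
}

#' Read a set of raster layers into a climate stack
#'
#' All layers must be on the same geographic grid (verified within
#' tolerance, not resampled). The combined validity mask is the
#' intersection of per-layer validity.
#'
#' @param paths Named character vector or list, layer name -> `.asc` path.
#'   Must cover all required layers (see [climate_stack()]).
#' @param tol Geometry agreement tolerance in degrees.
#' @return A [climate_stack()].
#' @export
read_stack <- function(paths, tol = 1e-9) {
  paths <- unlist(paths)
  missing <- setdiff(STACK_LAYERS, names(paths))
  if (length(missing) > 0)
    stop("missing required layer(s): ", paste(missing, collapse = ", "))
  grids <- lapply(paths, read_asc)
  g0 <- grids[[1]]
  for (nm in names(grids)) {
    g <- grids[[nm]]
    if (!identical(dim(g$mat), dim(g0$mat)) ||
        abs(g$xll - g0$xll) > tol || abs(g$yll - g0$yll) > tol ||
        abs(g$cellsize - g0$cellsize) > tol)
      stop("layer '", nm, "' geometry incompatible with '",
           names(grids)[1], "'")
  }
  climate_stack(lapply(grids, `[[`, "mat"),
                xll = g0$xll, yll = g0$yll, cellsize = g0$cellsize)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param stack A [climate_stack()].
#' @param dir Output directory (created if absent).
#' @return Named vector of file paths.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    m <- stack$layers[[nm]]
    m[!stack$mask] <- NA_real_
    write_asc(m, file.path(dir, paste0(nm, ".asc")),
              stack$xll, stack$yll, stack$cellsize)
  }, character(1))
  invisible(paths)
}

#' Read an occurrence point table
#'
#' Expects CSV columns `id,lon,lat` and optionally `elev`.
#'
#' @param path CSV file path.
#' @return data.frame of class `occurrence_set`.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "lon", "lat") %in% names(df)))
    stop("points file must have columns id, lon, lat")
  occurrence_set(df)
}

#' Construct an occurrence set
#'
#' @param df data.frame with columns `id`, `lon`, `lat` and optional `elev`.
#' @return The validated data.frame with class `occurrence_set` prepended.
#' @export
occurrence_set <- function(df) {
  stopifnot(all(c("id", "lon", "lat") %in% names(df)))
  if (anyDuplicated(df$id)) stop("occurrence identifiers must be unique")
  if (any(df$lon < -180 | df$lon > 180)) stop("longitude out of [-180, 180]")
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude out of [-90, 90]")
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Extract layer values at points
#'
#' Values are taken from the cell containing each point (half-open cell
#' convention: a point on a shared edge belongs to the cell on its
#' east/south side). Points outside the extent or on masked cells are
#' flagged via `valid = FALSE`, never dropped.
#'
#' @param stack A [climate_stack()].
#' @param points An [occurrence_set()] (or data.frame with lon/lat).
#' @return data.frame: id, lon, lat, row, col, one column per layer, valid.
#' @export
extract_at_points <- function(stack, points) {
  rc <- point_to_cell(stack, points$lon, points$lat)
  n <- nrow(points)
  inside <- !is.na(rc$row)
  idx <- ifelse(inside, (rc$col - 1L) * stack$nrow + rc$row, NA_integer_)
  valid <- inside & stack$mask[ifelse(inside, idx, 1L)]
  vals <- lapply(stack$layers, function(m) {
    v <- rep(NA_real_, n)
    v[inside] <- m[idx[inside]]
    v
  })
  out <- data.frame(id = points$id, lon = points$lon, lat = points$lat,
                    row = rc$row, col = rc$col, vals, valid = valid)
  out
}

#' Restrict the valid mask to a distance buffer around points
#'
#' Retains valid cells whose great-circle distance (haversine, spherical
#' Earth R = 6371.0088 km) to the nearest input point is at most
#' `radius_km`.
#'
#' @param stack A [climate_stack()].
#' @param points An [occurrence_set()]; must be non-empty.
#' @param radius_km Buffer radius in kilometres (> 0).
#' @return Logical matrix aligned to the stack (TRUE = inside buffer and
#'   valid).
#' @export
buffer_region <- function(stack, points, radius_km) {
  if (nrow(points) == 0) stop("empty point set")
  stopifnot(radius_km > 0)
  lons <- cell_lon(stack); lats <- cell_lat(stack)
  lon_g <- matrix(rep(lons, each = stack$nrow), nrow = stack$nrow)
  lat_g <- matrix(rep(lats, times = stack$ncol), nrow = stack$nrow)
  mind <- matrix(Inf, stack$nrow, stack$ncol)
  for (k in seq_len(nrow(points))) {
    d <- great_circle_km(lon_g, lat_g, points$lon[k], points$lat[k])
    mind <- pmin(mind, d)
  }
  stack$mask & (mind <= radius_km)
}

#' Sample background points
#'
#' Draws `n` cells uniformly (with replacement: per-cell counts follow a
#' uniform multinomial) from the valid cells of `region` and returns cell
#' centres with extracted layer values.
#'
#' @param stack A [climate_stack()].
#' @param region Logical matrix aligned to the stack (e.g. from
#'   [buffer_region()]); defaults to the stack mask.
#' @param n Number of points (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @return List of class `background_sample`: `points` data.frame (lon,
#'   lat, cell row/col, layer values), `seed`, `n`.
#' @export
sample_background <- function(stack, region = NULL, n, seed) {
  if (is.null(region)) region <- stack$mask
  cells <- which(region & stack$mask)
  if (length(cells) == 0) stop("region contains no valid cells")
  stopifnot(n >= 1)
  idx <- cells[with_seed(seed, sample.int(length(cells), n, replace = TRUE))]
  row <- ((idx - 1L) %% stack$nrow) + 1L
  col <- ((idx - 1L) %/% stack$nrow) + 1L
  lons <- cell_lon(stack); lats <- cell_lat(stack)
  vals <- lapply(stack$layers, function(m) m[idx])
  pts <- data.frame(lon = lons[col], lat = lats[row], row = row, col = col,
                    vals)
  structure(list(points = pts, seed = seed, n = n),
            class = "background_sample")
}
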