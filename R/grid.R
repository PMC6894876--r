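#' Georeferenced grid
#'
#' A minimal raster container: a numeric matrix plus square-cell
#' georeferencing.  Row 1 is the northernmost row (map display order);
#' `NA` is the nodata value.  Coordinates are projected map units
#' (metres assumed by the stock-accounting functions).
#'
#' @param values numeric matrix, row 1 = north.
#' @param cellsize cell edge length in map units (> 0).
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @return An object of class `geo_grid`: a list with elements
#'   `values`, `cellsize`, `xmin`, `ymin`.
#' @export
geo_grid <- function(values, cellsize = 1, xmin = 0, ymin = 0) {
  values <- as.matrix(values)
  if (!is.numeric(values) && !is.logical(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || !is.finite(cellsize) ||
      cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(list(values = values, cellsize = cellsize,
                 xmin = xmin, ymin = ymin),
            class = "geo_grid")
}

#' @export
dim.geo_grid <- function(x) dim(x$values)

#' @export
print.geo_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<geo_grid> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              d[1], d[2], x$cellsize, x$xmin, x$ymin))
  cat(sprintf("  values: min %s, max %s, %d nodata\n",
              format(suppressWarnings(min(x$values, na.rm = TRUE))),
              format(suppressWarnings(max(x$values, na.rm = TRUE))),
              sum(is.na(x$values))))
  invisible(x)
}

is_geo_grid <- function(x) inherits(x, "geo_grid")

#' Check that two grids share shape and georeferencing
#'
#' @param a,b `geo_grid` objects.
#' @param tol tolerance on georeferencing comparison.
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
check_registration <- function(a, b, tol = 1e-9) {
  if (!is_geo_grid(a) || !is_geo_grid(b))
    stop("both arguments must be geo_grid objects")
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("grid shape mismatch: %s vs %s",
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  if (abs(a$cellsize - b$cellsize) > tol ||
      abs(a$xmin - b$xmin) > tol || abs(a$ymin - b$ymin) > tol)
    stop("grid georeferencing mismatch")
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a `geo_grid`.
#' @return list with numeric vectors `x` (per column, west to east) and
#'   `y` (per row, north to south, matching row order of `values`).
#' @export
grid_coords <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$xmin + (seq_len(d[2]) - 0.5) * grid$cellsize,
       y = grid$ymin + (d[1] - seq_len(d[1]) + 0.5) * grid$cellsize)
}

# ---- grassland-type mask ----------------------------------------------------

#' Grassland type codes used by mask grids
#' @export
mask_levels <- function() c(other = 0L, steppe = 1L, meadow = 2L)

#' Grassland-type mask grid
#'
#' A `geo_grid` whose values are integer codes 0 = other, 1 = steppe,
#' 2 = meadow (see [mask_levels()]).  A character matrix of level names
#' is also accepted.
#'
#' @inheritParams geo_grid
#' @export
grass_mask <- function(values, cellsize = 1, xmin = 0, ymin = 0) {
  values <- as.matrix(values)
  if (is.character(values)) {
    lv <- mask_levels()
    bad <- !(values %in% names(lv)) & !is.na(values)
    if (any(bad)) stop("unknown grassland type: ", values[bad][1])
    values <- matrix(lv[values], nrow = nrow(values))
  }
  storage.mode(values) <- "integer"
  if (!all(values %in% c(mask_levels(), NA)))
    stop("mask codes must be 0 (other), 1 (steppe) or 2 (meadow)")
  g <- geo_grid(values, cellsize, xmin, ymin)
  class(g) <- c("grass_mask", class(g))
  g
}

#' Logical matrix selecting one grassland type from a mask
#'
#' @param mask a `grass_mask`.
#' @param type `"steppe"`, `"meadow"` or `"other"`.
#' @export
mask_is <- function(mask, type) {
  code <- mask_levels()[[match.arg(type, names(mask_levels()))]]
  m <- mask$values == code
  m[is.na(m)] <- FALSE
  m
}

# ---- annual stacks ----------------------------------------------------------

#' Year-indexed stack of co-registered grids
#'
#' @param grids list of `geo_grid` objects sharing shape and
#'   georeferencing.
#' @param years integer vector, one per grid, strictly increasing.
#' @return object of class `grid_stack` with elements `grids`, `years`.
#' @export
grid_stack <- function(grids, years) {
  if (!length(grids)) stop("empty stack")
  if (length(grids) != length(years)) stop("one year per grid required")
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  for (g in grids[-1]) check_registration(grids[[1]], g)
  structure(list(grids = grids, years = as.integer(years)),
            class = "grid_stack")
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf("<grid_stack> %d years (%d-%d), %s cells\n",
              length(x$years), min(x$years), max(x$years),
              paste(dim(x$grids[[1]]$values), collapse = "x")))
  invisible(x)
}

#' Flatten a stack to a pixels-by-years matrix
#'
#' Pixels in column-major matrix order of the underlying grids.
#' @param stack a `grid_stack`.
#' @export
stack_matrix <- function(stack) {
  vapply(stack$grids, function(g) as.vector(g$values),
         numeric(length(stack$grids[[1]]$values)))
}

# ---- plain-text raster I/O --------------------------------------------------

# ESRI ASCII grid is used as the on-disk raster format: the environment
# ships no GeoTIFF-capable R package and the format is plain text, which
# keeps fixtures reviewable and byte-stable.

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid a `geo_grid`.
#' @param path output file path.
#' @param nodata sentinel written for `NA` cells.
#' @param digits significant digits used for formatting.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 10) {
  stopifnot(is_geo_grid(grid))
  v <- grid$values
  hdr <- c(sprintf("NCOLS %d", ncol(v)),
           sprintf("NROWS %d", nrow(v)),
           sprintf("XLLCORNER %.10g", grid$xmin),
           sprintf("YLLCORNER %.10g", grid$ymin),
           sprintf("CELLSIZE %.10g", grid$cellsize),
           sprintf("NODATA_VALUE %.10g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @param mask if `TRUE` return a [grass_mask()].
#' @return a `geo_grid` (or `grass_mask`).
#' @export
read_ascii_grid <- function(path, mask = FALSE) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    if (!length(ln)) stop("missing ASCII grid header field: ", key)
    as.numeric(sub("^\\S+\\s+", "", ln[1]))
  }
  nc <- as.integer(val("NCOLS")); nr <- as.integer(val("NROWS"))
  nodata <- val("NODATA_VALUE")
  nums <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(nums) != nr * nc) stop("ASCII grid body size mismatch")
  m <- matrix(nums, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  if (mask) grass_mask(m, val("CELLSIZE"), val("XLLCORNER"), val("YLLCORNER"))
  else geo_grid(m, val("CELLSIZE"), val("XLLCORNER"), val("YLLCORNER"))
}
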