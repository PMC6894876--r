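#' Annual maximum-value composite
#'
#' Per-pixel maximum over sub-annual NDVI composites, the standard MVC
#' cloud/atmosphere suppression.  Nodata is ignored; a pixel is nodata
#' only when every input is nodata.
#'
#' @param composites list of co-registered `geo_grid` objects for one
#'   year (length >= 1).
#' @return a `geo_grid`.
#' @export
mvc_annual <- function(composites) {
  if (!length(composites)) stop("need at least one composite")
  for (g in composites[-1]) check_registration(composites[[1]], g)
  arr <- vapply(composites, function(g) g$values,
                composites[[1]]$values)
  dim(arr) <- c(dim(composites[[1]]$values), length(composites))
  out <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  g1 <- composites[[1]]
  geo_grid(out, g1$cellsize, g1$xmin, g1$ymin)
}

#' Block-mean spatial aggregation
#'
#' Non-overlapping `factor` x `factor` block means ignoring nodata
#' (partial edge blocks average their available cells).  The output
#' cell size is scaled by `factor`; the lower-left corner is kept.
#'
#' @param grid a `geo_grid`.
#' @param factor positive integer aggregation factor (1 = identity).
#' @return a `geo_grid` at the coarser resolution.
#' @export
aggregate_blocks <- function(grid, factor) {
  stopifnot(is_geo_grid(grid))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  # row 1 is north: block rows count from the top so that the
  # aggregated grid keeps display order; ymin moves if nr %% factor != 0
  br <- ceiling(seq_len(nr) / factor)
  bc <- ceiling(seq_len(nc) / factor)
  idx <- (rep(bc, each = nr) - 1L) * max(br) + rep(br, times = nc)
  sums <- tapply(as.vector(v), idx, function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  out <- matrix(NA_real_, max(br), max(bc))
  out[as.integer(names(sums))] <- as.numeric(sums)
  # the top block row anchors at the original top edge
  new_ymin <- grid$ymin + nr * grid$cellsize -
    max(br) * factor * grid$cellsize
  geo_grid(out, grid$cellsize * factor, grid$xmin, new_ymin)
}

#' NDVI to SOCD regression coefficients per grassland type
#'
#' Linear retrieval of 0-30 cm SOCD (kg C m^-2) from annual NDVI,
#' with a separate equation per grassland type:
#' steppe `SOCD = 20.201 NDVI - 0.9206`,
#' meadow `SOCD = 17.846 NDVI + 0.0155`.
#' @return named list of `c(gain, offset)` pairs.
#' @export
socd_ndvi_coefs <- function() {
  list(steppe = c(gain = 20.201, offset = -0.9206),
       meadow = c(gain = 17.846, offset = 0.0155))
}

#' Map NDVI to SOCD by grassland type
#'
#' Steppe and meadow pixels each use their own linear equation; other
#' or unmasked pixels become nodata.  Negative predictions (possible
#' for steppe NDVI below ~0.0456) are clamped to 0 and flagged when
#' `clamp_negative` is on.  Pixels at or above the NDVI saturation
#' threshold are flagged (no value adjustment).
#'
#' @param ndvi `geo_grid` of annual NDVI in [-1, 1].
#' @param mask co-registered [grass_mask()].
#' @param clamp_negative clamp negative SOCD to 0 (default `TRUE`).
#' @param saturation NDVI saturation flag threshold (default 0.8).
#' @param coefs regression coefficients, see [socd_ndvi_coefs()].
#' @param year optional year tag carried on the result.
#' @return object of class `socd_map`: list with `socd` (`geo_grid`),
#'   `saturated` and `clamped` (logical matrices), `method`, `year`.
#' @export
ndvi_to_socd <- function(ndvi, mask, clamp_negative = TRUE,
                         saturation = 0.8, coefs = socd_ndvi_coefs(),
                         year = NA_integer_) {
  check_registration(ndvi, mask)
  v <- ndvi$values
  if (any(v < -1 | v > 1, na.rm = TRUE))
    stop("NDVI values outside [-1, 1]")
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (ty in names(coefs)) {
    sel <- mask_is(mask, ty)
    out[sel] <- coefs[[ty]]["gain"] * v[sel] + coefs[[ty]]["offset"]
  }
  saturated <- !is.na(v) & !is.na(out) & v >= saturation
  clamped <- matrix(FALSE, nrow(v), ncol(v))
  if (clamp_negative) {
    clamped <- !is.na(out) & out < 0
    out[clamped] <- 0
  }
  structure(list(socd = geo_grid(out, ndvi$cellsize, ndvi$xmin, ndvi$ymin),
                 saturated = saturated, clamped = clamped,
                 method = "ndvi", year = year),
            class = "socd_map")
}

#' @export
print.socd_map <- function(x, ...) {
  cat(sprintf("<socd_map> method %s, year %s, %d saturated, %d clamped\n",
              x$method, x$year, sum(x$saturated), sum(x$clamped)))
  print(x$socd)
  invisible(x)
}

#' Annual SOCD stack from an NDVI stack
#'
#' Applies [ndvi_to_socd()] to every year of an NDVI stack.
#'
#' @param ndvi_stack a `grid_stack` of annual NDVI grids.
#' @param mask co-registered [grass_mask()].
#' @param ... passed to [ndvi_to_socd()].
#' @return a `grid_stack` of SOCD grids.
#' @export
socd_stack_from_ndvi <- function(ndvi_stack, mask, ...) {
  maps <- Map(function(g, yr) ndvi_to_socd(g, mask, year = yr, ...)$socd,
              ndvi_stack$grids, ndvi_stack$years)
  grid_stack(maps, ndvi_stack$years)
}
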