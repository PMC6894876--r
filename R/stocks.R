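#' Interpolate point observations onto a grid
#'
#' Point-to-raster interpolation for profile-based SOCD surfaces.
#' Two interpolators are provided:
#' * `"idw"` -- inverse distance weighting with power `power` over the
#'   `k` nearest points (exact at data sites);
#' * `"kriging"` -- ordinary kriging with an isotropic exponential
#'   variogram `gamma(h) = nugget + psill * (1 - exp(-h / range))`,
#'   parameters supplied or fitted by method-of-moments on the binned
#'   empirical variogram.  With nugget 0 kriging is exact at data
#'   sites.  A degenerate variogram fit falls back to IDW with a
#'   warning.
#'
#' @param points data frame with columns `x`, `y`, `value`.
#' @param template `geo_grid` defining the target shape and
#'   georeferencing (its values are ignored).
#' @param method `"idw"` or `"kriging"`.
#' @param power IDW distance power (default 2).
#' @param k number of nearest neighbours for IDW (default 12).
#' @param variogram optional named vector `c(nugget, psill, range)`.
#' @return a `geo_grid` of interpolated values.
#' @export
interpolate_points <- function(points, template,
                               method = c("idw", "kriging"),
                               power = 2, k = 12, variogram = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(points),
            all(c("x", "y", "value") %in% names(points)))
  points <- points[stats::complete.cases(points[c("x", "y", "value")]), ]
  if (!nrow(points)) stop("no points to interpolate")
  if (method == "kriging") {
    vg <- variogram
    if (is.null(vg)) vg <- tryCatch(fit_exp_variogram(points),
                                    error = function(e) NULL)
    if (is.null(vg) || vg["psill"] <= 0 || vg["range"] <= 0) {
      warning("degenerate variogram; falling back to IDW")
      method <- "idw"
    } else {
      return(ok_krige(points, template, vg))
    }
  }
  idw_grid(points, template, power = power, k = k)
}

idw_grid <- function(points, template, power = 2, k = 12) {
  co <- grid_coords(template)
  gx <- rep(co$x, each = length(co$y))
  gy <- rep(co$y, times = length(co$x))
  k <- min(k, nrow(points))
  out <- numeric(length(gx))
  for (cell in seq_along(gx)) {
    d <- sqrt((points$x - gx[cell])^2 + (points$y - gy[cell])^2)
    if (any(d < 1e-12)) { out[cell] <- points$value[which.min(d)]; next }
    sel <- order(d)[seq_len(k)]
    w <- 1 / d[sel]^power
    out[cell] <- sum(w * points$value[sel]) / sum(w)
  }
  geo_grid(matrix(out, nrow = length(co$y)),
           template$cellsize, template$xmin, template$ymin)
}

#' Method-of-moments exponential variogram fit
#'
#' Bins the empirical semivariance up to half the maximum pairwise
#' distance and least-squares fits `nugget + psill*(1 - exp(-h/range))`.
#'
#' @param points data frame with `x`, `y`, `value`.
#' @param n_bins number of distance bins (default 12).
#' @return named vector `c(nugget, psill, range)`.
#' @export
fit_exp_variogram <- function(points, n_bins = 12) {
  n <- nrow(points)
  if (n < 10) stop("too few points to fit a variogram")
  pr <- utils::combn(n, 2)
  h <- sqrt((points$x[pr[1, ]] - points$x[pr[2, ]])^2 +
              (points$y[pr[1, ]] - points$y[pr[2, ]])^2)
  sv <- (points$value[pr[1, ]] - points$value[pr[2, ]])^2 / 2
  hmax <- max(h) / 2
  keep <- h <= hmax & h > 0
  h <- h[keep]; sv <- sv[keep]
  bins <- cut(h, breaks = seq(0, hmax, length.out = n_bins + 1))
  eh <- tapply(h, bins, mean)
  eg <- tapply(sv, bins, mean)
  ok <- !is.na(eh) & !is.na(eg)
  eh <- eh[ok]; eg <- eg[ok]
  if (length(eh) < 4) stop("too few variogram bins")
  obj <- function(p) {
    g <- p[1] + p[2] * (1 - exp(-eh / p[3]))
    sum((g - eg)^2)
  }
  init <- c(0, max(eg), hmax / 3)
  fit <- stats::optim(init, obj, lower = c(0, 1e-12, hmax * 1e-3),
                      upper = c(max(eg), 10 * max(eg), 10 * hmax),
                      method = "L-BFGS-B")
  stats::setNames(fit$par, c("nugget", "psill", "range"))
}

ok_krige <- function(points, template, vg) {
  gamma_fn <- function(h) {
    g <- vg["nugget"] + vg["psill"] * (1 - exp(-h / vg["range"]))
    g[h < 1e-12] <- 0   # gamma(0) = 0 even with a nugget: exactness at sites
    unname(g)
  }
  n <- nrow(points)
  dmat <- as.matrix(stats::dist(points[c("x", "y")]))
  A <- rbind(cbind(gamma_fn(dmat), 1), c(rep(1, n), 0))
  co <- grid_coords(template)
  gx <- rep(co$x, each = length(co$y))
  gy <- rep(co$y, times = length(co$x))
  d0 <- sqrt(outer(points$x, gx, "-")^2 + outer(points$y, gy, "-")^2)
  rhs <- rbind(gamma_fn(d0), 1)
  lam <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(lam)) {
    warning("singular kriging system; falling back to IDW")
    return(idw_grid(points, template))
  }
  vals <- colSums(lam[seq_len(n), , drop = FALSE] * points$value)
  # exact at (numerically coincident) data sites
  hit <- apply(d0, 2, function(d) {
    i <- which.min(d); if (d[i] < 1e-9) i else NA_integer_
  })
  vals[!is.na(hit)] <- points$value[hit[!is.na(hit)]]
  geo_grid(matrix(vals, nrow = length(co$y)),
           template$cellsize, template$xmin, template$ymin)
}

#' Zonal SOC storage by grassland type
#'
#' `storage = sum(SOCD * cell_area)` over the valid pixels of each
#' type, reported in 10^10 kg.  Nodata pixels are excluded from both
#' storage and area.  An `all` row over the union of steppe and meadow
#' is appended; because types partition the mask it equals the sum of
#' the type rows exactly.
#'
#' @param socd `geo_grid` of SOCD in kg C m^-2.
#' @param mask co-registered [grass_mask()].
#' @param cell_area pixel area in m^2 (default `cellsize^2`, projected
#'   units assumed).
#' @param method method tag carried into the output.
#' @param layer layer tag (default `"total"`).
#' @return data frame with columns `method`, `grassland_type`, `layer`,
#'   `n_cells`, `area_km2`, `mean_socd`, `storage_1e10kg`.
#' @export
zonal_storage <- function(socd, mask, cell_area = NULL,
                          method = "ndvi", layer = "total") {
  check_registration(socd, mask)
  if (is.null(cell_area)) cell_area <- socd$cellsize^2
  if (!is.numeric(cell_area) || cell_area <= 0)
    stop("`cell_area` must be > 0")
  one <- function(type) {
    sel <- mask_is(mask, type) & !is.na(socd$values)
    n <- sum(sel)
    storage_kg <- sum(socd$values[sel]) * cell_area
    data.frame(method = method, grassland_type = type, layer = layer,
               n_cells = n, area_km2 = n * cell_area / 1e6,
               mean_socd = if (n) mean(socd$values[sel]) else NA_real_,
               storage_1e10kg = storage_kg / 1e10)
  }
  rows <- rbind(one("steppe"), one("meadow"))
  all_row <- data.frame(method = method, grassland_type = "all",
                        layer = layer, n_cells = sum(rows$n_cells),
                        area_km2 = sum(rows$area_km2),
                        mean_socd = NA_real_,
                        storage_1e10kg = sum(rows$storage_1e10kg))
  if (all_row$n_cells > 0) {
    w <- rows$n_cells / all_row$n_cells
    all_row$mean_socd <- sum(w * rows$mean_socd, na.rm = TRUE)
  }
  rbind(rows, all_row)
}

#' Regional storage from profile group means
#'
#' Profile-based accounting: per grassland type and layer,
#' `storage = mean SOCD x type area`.  Areas are supplied per type in
#' km^2 (e.g. counted off the mask).
#'
#' @param group_means output of [socd_group_means()].
#' @param areas_km2 named numeric vector of areas by grassland type.
#' @return data frame in the same shape as [zonal_storage()] output.
#' @export
profile_storage <- function(group_means, areas_km2) {
  stopifnot(all(group_means$grassland_type %in% names(areas_km2)))
  a <- areas_km2[group_means$grassland_type]
  data.frame(method = group_means$method,
             grassland_type = group_means$grassland_type,
             layer = group_means$layer,
             n_cells = NA_integer_, area_km2 = as.numeric(a),
             mean_socd = group_means$mean_socd,
             storage_1e10kg = group_means$mean_socd * a * 1e6 / 1e10)
}

#' Combine per-method storage summaries into one comparison table
#'
#' Binds summaries into a long method x type x layer table.  For
#' methods carrying layer rows, a `"total"` row is added per method x
#' type when absent (sum of the layer rows).  Profile-based methods
#' contribute per-layer decompositions; the NDVI method is total-only
#' (its regression predicts the whole 0-30 cm stock, so no per-layer
#' split exists).
#'
#' @param summaries list of data frames shaped like [zonal_storage()]
#'   output.
#' @return single long-format data frame.
#' @export
storage_table <- function(summaries) {
  if (!length(summaries)) stop("need at least one summary")
  tbl <- do.call(rbind, summaries)
  sp <- split(tbl, list(tbl$method, tbl$grassland_type), drop = TRUE)
  add <- lapply(sp, function(g) {
    if ("total" %in% g$layer) return(NULL)
    tot <- g[1, ]
    tot$layer <- "total"
    tot$mean_socd <- sum(g$mean_socd)
    tot$storage_1e10kg <- sum(g$storage_1e10kg)
    tot
  })
  add <- add[!vapply(add, is.null, TRUE)]
  out <- rbind(tbl, do.call(rbind, add))
  rownames(out) <- NULL
  out[order(out$method, out$grassland_type, out$layer), ]
}
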