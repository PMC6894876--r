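#' Least-squares trend slope of an annual series
#'
#' Closed-form OLS slope of value against serial year number,
#' `(n*sum(i*x_i) - sum(i)*sum(x_i)) / (n*sum(i^2) - sum(i)^2)`.
#' Missing entries are dropped pairwise with their index.
#'
#' @param x annual values (SOCD of year i).
#' @param index serial year numbers (default `1:length(x)`).
#' @return slope in value units per year, or `NA` when fewer than two
#'   distinct time points remain.
#' @export
ols_slope <- function(x, index = seq_along(x)) {
  stopifnot(length(x) == length(index))
  ok <- !is.na(x) & !is.na(index)
  x <- x[ok]; i <- index[ok]
  n <- length(x)
  if (n < 2L || length(unique(i)) < 2L) return(NA_real_)
  (n * sum(i * x) - sum(i) * sum(x)) / (n * sum(i^2) - sum(i)^2)
}

#' Mann-Kendall monotone trend test
#'
#' Nonparametric trend test on an annual series:
#' `S = sum_{i<j} sign(x_j - x_i)`, variance with tie correction
#' `Var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tied
#' groups of extent t, and the continuity-corrected normal deviate
#' `Z = (S-1)/sqrt(Var)` for `S > 0`, 0 for `S = 0`,
#' `(S+1)/sqrt(Var)` for `S < 0`.  Significance is the three-way rule
#' at the 5% normal quantile: `Z > 1.96` significant increase,
#' `Z < -1.96` significant decrease, otherwise none.
#'
#' @param x annual values; `NA`s are dropped (order retained).
#' @param z_crit critical deviate (default 1.96).
#' @return list with `s`, `var_s`, `z` and `significance`
#'   (`"sig_increase"`, `"none"`, `"sig_decrease"`).
#' @export
mann_kendall <- function(x, z_crit = 1.96) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("Mann-Kendall test needs at least 3 non-missing values")
  d <- sign(outer(x, x, "-"))       # d[i,j] = sign(x_i - x_j)
  s <- sum(d[lower.tri(d)])         # i > j, i.e. later minus earlier
  ties <- table(x)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s)
       else 0
  sig <- if (z > z_crit) "sig_increase"
         else if (z < -z_crit) "sig_decrease"
         else "none"
  list(s = s, var_s = var_s, z = z, significance = sig)
}

#' Sen (Theil-Sen / Kendall) slope
#'
#' Median of all pairwise slopes `(x_j - x_i)/(index_j - index_i)`,
#' i < j; a robust trend magnitude whose sign matches the Mann-Kendall
#' S statistic.
#'
#' @inheritParams ols_slope
#' @return the median pairwise slope, `NA` if fewer than 2 points.
#' @export
sen_slope <- function(x, index = seq_along(x)) {
  stopifnot(length(x) == length(index))
  ok <- !is.na(x) & !is.na(index)
  x <- x[ok]; i <- index[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  pair <- utils::combn(n, 2)
  stats::median((x[pair[2, ]] - x[pair[1, ]]) / (i[pair[2, ]] - i[pair[1, ]]))
}

#' Five-level slope classification
#'
#' Classifies a trend slope into the five half-open ranges
#' (slope units per year):
#' \tabular{ll}{
#'   `slope < -0.1`          \tab significant decrease \cr
#'   `-0.1 <= slope < -0.01` \tab non-significant decrease \cr
#'   `-0.01 <= slope < 0.01` \tab nearly unchangeable \cr
#'   `0.01 <= slope < 0.1`   \tab non-significant increase \cr
#'   `slope >= 0.1`          \tab significant increase
#' }
#' The "significant" wording is a slope-magnitude label, decoupled from
#' the Mann-Kendall Z test, which is reported separately.
#'
#' @param slope numeric vector; `NA` passes through.
#' @return factor with the five levels above (in increasing order).
#' @export
classify_trend <- function(slope) {
  if (any(is.infinite(slope))) stop("slope must be finite or NA")
  labs <- trend_class_levels()
  cut(slope, breaks = c(-Inf, -0.1, -0.01, 0.01, 0.1, Inf),
      labels = labs, right = FALSE)
}

#' @rdname classify_trend
#' @export
trend_class_levels <- function() {
  c("significant decrease", "non-significant decrease",
    "nearly unchangeable", "non-significant increase",
    "significant increase")
}

#' Per-pixel trend analysis of an annual SOCD stack
#'
#' Applies [ols_slope()], [mann_kendall()], [sen_slope()] and
#' [classify_trend()] to every pixel series with at least `min_years`
#' valid years, and tabulates class area percentages by grassland
#' type.
#'
#' @param stack a `grid_stack` of >= 3 co-registered annual grids.
#' @param mask optional co-registered [grass_mask()] for the area
#'   table; without it only the total column is produced.
#' @param min_years minimum valid years per pixel (default 3).
#' @return list with `geo_grid`s `slope`, `z`, `sen`, `class` (integer
#'   codes 1..5 into [trend_class_levels()]) and the data frame
#'   `class_area` (percent of valid pixels per class, by type and
#'   total; columns sum to 100).
#' @export
trend_raster <- function(stack, mask = NULL, min_years = 3) {
  stopifnot(inherits(stack, "grid_stack"))
  if (length(stack$years) < 3L) stop("need at least 3 annual grids")
  if (!is.null(mask)) check_registration(stack$grids[[1]], mask)
  X <- stack_matrix(stack)                  # pixels x years
  idx <- seq_along(stack$years)
  nvalid <- rowSums(!is.na(X))
  slope <- z <- sen <- rep(NA_real_, nrow(X))
  run <- which(nvalid >= max(min_years, 3L))
  for (p in run) {
    xs <- X[p, ]
    slope[p] <- ols_slope(xs, idx)
    mk <- mann_kendall(xs)
    z[p] <- mk$z
    sen[p] <- sen_slope(xs, idx)
  }
  cls <- as.integer(classify_trend(slope))
  tmpl <- stack$grids[[1]]
  as_grid <- function(v) geo_grid(matrix(v, nrow(tmpl$values)),
                                  tmpl$cellsize, tmpl$xmin, tmpl$ymin)
  out <- list(slope = as_grid(slope), z = as_grid(z), sen = as_grid(sen),
              class = as_grid(as.numeric(cls)))
  out$class_area <- class_area_table(out$class, mask)
  out
}

#' Class-area percentage table
#'
#' Percentages of valid (classified) pixels in each of the five trend
#' classes, by grassland type and in total.  Each column sums to 100.
#'
#' @param class_grid `geo_grid` of integer class codes 1..5.
#' @param mask optional co-registered [grass_mask()].
#' @return data frame with columns `class` and one percentage column
#'   per stratum (`steppe`, `meadow` when a mask is given, plus
#'   `total`).
#' @export
class_area_table <- function(class_grid, mask = NULL) {
  cls <- as.vector(class_grid$values)
  labs <- trend_class_levels()
  pct <- function(sel) {
    v <- cls[sel & !is.na(cls)]
    if (!length(v)) return(rep(NA_real_, length(labs)))
    as.numeric(tabulate(v, nbins = length(labs))) / length(v) * 100
  }
  out <- data.frame(class = labs)
  if (!is.null(mask)) {
    check_registration(class_grid, mask)
    out$steppe <- pct(as.vector(mask_is(mask, "steppe")))
    out$meadow <- pct(as.vector(mask_is(mask, "meadow")))
  }
  out$total <- pct(rep(TRUE, length(cls)))
  out
}

#' Regional mean annual series
#'
#' Per-year mean SOCD over the pixels of one grassland type; the
#' resulting series feeds [ols_slope()] and [mann_kendall()] for
#' region-level change rates.
#'
#' @param stack a `grid_stack`.
#' @param mask co-registered [grass_mask()].
#' @param type `"steppe"` or `"meadow"`.
#' @return data frame with columns `year` and `mean_socd`.
#' @export
regional_series <- function(stack, mask, type) {
  check_registration(stack$grids[[1]], mask)
  sel <- mask_is(mask, type)
  if (!any(sel)) stop("no pixels of type ", type, " in mask")
  vals <- vapply(stack$grids, function(g) mean(g$values[sel], na.rm = TRUE),
                 0)
  data.frame(year = stack$years, mean_socd = vals)
}
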