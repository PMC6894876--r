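#' Pearson correlation coefficient
#'
#' `r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) *
#' sum((y - ybar)^2))`, computed on pairwise-complete observations.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return `r` in [-1, 1]; `NA` with a warning when either variable has
#'   zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  r <- sum(dx * dy) / den
  max(-1, min(1, r))
}

#' Two-level significance flag for a correlation
#'
#' Two-sided t test with `t = r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom, flagged at the 0.01 and 0.05 levels.  `|r| = 1`
#' is reported as `p<0.01` by convention (the statistic diverges).
#'
#' @param r correlation coefficient.
#' @param n number of pairs (>= 3).
#' @return list with `p` and `flag` (`"p<0.01"`, `"p<0.05"`, `"ns"`).
#' @export
cor_significance <- function(r, n) {
  if (is.na(r)) return(list(p = NA_real_, flag = "undefined"))
  if (n < 3L) stop("need n >= 3")
  if (abs(r) >= 1) return(list(p = 0, flag = "p<0.01"))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  flag <- if (p < 0.01) "p<0.01" else if (p < 0.05) "p<0.05" else "ns"
  list(p = p, flag = flag)
}

#' Pairwise correlation screening of plot-survey variables
#'
#' All pairwise Pearson correlations among the selected columns with
#' pairwise deletion of missing values, plus two-level significance
#' flags -- the correlation-matrix screening of SOCD against its
#' candidate environmental drivers (biomass, soil moisture,
#' temperature, conductivity, elevation).  No multiple-testing
#' correction is applied by default, matching common practice for this
#' style of screening; `adjust` exposes `p.adjust` methods.
#'
#' @param data data frame of plot surveys (one row per plot).
#' @param columns columns to correlate (default: all numeric).
#' @param adjust p-value adjustment method (default `"none"`).
#' @return object of class `cor_screen`: list of matrices `r`, `p`,
#'   `n`, `flag`.  `r` is exactly symmetric with unit diagonal.
#' @export
correlation_matrix <- function(data, columns = NULL, adjust = "none") {
  if (is.null(columns))
    columns <- names(data)[vapply(data, is.numeric, TRUE)]
  stopifnot(all(columns %in% names(data)), length(columns) >= 2L)
  k <- length(columns)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); nm <- matrix(NA_real_, k, k)
  flag <- matrix("", k, k)
  dimnames(r) <- dimnames(p) <- dimnames(nm) <- dimnames(flag) <-
    list(columns, columns)
  diag(flag) <- "p<0.01"
  diag(nm) <- colSums(!is.na(data[columns]))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- data[[columns[i]]]; xj <- data[[columns[j]]]
    n_ij <- sum(!is.na(xi) & !is.na(xj))
    if (n_ij < 3L) stop("fewer than 3 complete pairs for ",
                        columns[i], " vs ", columns[j])
    rij <- suppressWarnings(pearson_r(xi, xj))
    r[i, j] <- r[j, i] <- rij
    nm[i, j] <- nm[j, i] <- n_ij
    sg <- cor_significance(rij, n_ij)
    p[i, j] <- p[j, i] <- sg$p
  }
  if (adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fl <- if (is.na(r[i, j])) "undefined"
          else if (p[i, j] < 0.01) "p<0.01"
          else if (p[i, j] < 0.05) "p<0.05" else "ns"
    flag[i, j] <- flag[j, i] <- fl
  }
  structure(list(r = r, p = p, n = nm, flag = flag), class = "cor_screen")
}

#' @export
print.cor_screen <- function(x, digits = 3, ...) {
  cat("<cor_screen> Pearson r (flags in brackets)\n")
  k <- ncol(x$r)
  disp <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k))
    disp[i, j] <- sprintf("%s [%s]", format(round(x$r[i, j], digits)),
                          x$flag[i, j])
  print(disp, quote = FALSE)
  invisible(x)
}

#' Long-format view of a correlation screen
#'
#' @param x a `cor_screen`.
#' @param ... unused.
#' @return data frame `var1`, `var2`, `r`, `n`, `p`, `flag`, one row
#'   per unordered variable pair.
#' @export
as.data.frame.cor_screen <- function(x, ...) {
  k <- ncol(x$r); nms <- colnames(x$r)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = nms[i], var2 = nms[j], r = x$r[i, j],
      n = x$n[i, j], p = x$p[i, j], flag = x$flag[i, j])
  do.call(rbind, rows)
}
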