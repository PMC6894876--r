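#' Pedotransfer model relating bulk density to soil organic carbon
#'
#' The supported functional form is `BD = c + a * exp(-b * SOC)` with
#' `BD` in g cm^-3 and `SOC` in g kg^-1.  Models with `c = 0` are pure
#' exponentials; `c > 0` adds a bulk-density asymptote that caps the
#' mineral-soil limit.  The inverse (SOC from BD) is defined on the
#' half-open domain `(c, a + c]`: at `BD = a + c` the inverse is 0, and
#' no finite SOC reproduces a BD at or below the asymptote `c`.
#'
#' @param a exponential amplitude, g cm^-3 (> 0).
#' @param b decay rate per unit SOC, kg g^-1 (> 0).
#' @param c asymptotic bulk density, g cm^-3 (>= 0).
#' @param id optional identifier carried through outputs.
#' @return object of class `ptf_model` with fields `id`, `form`
#'   (`"offset_exp"` or `"pure_exp"`), `a`, `b`, `c` and `bd_domain`
#'   (length-2 vector, lower bound exclusive, upper inclusive).
#' @examples
#' m <- ptf_model(a = 1.4055, b = 0.1039, c = 0, id = "4")
#' forward_bd(m, 0)          # 1.4055
#' invert_soc(m, 1.4055)     # 0
#' @export
ptf_model <- function(a, b, c = 0, id = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (!is.finite(a) || a <= 0) stop("`a` must be finite and > 0")
  if (!is.finite(b) || b <= 0) stop("`b` must be finite and > 0")
  if (!is.finite(c) || c < 0) stop("`c` must be finite and >= 0")
  structure(list(id = id,
                 form = if (c == 0) "pure_exp" else "offset_exp",
                 a = a, b = b, c = c,
                 bd_domain = c(lower = c, upper = a + c)),
            class = "ptf_model")
}

#' @export
print.ptf_model <- function(x, ...) {
  cat(sprintf("<ptf_model %s> BD = %g + %g * exp(-%g * SOC);  BD domain (%g, %g]\n",
              if (is.null(x$id)) "" else x$id, x$c, x$a, x$b,
              x$bd_domain[1], x$bd_domain[2]))
  invisible(x)
}

#' The four built-in BD-SOC models
#'
#' Frozen coefficients of four published empirical bulk-density models
#' for Qinghai-Tibet Plateau soils:
#' \describe{
#'   \item{1}{BD = 0.3 + 1.28 exp(-0.01724 SOC)}
#'   \item{2}{BD = 1.515 exp(-0.102 SOC)}
#'   \item{3}{BD = 0.9955 + 0.5427 exp(-0.077 SOC)}
#'   \item{4}{BD = 1.4055 exp(-0.1039 SOC)}
#' }
#' @return named list of [ptf_model()] objects, names `"1"`..`"4"`.
#' @export
ptf_models <- function() {
  list(`1` = ptf_model(1.28,   0.01724, 0.3,    id = "1"),
       `2` = ptf_model(1.515,  0.102,   0,      id = "2"),
       `3` = ptf_model(0.5427, 0.077,   0.9955, id = "3"),
       `4` = ptf_model(1.4055, 0.1039,  0,      id = "4"))
}

#' Forward pedotransfer evaluation: bulk density from SOC
#'
#' @param model a [ptf_model()].
#' @param soc SOC concentration, g kg^-1 (vectorised; must be finite,
#'   >= 0).
#' @return bulk density, g cm^-3.
#' @export
forward_bd <- function(model, soc) {
  stopifnot(inherits(model, "ptf_model"))
  if (!is.numeric(soc) || any(!is.finite(soc)) || any(soc < 0))
    stop("`soc` must be finite and >= 0")
  model$c + model$a * exp(-model$b * soc)
}

#' Analytic inversion: SOC from bulk density
#'
#' Closed form `SOC = -log((bd - c)/a) / b` on the model's BD domain.
#' Out-of-domain values are never dropped silently: each element gets a
#' flag.  `bd > a + c` (SOC would be negative) follows `policy`;
#' `bd <= c` (no finite preimage) is always missing.
#'
#' @param model a [ptf_model()].
#' @param bd bulk density, g cm^-3 (vectorised; finite, > 0).
#' @param policy `"missing"` (default) or `"clamp_zero"` for BD above
#'   the SOC = 0 intercept.
#' @return numeric vector of SOC (g kg^-1, `NA` where missing) with a
#'   character attribute `"flag"`: `"ok"`, `"above_intercept"` or
#'   `"below_asymptote"`.
#' @export
invert_soc <- function(model, bd, policy = c("missing", "clamp_zero")) {
  stopifnot(inherits(model, "ptf_model"))
  policy <- match.arg(policy)
  if (!is.numeric(bd) || any(!is.finite(bd)) || any(bd <= 0))
    stop("`bd` must be finite and > 0")
  flag <- rep("ok", length(bd))
  soc <- rep(NA_real_, length(bd))
  lo <- bd <= model$c
  hi <- bd > model$a + model$c
  ok <- !lo & !hi
  soc[ok] <- -log((bd[ok] - model$c) / model$a) / model$b
  # guard against -0 at the intercept
  soc[ok][soc[ok] < 0 & soc[ok] > -1e-12] <- 0
  flag[lo] <- "below_asymptote"
  flag[hi] <- "above_intercept"
  if (policy == "clamp_zero") soc[hi] <- 0
  attr(soc, "flag") <- flag
  soc
}

#' Batch SOC inversion over a bulk-density table
#'
#' @param tbl data frame with at least a `bd` column; `site_id` and
#'   `layer` are carried through when present.
#' @param model a [ptf_model()].
#' @inheritParams invert_soc
#' @return the input columns plus `soc` and `flag`.
#' @export
invert_soc_table <- function(tbl, model, policy = c("missing", "clamp_zero")) {
  stopifnot(is.data.frame(tbl), "bd" %in% names(tbl))
  soc <- invert_soc(model, tbl$bd, policy)
  keep <- intersect(c("site_id", "layer", "bd"), names(tbl))
  out <- tbl[keep]
  out$soc <- as.numeric(soc)
  out$flag <- attr(soc, "flag")
  out
}

#' Convert soil organic matter to soil organic carbon
#'
#' Two conventions are supported because the source relation is printed
#' in two incompatible directions in the literature this package
#' follows:
#' * `"as_printed"` inverts `SOM = SOC * 0.58`, i.e. `SOC = SOM / 0.58`
#'   (the default, for fidelity to the printed relation);
#' * `"van_bemmelen"` applies the conventional van Bemmelen factor,
#'   `SOC = SOM / 1.724 = 0.58 * SOM`.
#'
#' The convention used should be recorded in downstream provenance; the
#' batch functions do so via their `method` tag.
#'
#' @param som SOM, g kg^-1 (vectorised, >= 0).
#' @param convention `"as_printed"` or `"van_bemmelen"`.
#' @return SOC, g kg^-1.
#' @export
soc_from_som <- function(som, convention = c("as_printed", "van_bemmelen")) {
  convention <- match.arg(convention)
  if (!is.numeric(som) || any(!is.finite(som)) || any(som < 0))
    stop("`som` must be finite and >= 0")
  if (convention == "as_printed") som / 0.58 else som * 0.58
}

#' Soil organic matter from dichromate titration volumes
#'
#' Wet-oxidation data reduction: `SOM = (a - b) * N_Fe * 0.003 * 1.724
#' * 1.08 / W`, where 0.003 g is the milli-equivalent weight of carbon,
#' 1.724 the SOC-to-SOM factor and 1.08 the oxidation correction.  The
#' quotient is g SOM per g dry soil; the return value is scaled by 1000
#' to g kg^-1.
#'
#' @param a_blank titrant volume in the blank run, mL.
#' @param b_sample titrant volume in the sample run, mL
#'   (`a_blank >= b_sample >= 0`).
#' @param n_fe equivalent concentration of the Fe2+ standard (> 0).
#' @param w_dry dry soil mass, g (> 0).
#' @return SOM, g kg^-1.
#' @export
som_from_titration <- function(a_blank, b_sample, n_fe, w_dry) {
  if (any(w_dry <= 0)) stop("`w_dry` must be > 0")
  if (any(n_fe <= 0)) stop("`n_fe` must be > 0")
  if (any(b_sample < 0) || any(a_blank < b_sample))
    stop("titration volumes must satisfy a_blank >= b_sample >= 0")
  (a_blank - b_sample) * n_fe * 0.003 * 1.724 * 1.08 / w_dry * 1000
}

#' Dry bulk density from a volumetric core sample
#'
#' `BD = (M - G) * 100 / V / (100 + W)`: the fresh core mass is
#' corrected to dry mass through the gravimetric water content W (%).
#'
#' @param m_total cylinder + soil mass, g.
#' @param g_cyl cylinder mass, g (`m_total >= g_cyl`).
#' @param v_cyl cylinder volume, cm^3 (> 0).
#' @param w_pct gravimetric water content, % (>= 0).
#' @return bulk density, g cm^-3.
#' @export
bd_from_core <- function(m_total, g_cyl, v_cyl, w_pct) {
  if (any(v_cyl <= 0)) stop("`v_cyl` must be > 0")
  if (any(w_pct < 0)) stop("`w_pct` must be >= 0")
  if (any(m_total < g_cyl)) stop("`m_total` must be >= `g_cyl`")
  (m_total - g_cyl) * 100 / v_cyl / (100 + w_pct)
}

# ---- model registry I/O -----------------------------------------------------

#' Write a pedotransfer model registry to CSV
#'
#' Columns: `id, form, a, b, c`.
#' @param models named list of [ptf_model()].
#' @param path output CSV path.
#' @export
write_ptf_registry <- function(models, path) {
  df <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    data.frame(id = nm, form = m$form, a = m$a, b = m$b, c = m$c)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pedotransfer model registry from CSV
#'
#' @param path CSV with columns `id, a, b, c` (and optional `form`,
#'   which is recomputed from `c`).
#' @return named list of [ptf_model()].
#' @export
read_ptf_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "a", "b", "c") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i)
    ptf_model(df$a[i], df$b[i], df$c[i], id = as.character(df$id[i])))
  names(out) <- as.character(df$id)
  out
}
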