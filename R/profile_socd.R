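#' Depth layer scheme
#'
#' Fixed depth boundaries onto which arbitrary profile layering is
#' resliced before SOCD integration.  The default is the three-layer
#' topsoil scheme 0-9.1, 9.1-16.6 and 16.6-30 cm.
#'
#' @param boundaries strictly increasing depths in cm starting at 0.
#' @export
layer_scheme <- function(boundaries = c(0, 9.1, 16.6, 30)) {
  if (!is.numeric(boundaries) || length(boundaries) < 2L)
    stop("need at least two boundary depths")
  if (boundaries[1] != 0) stop("scheme must start at 0 cm")
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  structure(list(boundaries = boundaries), class = "layer_scheme")
}

#' Soil profile record
#'
#' @param site_id profile identifier.
#' @param x,y map coordinates.
#' @param grassland_type `"steppe"` or `"meadow"`.
#' @param layers data frame with columns `top`, `bottom` (cm), `bd`
#'   (g cm^-3), `soc` (g kg^-1); optional `gravel` (% > 2 mm, defaults
#'   to 0 with a `gravel_missing` attribute flag) and `som` (g kg^-1).
#'   Layers must be contiguous and non-overlapping from 0 cm down.
#' @return object of class `soil_profile`.
#' @export
soil_profile <- function(site_id, x = NA_real_, y = NA_real_,
                         grassland_type = c("steppe", "meadow"),
                         layers) {
  grassland_type <- match.arg(grassland_type)
  stopifnot(is.data.frame(layers),
            all(c("top", "bottom", "bd", "soc") %in% names(layers)))
  layers <- layers[order(layers$top), , drop = FALSE]
  gravel_missing <- is.null(layers$gravel)
  if (gravel_missing) layers$gravel <- 0
  with(layers, {
    if (any(bottom <= top)) stop("layer bottom must exceed top")
    if (abs(top[1]) > 1e-9) stop("profile must start at 0 cm")
    if (nrow(layers) > 1 &&
        any(abs(top[-1] - bottom[-length(bottom)]) > 1e-9))
      stop("layers must be contiguous and non-overlapping")
    if (any(bd <= 0)) stop("bd must be > 0")
    if (any(soc < 0)) stop("soc must be >= 0")
    if (any(gravel < 0 | gravel > 100)) stop("gravel must be in [0, 100]")
  })
  layers$thickness <- layers$bottom - layers$top
  structure(list(site_id = site_id, x = x, y = y,
                 grassland_type = grassland_type,
                 layers = layers, gravel_missing = gravel_missing),
            class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("<soil_profile %s> %s, %d layers to %g cm\n",
              x$site_id, x$grassland_type, nrow(x$layers),
              max(x$layers$bottom)))
  invisible(x)
}

#' Reslice a profile onto a layer scheme
#'
#' Each target layer takes the thickness-weighted mean of the source
#' layers overlapping it (applied to `bd`, `soc`, `gravel` and, when
#' present, `som`).  For piecewise-constant properties this conserves
#' mass per unit area (thickness x bd).
#'
#' @param profile a [soil_profile()].
#' @param scheme a [layer_scheme()].
#' @return a `soil_profile` on the scheme boundaries.
#' @export
reslice_profile <- function(profile, scheme = layer_scheme()) {
  stopifnot(inherits(profile, "soil_profile"), inherits(scheme, "layer_scheme"))
  b <- scheme$boundaries
  src <- profile$layers
  if (max(src$bottom) < b[length(b)] - 1e-9)
    stop(sprintf("profile %s does not cover depth interval %g-%g cm",
                 profile$site_id, max(src$bottom), b[length(b)]))
  cols <- intersect(c("bd", "soc", "gravel", "som"), names(src))
  out <- lapply(seq_len(length(b) - 1L), function(i) {
    lo <- b[i]; hi <- b[i + 1L]
    ov <- pmin(src$bottom, hi) - pmax(src$top, lo)
    w <- pmax(ov, 0)
    if (abs(sum(w) - (hi - lo)) > 1e-9)
      stop(sprintf("coverage gap in %g-%g cm", lo, hi))
    vals <- vapply(cols, function(cl) sum(w * src[[cl]]) / sum(w), 0)
    c(top = lo, bottom = hi, vals)
  })
  new_layers <- as.data.frame(do.call(rbind, out))
  prof <- soil_profile(profile$site_id, profile$x, profile$y,
                       profile$grassland_type, new_layers)
  prof$gravel_missing <- profile$gravel_missing
  prof
}

#' SOCD of a single soil layer
#'
#' Depth-weighted, gravel-corrected carbon density
#' `SOCD = T * BD * SOC * (1 - C/100) / 100` with T in cm, BD in
#' g cm^-3, SOC in g kg^-1 and C the percent fraction > 2 mm.  The
#' units resolve to kg C m^-2: T (cm) = 1e-2 m, BD (g cm^-3) =
#' 1e3 kg m^-3, SOC (g kg^-1) = 1e-3 kg C per kg soil, and
#' 1e-2 * 1e3 * 1e-3 = 1/100 -- the /100 in the formula is exactly this
#' unit resolution, so the result is in kg C m^-2 with no further
#' conversion.
#'
#' @param thickness layer thickness, cm.
#' @param bd bulk density, g cm^-3.
#' @param soc SOC, g kg^-1.
#' @param gravel percent of the > 2 mm fraction (default 0).
#' @return SOCD in kg C m^-2 (vectorised).
#' @export
layer_socd <- function(thickness, bd, soc, gravel = 0) {
  if (any(thickness < 0, na.rm = TRUE)) stop("thickness must be >= 0")
  if (any(gravel < 0 | gravel > 100, na.rm = TRUE))
    stop("gravel must be in [0, 100]")
  thickness * bd * soc * (1 - gravel / 100) / 100
}

#' Per-layer and total SOCD of a profile
#'
#' The profile is resliced onto `scheme`; the total is the exact sum of
#' the per-layer values.
#'
#' @param profile a [soil_profile()] covering the scheme extent.
#' @param scheme a [layer_scheme()].
#' @return list with `layers` (data frame: `layer`, `top`, `bottom`,
#'   `socd`) and `total` (kg C m^-2).
#' @export
profile_socd <- function(profile, scheme = layer_scheme()) {
  p <- reslice_profile(profile, scheme)
  ly <- p$layers
  socd <- layer_socd(ly$thickness, ly$bd, ly$soc, ly$gravel)
  list(layers = data.frame(layer = seq_len(nrow(ly)), top = ly$top,
                           bottom = ly$bottom, socd = socd),
       total = sum(socd))
}

#' Batch SOCD over many profiles under a chosen SOC source
#'
#' For `method = "measured"` the profile's own `soc` column is used.
#' For `"bd_model_1"`..`"bd_model_4"` SOC per layer is recovered from
#' bulk density by [invert_soc()]; inversion failures propagate as
#' flagged rows with `NA` SOCD, never dropped.  For `"som"` SOC comes
#' from the profile's `som` column via [soc_from_som()].
#'
#' Profiles that do not cover the scheme extent are excluded from the
#' output table and reported in the `qc` attribute.
#'
#' @param profiles list of [soil_profile()] objects.
#' @param method SOC source, see Details.
#' @param scheme a [layer_scheme()].
#' @param models model registry for the BD methods (default
#'   [ptf_models()]).
#' @param policy out-of-domain policy passed to [invert_soc()].
#' @param som_convention passed to [soc_from_som()].
#' @return data frame with one row per profile x layer (plus a
#'   `"total"` row per profile): columns `site_id`, `grassland_type`,
#'   `method`, `layer`, `socd`, `flag`.  Attribute `"qc"` holds a data
#'   frame of excluded profiles and reasons.
#' @export
batch_socd <- function(profiles,
                       method = c("measured", "bd_model_1", "bd_model_2",
                                  "bd_model_3", "bd_model_4", "som"),
                       scheme = layer_scheme(), models = ptf_models(),
                       policy = c("missing", "clamp_zero"),
                       som_convention = c("as_printed", "van_bemmelen")) {
  method <- match.arg(method)
  policy <- match.arg(policy)
  som_convention <- match.arg(som_convention)
  rows <- list(); qc <- list()
  for (p in profiles) {
    rp <- tryCatch(reslice_profile(p, scheme), error = function(e) e)
    if (inherits(rp, "error")) {
      qc[[length(qc) + 1L]] <- data.frame(site_id = p$site_id,
                                          reason = conditionMessage(rp))
      next
    }
    ly <- rp$layers
    flag <- rep("ok", nrow(ly))
    if (method == "measured") {
      soc <- ly$soc
    } else if (method == "som") {
      if (is.null(ly$som)) stop("profiles carry no `som` column")
      soc <- soc_from_som(ly$som, som_convention)
    } else {
      mid <- sub("bd_model_", "", method)
      inv <- invert_soc(models[[mid]], ly$bd, policy)
      soc <- as.numeric(inv)
      flag <- attr(inv, "flag")
    }
    socd <- layer_socd(ly$thickness, ly$bd, soc, ly$gravel)
    tot_flag <- if (all(flag == "ok")) "ok" else "has_flagged_layer"
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = p$site_id, grassland_type = p$grassland_type,
      method = method,
      layer = c(as.character(seq_len(nrow(ly))), "total"),
      socd = c(socd, if (anyNA(socd)) NA_real_ else sum(socd)),
      flag = c(flag, tot_flag))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), grassland_type = character(),
               method = character(), layer = character(),
               socd = numeric(), flag = character())
  attr(out, "qc") <- if (length(qc)) do.call(rbind, qc) else
    data.frame(site_id = character(), reason = character())
  out
}

#' Missing-aware group means of batch SOCD
#'
#' Unweighted arithmetic means by grassland type x layer, dropping
#' flagged/missing rows; strata with no valid rows are absent, not
#' zero.
#'
#' @param tbl output of [batch_socd()].
#' @return data frame `grassland_type`, `method`, `layer`, `mean_socd`,
#'   `n` (profiles contributing), `n_missing`.
#' @export
socd_group_means <- function(tbl) {
  sp <- split(tbl, list(tbl$grassland_type, tbl$method, tbl$layer), drop = TRUE)
  out <- lapply(sp, function(g) {
    ok <- !is.na(g$socd)
    if (!any(ok)) return(NULL)
    data.frame(grassland_type = g$grassland_type[1], method = g$method[1],
               layer = g$layer[1], mean_socd = mean(g$socd[ok]),
               n = sum(ok), n_missing = sum(!ok))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out[order(out$grassland_type, out$method, out$layer), ]
}
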