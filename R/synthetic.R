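#' Specification of a synthetic study region
#'
#' Collects every tunable of the synthetic-data generators, with
#' defaults sized to the emulated study: a 50 x 50 grid of 10 km
#' cells, annual composites for 2000-2015 (16 years), 200 soil
#' profiles on the three-layer topsoil scheme and 59 plot surveys.
#' NDVI baselines and trends are chosen so that the implied SOCD
#' levels and change rates sit where the regional literature puts
#' them (steppe around 3-4 kg C m^-2 rising ~0.02 kg C m^-2 yr^-1,
#' meadow around 7-8 rising ~0.065).
#'
#' Identical spec + seed reproduces bit-identical outputs; each
#' generator draws from its own derived substream so regenerating one
#' input does not disturb the others.
#'
#' @param seed root integer seed.
#' @param nrow,ncol grid shape.
#' @param cellsize cell edge, m (default 10 km).
#' @param years annual time axis.
#' @param steppe_fraction westward fraction of columns typed steppe;
#'   the rest is meadow.
#' @param ndvi_intercept,ndvi_slope per-type `c(mean, sd)` of the
#'   per-pixel NDVI baseline and linear trend per year.
#' @param ndvi_noise_sd s.d. of the Gaussian interannual NDVI noise.
#' @param n_profiles number of soil profiles.
#' @param profile_model_id generating pedotransfer model (`"1"`..`"4"`).
#' @param soc_meanlog,soc_sdlog lognormal SOC parameters per scheme
#'   layer (g kg^-1 scale).
#' @param bd_noise_sd s.d. of Gaussian noise added to the forward BD,
#'   g cm^-3 (result truncated into the model's invertible domain).
#' @param gravel_range uniform range of the gravel percentage.
#' @param n_surveys number of plot surveys.
#' @param survey_cor target correlation matrix of the survey columns
#'   (symmetric, unit diagonal, positive semi-definite).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           nrow = 50L, ncol = 50L, cellsize = 10000,
                           years = 2000:2015,
                           steppe_fraction = 0.5,
                           ndvi_intercept = list(steppe = c(mean = 0.20, sd = 0.05),
                                                 meadow = c(mean = 0.43, sd = 0.08)),
                           ndvi_slope = list(steppe = c(mean = 0.0010, sd = 0.0010),
                                             meadow = c(mean = 0.0036, sd = 0.0015)),
                           ndvi_noise_sd = 0.02,
                           n_profiles = 200L,
                           profile_model_id = "1",
                           soc_meanlog = log(c(30, 20, 10)),
                           soc_sdlog = 0.4,
                           bd_noise_sd = 0.05,
                           gravel_range = c(0, 20),
                           n_surveys = 59L,
                           survey_cor = default_survey_cor()) {
  stopifnot(seed == round(seed), nrow >= 1, ncol >= 1, cellsize > 0,
            length(years) >= 1, steppe_fraction >= 0, steppe_fraction <= 1,
            ndvi_noise_sd >= 0, bd_noise_sd >= 0,
            n_profiles >= 1, n_surveys >= 1,
            length(gravel_range) == 2, all(gravel_range >= 0),
            all(gravel_range <= 100))
  validate_cor_target(survey_cor)
  structure(list(seed = as.integer(seed), nrow = as.integer(nrow),
                 ncol = as.integer(ncol), cellsize = cellsize,
                 years = as.integer(years),
                 steppe_fraction = steppe_fraction,
                 ndvi_intercept = ndvi_intercept, ndvi_slope = ndvi_slope,
                 ndvi_noise_sd = ndvi_noise_sd,
                 n_profiles = as.integer(n_profiles),
                 profile_model_id = as.character(profile_model_id),
                 soc_meanlog = soc_meanlog, soc_sdlog = soc_sdlog,
                 bd_noise_sd = bd_noise_sd, gravel_range = gravel_range,
                 n_surveys = as.integer(n_surveys),
                 survey_cor = survey_cor),
            class = "synthetic_spec")
}

#' Default plot-survey correlation target
#'
#' Signs follow the screening findings this generator emulates: SOCD
#' correlates positively with biomass and soil moisture, negatively
#' with temperature, conductivity and elevation; conductivity rises
#' with temperature and falls with moisture; temperature falls with
#' elevation.
#' @return 6 x 6 correlation matrix over `socd`, `biomass`,
#'   `moisture`, `temperature`, `conductivity`, `elevation`.
#' @export
default_survey_cor <- function() {
  v <- c("socd", "biomass", "moisture", "temperature", "conductivity",
         "elevation")
  R <- diag(6)
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, val) {
    R[a, b] <<- val; R[b, a] <<- val
  }
  set_r("socd", "biomass", 0.60); set_r("socd", "moisture", 0.55)
  set_r("socd", "temperature", -0.30); set_r("socd", "conductivity", -0.35)
  set_r("socd", "elevation", -0.25)
  set_r("biomass", "moisture", 0.45); set_r("biomass", "temperature", -0.15)
  set_r("biomass", "conductivity", -0.25); set_r("biomass", "elevation", -0.20)
  set_r("moisture", "temperature", -0.20); set_r("moisture", "conductivity", -0.40)
  set_r("moisture", "elevation", -0.10)
  set_r("temperature", "conductivity", 0.45); set_r("temperature", "elevation", -0.50)
  set_r("conductivity", "elevation", 0.10)
  R
}

validate_cor_target <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("correlation target must be square")
  if (max(abs(R - t(R))) > 1e-12) stop("correlation target must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-12)) stop("correlation target needs unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("correlation target is not positive semi-definite (eigenvalue %g)",
                 min(ev)))
  invisible(TRUE)
}

# derived per-generator substream seeds (kept below 2^31)
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 2633) %% 2147483647L)
}

#' Generate a grassland-type mask
#'
#' Deterministic split-halves geography: the westernmost
#' `steppe_fraction` of columns is steppe, the rest meadow (no RNG
#' involved, so the mask is identical across seeds with the same
#' shape).
#'
#' @param spec a [synthetic_spec()].
#' @return a [grass_mask()].
#' @export
gen_mask <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_steppe <- round(spec$ncol * spec$steppe_fraction)
  m <- matrix(rep(c(rep(1L, n_steppe), rep(2L, spec$ncol - n_steppe)),
                  each = spec$nrow),
              nrow = spec$nrow)
  grass_mask(m, spec$cellsize, 0, 0)
}

#' Generate an annual NDVI stack with planted per-pixel trends
#'
#' Per pixel, `NDVI_i = clip(intercept + slope * i + eps_i, 0, 1)`
#' with `eps ~ N(0, ndvi_noise_sd)` and i the serial year number
#' (1..n).  Intercept and slope are drawn per pixel from the
#' grassland-type distributions in the spec.  The clipping bound can
#' be disabled for generic planted-trend stacks.
#'
#' @param spec a [synthetic_spec()].
#' @param mask optional mask (default [gen_mask()]).
#' @param clip length-2 clip bounds or `NULL` to disable.
#' @return list with `stack` (a `grid_stack`), and `truth` (list of
#'   `geo_grid`s `intercept` and `slope`).
#' @export
gen_ndvi_stack <- function(spec, mask = gen_mask(spec), clip = c(0, 1)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(sub_seed(spec$seed, 2L))
  nr <- spec$nrow; nc <- spec$ncol
  intercept <- slope <- matrix(NA_real_, nr, nc)
  for (ty in c("steppe", "meadow")) {
    sel <- mask_is(mask, ty)
    n <- sum(sel)
    ic <- spec$ndvi_intercept[[ty]]; sl <- spec$ndvi_slope[[ty]]
    intercept[sel] <- stats::rnorm(n, ic["mean"], ic["sd"])
    slope[sel] <- stats::rnorm(n, sl["mean"], sl["sd"])
  }
  ny <- length(spec$years)
  grids <- vector("list", ny)
  for (i in seq_len(ny)) {
    eps <- matrix(stats::rnorm(nr * nc, 0, spec$ndvi_noise_sd), nr, nc)
    v <- intercept + slope * i + eps
    if (!is.null(clip)) v <- pmin(pmax(v, clip[1]), clip[2])
    v[is.na(intercept)] <- NA
    grids[[i]] <- geo_grid(v, spec$cellsize, 0, 0)
  }
  list(stack = grid_stack(grids, spec$years),
       truth = list(intercept = geo_grid(intercept, spec$cellsize, 0, 0),
                    slope = geo_grid(slope, spec$cellsize, 0, 0)))
}

#' Generate soil profiles consistent with a pedotransfer model
#'
#' Per profile, three layers on the default scheme: true SOC is drawn
#' lognormally per layer, BD is the generating model's forward value
#' plus truncated Gaussian noise (kept strictly inside the model's
#' invertible BD domain), gravel is uniform on `gravel_range`, and a
#' `som` column is derived as `SOC * 0.58`.  Site coordinates are
#' uniform over the grid extent; grassland type is read off the mask.
#'
#' @param spec a [synthetic_spec()].
#' @param mask optional mask (default [gen_mask()]).
#' @param scheme layer scheme (default [layer_scheme()]).
#' @return list with `profiles` (list of [soil_profile()]) and `truth`
#'   (data frame `site_id`, `layer`, `soc_true`, `bd`).
#' @export
gen_soil_profiles <- function(spec, mask = gen_mask(spec),
                              scheme = layer_scheme()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(sub_seed(spec$seed, 3L))
  model <- ptf_models()[[spec$profile_model_id]]
  b <- scheme$boundaries
  nl <- length(b) - 1L
  if (length(spec$soc_meanlog) != nl)
    stop("soc_meanlog must have one entry per scheme layer")
  lo_bd <- model$bd_domain[1]; hi_bd <- model$bd_domain[2]
  profiles <- vector("list", spec$n_profiles)
  truth <- vector("list", spec$n_profiles)
  for (s in seq_len(spec$n_profiles)) {
    x <- stats::runif(1, 0, spec$ncol * spec$cellsize)
    y <- stats::runif(1, 0, spec$nrow * spec$cellsize)
    col <- min(floor(x / spec$cellsize) + 1, spec$ncol)
    row <- min(max(spec$nrow - floor(y / spec$cellsize), 1L), spec$nrow)
    ty <- names(mask_levels())[match(mask$values[row, col], mask_levels())]
    soc_true <- stats::rlnorm(nl, spec$soc_meanlog, spec$soc_sdlog)
    bd <- forward_bd(model, soc_true) +
      stats::rnorm(nl, 0, spec$bd_noise_sd)
    bd <- pmin(pmax(bd, lo_bd + 1e-6), hi_bd)
    gravel <- stats::runif(nl, spec$gravel_range[1], spec$gravel_range[2])
    id <- sprintf("site_%04d", s)
    layers <- data.frame(top = b[-length(b)], bottom = b[-1],
                         bd = bd, soc = soc_true,
                         gravel = gravel, som = soc_true * 0.58)
    profiles[[s]] <- soil_profile(id, x, y, ty, layers)
    truth[[s]] <- data.frame(site_id = id, layer = seq_len(nl),
                             soc_true = soc_true, bd = bd)
  }
  list(profiles = profiles, truth = do.call(rbind, truth))
}

#' Generate plot surveys with a planted correlation structure
#'
#' Standard-normal draws are coloured by the Cholesky (or, for a
#' singular target, eigen) factor of the target correlation matrix,
#' then affinely mapped to plausible field units -- shift/scale only,
#' which preserves all pairwise correlations up to sign (all scales
#' are positive).
#'
#' Unit mapping: SOCD 6 +/- 2 kg C m^-2, biomass 150 +/- 60 g m^-2,
#' moisture 20 +/- 8 %, temperature 10 +/- 4 degC, conductivity
#' 0.3 +/- 0.1 mS cm^-1, elevation 4200 +/- 400 m.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `surveys` (data frame, one row per plot) and
#'   `target` (the correlation matrix used).
#' @export
gen_plot_surveys <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_cor_target(spec$survey_cor)
  set.seed(sub_seed(spec$seed, 4L))
  R <- spec$survey_cor
  k <- ncol(R)
  L <- tryCatch(chol(R), error = function(e) {
    e <- eigen(R, symmetric = TRUE)
    t(e$vectors %*% diag(sqrt(pmax(e$values, 0))))
  })
  Z <- matrix(stats::rnorm(spec$n_surveys * k), spec$n_surveys, k)
  X <- Z %*% L
  colnames(X) <- colnames(R)
  units <- list(socd = c(6, 2), biomass = c(150, 60), moisture = c(20, 8),
                temperature = c(10, 4), conductivity = c(0.3, 0.1),
                elevation = c(4200, 400))
  out <- data.frame(plot_id = sprintf("plot_%03d", seq_len(spec$n_surveys)))
  for (nm in colnames(R)) {
    u <- units[[nm]]
    if (is.null(u)) u <- c(0, 1)
    out[[nm]] <- u[1] + u[2] * X[, nm]
  }
  list(surveys = out, target = R)
}
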