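# shared fixture builders (all programmatic; no data files)

make_grid <- function(values, cellsize = 1, xmin = 0, ymin = 0) {
  geo_grid(as.matrix(values), cellsize, xmin, ymin)
}

# a 0-30 cm profile on arbitrary layering
make_profile <- function(id = "p1", tops, bottoms, bd, soc, gravel = 0,
                         som = NULL, type = "steppe") {
  ly <- data.frame(top = tops, bottom = bottoms, bd = bd, soc = soc,
                   gravel = gravel)
  if (!is.null(som)) ly$som <- som
  soil_profile(id, 0, 0, type, ly)
}

# profile with three scheme layers generated exactly from a model
model_consistent_profile <- function(id, model, soc, gravel = 0,
                                     type = "steppe") {
  b <- layer_scheme()$boundaries
  make_profile(id, b[-length(b)], b[-1], bd = forward_bd(model, soc),
               soc = soc, gravel = gravel, type = type)
}

# brute-force Mann-Kendall S (independent double-loop oracle)
mk_s_bruteforce <- function(x) {
  n <- length(x); s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i])
  s
}

# tie-corrected variance, written independently from the package
mk_var_bruteforce <- function(x) {
  n <- length(x)
  tie_term <- 0
  for (t in table(x)) if (t > 1) tie_term <- tie_term + t * (t - 1) * (2 * t + 5)
  (n * (n - 1) * (2 * n + 5) - tie_term) / 18
}
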