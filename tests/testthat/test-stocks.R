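test_that("IDW: constants, symmetry, exactness at sites", {
  tmpl <- make_grid(matrix(0, 5, 5), cellsize = 1)
  one <- data.frame(x = 2.5, y = 2.5, value = 7)
  g1 <- interpolate_points(one, tmpl, "idw")
  expect_true(all(g1$values == 7))
  two_eq <- data.frame(x = c(0.5, 4.5), y = c(2.5, 2.5), value = 4)
  expect_true(all(interpolate_points(two_eq, tmpl, "idw")$values == 4))
  # midpoint of 0 and 10 -> 5 for any power (equal weights)
  two <- data.frame(x = c(0.5, 4.5), y = c(2.5, 2.5), value = c(0, 10))
  for (p in c(1, 2, 4)) {
    g <- interpolate_points(two, tmpl, "idw", power = p)
    expect_equal(g$values[3, 3], 5)          # cell centre (2.5, 2.5)
    # exact at the data sites
    expect_equal(g$values[3, 1], 0)
    expect_equal(g$values[3, 5], 10)
  }
  expect_error(interpolate_points(two[0, ], tmpl), "no points")
})

test_that("ordinary kriging is exact at sites and handles degeneracy", {
  set.seed(31)
  tmpl <- make_grid(matrix(0, 8, 8), cellsize = 1)
  pts <- data.frame(x = runif(15, 0, 8), y = runif(15, 0, 8),
                    value = rnorm(15, 10, 2))
  # snap three points onto cell centres to probe exactness
  pts$x[1:3] <- c(0.5, 3.5, 6.5); pts$y[1:3] <- c(0.5, 4.5, 7.5)
  vg <- c(nugget = 0, psill = 4, range = 3)
  g <- interpolate_points(pts, tmpl, "kriging", variogram = vg)
  expect_equal(g$values[8, 1], pts$value[1])   # (0.5, 0.5) is row 8, col 1
  expect_equal(g$values[4, 4], pts$value[2])
  expect_equal(g$values[1, 7], pts$value[3])
  expect_true(all(is.finite(g$values)))
  # degenerate variogram falls back to IDW with a warning
  expect_warning(
    g2 <- interpolate_points(pts, tmpl, "kriging",
                             variogram = c(nugget = 0, psill = 0, range = 1)),
    "falling back to IDW")
  expect_equal(g2$values, interpolate_points(pts, tmpl, "idw")$values)
  # moment fit on a smooth field returns usable parameters
  smooth <- expand.grid(x = seq(0.5, 7.5, 1), y = seq(0.5, 7.5, 1))
  smooth$value <- sin(smooth$x / 3) + cos(smooth$y / 4)
  vg_fit <- fit_exp_variogram(smooth)
  expect_true(all(vg_fit[c("psill", "range")] > 0))
  g3 <- interpolate_points(smooth, tmpl, "kriging")
  expect_equal(g3$values[8, 1], smooth$value[1], tolerance = 1e-6)
})

test_that("zonal storage: hand-computed, empty strata, linearity", {
  # two steppe pixels of 1e8 m^2 at 5 kg m^-2 -> 1e9 kg = 0.1e10 kg
  socd <- make_grid(matrix(c(5, 5, 2, NA), 1), cellsize = 10000)
  mask <- grass_mask(matrix(c(1, 1, 2, 2), 1), cellsize = 10000)
  zs <- zonal_storage(socd, mask)
  st <- zs[zs$grassland_type == "steppe", ]
  expect_equal(st$storage_1e10kg, 0.1)
  expect_equal(st$area_km2, 200)
  expect_equal(st$mean_socd, 5)
  md <- zs[zs$grassland_type == "meadow", ]
  expect_equal(md$storage_1e10kg, 2 * 1e8 / 1e10)
  expect_equal(md$n_cells, 1)                  # nodata pixel excluded
  # conservation: all = steppe + meadow exactly
  al <- zs[zs$grassland_type == "all", ]
  expect_identical(al$storage_1e10kg, st$storage_1e10kg + md$storage_1e10kg)
  expect_identical(al$n_cells, st$n_cells + md$n_cells)
  # doubling cell area doubles storage
  zs2 <- zonal_storage(socd, mask, cell_area = 2e8)
  expect_equal(zs2$storage_1e10kg, 2 * zs$storage_1e10kg)
  # empty class flagged absent via zero area, not fabricated storage
  mask2 <- grass_mask(matrix(c(1, 1, 1, 1), 1), cellsize = 10000)
  zs3 <- zonal_storage(socd, mask2)
  md3 <- zs3[zs3$grassland_type == "meadow", ]
  expect_equal(md3$n_cells, 0)
  expect_equal(md3$storage_1e10kg, 0)
  expect_true(is.na(md3$mean_socd))
  expect_error(zonal_storage(socd, grass_mask(matrix(1, 2, 2))), "mismatch")
})

test_that("unit bookkeeping round-trips at double precision", {
  kg <- c(2.41e12, 3.979e12, 1.883e12)
  expect_identical(kg / 1e10 * 1e10, kg)
})

test_that("storage table: long format, totals, layer additivity", {
  gm <- data.frame(grassland_type = rep(c("steppe", "meadow"), each = 4),
                   method = "measured",
                   layer = rep(c("1", "2", "3", "total"), 2),
                   mean_socd = c(2.2, 2.1, 1.0, 5.3, 2.6, 2.4, 1.2, 6.2),
                   n = 10, n_missing = 0)
  st <- profile_storage(gm, c(steppe = 100, meadow = 150))
  ndvi <- data.frame(method = "ndvi", grassland_type = "steppe",
                     layer = "total", n_cells = 4, area_km2 = 100,
                     mean_socd = 5.0, storage_1e10kg = 0.05)
  tab <- storage_table(list(st, ndvi))
  # one total row per method x type; layer rows sum to it
  for (ty in c("steppe", "meadow")) {
    rows <- tab[tab$method == "measured" & tab$grassland_type == ty, ]
    tot <- rows$storage_1e10kg[rows$layer == "total"]
    expect_equal(sum(rows$storage_1e10kg[rows$layer != "total"]), tot,
                 tolerance = 1e-9)
  }
  # NDVI method stays total-only
  expect_identical(tab$layer[tab$method == "ndvi"], "total")
  # identical inputs under two tags give identical storage
  ndvi2 <- ndvi; ndvi2$method <- "other"
  tab2 <- storage_table(list(ndvi, ndvi2))
  expect_equal(tab2$storage_1e10kg[tab2$method == "ndvi"],
               tab2$storage_1e10kg[tab2$method == "other"])
})
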