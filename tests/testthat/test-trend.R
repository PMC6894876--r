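test_that("OLS slope: closed form, degeneracy, antisymmetry", {
  i <- 1:10
  expect_equal(ols_slope(2 + 0.5 * i), 0.5, tolerance = 1e-14)
  expect_equal(ols_slope(rep(3.2, 8)), 0)
  x <- c(4.1, 3.9, 4.4, 4.0, 4.6)
  expect_equal(ols_slope(rev(x)), -ols_slope(x), tolerance = 1e-12)
  # agrees with lm on noisy data
  set.seed(21)
  y <- 1 + 0.07 * i + rnorm(10, 0, 0.3)
  expect_equal(ols_slope(y), unname(coef(lm(y ~ i))[2]), tolerance = 1e-12)
  # missing years: available pairs only
  y2 <- y; y2[c(3, 7)] <- NA
  keep <- !is.na(y2)
  expect_equal(ols_slope(y2), unname(coef(lm(y2[keep] ~ i[keep]))[2]),
               tolerance = 1e-12)
  expect_true(is.na(ols_slope(c(NA, NA, 1))))
})

test_that("Mann-Kendall: monotone series, ties, antisymmetry", {
  up <- mann_kendall(1:10)
  expect_equal(up$s, 45)
  expect_equal(up$z, 44 / sqrt(125))
  expect_identical(up$significance, "sig_increase")
  dn <- mann_kendall(10:1)
  expect_equal(dn$s, -45)
  expect_equal(dn$z, -44 / sqrt(125))
  expect_identical(dn$significance, "sig_decrease")
  tie <- mann_kendall(rep(5, 6))
  expect_equal(tie$s, 0)
  expect_equal(tie$z, 0)
  expect_identical(tie$significance, "none")
  expect_error(mann_kendall(c(1, 2)), "at least 3")
})

test_that("Mann-Kendall matches the brute-force oracle incl. ties", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    x <- if (rep %% 3) rnorm(n) else sample(1:4, n, replace = TRUE)
    mk <- mann_kendall(x)
    expect_equal(mk$s, mk_s_bruteforce(x))
    expect_equal(mk$var_s, mk_var_bruteforce(x), tolerance = 1e-12)
    zo <- if (mk$s > 0) (mk$s - 1) / sqrt(mk_var_bruteforce(x))
          else if (mk$s < 0) (mk$s + 1) / sqrt(mk_var_bruteforce(x)) else 0
    expect_equal(mk$z, zo, tolerance = 1e-12)
  }
})

test_that("Sen slope: enumeration, exact linear, shift invariance", {
  # pairwise slopes of (1,2,4) at i=1:3 are {1, 2, 1.5}
  expect_equal(sen_slope(c(1, 2, 4)), 1.5)
  i <- 1:12
  expect_equal(sen_slope(3 - 0.25 * i), -0.25, tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(9)
  expect_equal(sen_slope(x + 100), sen_slope(x), tolerance = 1e-9)
  # sign matches S when S != 0
  for (k in 1:20) {
    x <- rnorm(8)
    mk <- mann_kendall(x)
    if (mk$s != 0) expect_true(sign(sen_slope(x)) == sign(mk$s))
  }
})

test_that("five-level classification boundaries are half-open as printed", {
  lv <- trend_class_levels()
  got <- as.character(classify_trend(c(-0.2, -0.1, -0.05, -0.01, 0,
                                       0.009999, 0.01, 0.05, 0.0999, 0.1,
                                       0.4)))
  expect_identical(got,
    c("significant decrease",
      "non-significant decrease", "non-significant decrease",
      "nearly unchangeable", "nearly unchangeable", "nearly unchangeable",
      "non-significant increase", "non-significant increase",
      "non-significant increase",
      "significant increase", "significant increase"))
  expect_true(is.na(classify_trend(NA_real_)))
  expect_identical(levels(classify_trend(0)), lv)
})

test_that("raster trend recovers planted noiseless slopes", {
  set.seed(9)
  nr <- 6; nc <- 8; ny <- 10
  slope <- matrix(runif(nr * nc, -0.3, 0.3), nr, nc)
  grids <- lapply(1:ny, function(i)
    make_grid(5 + slope * i, cellsize = 100))
  st <- grid_stack(grids, 2000 + 1:ny)
  tr <- trend_raster(st)
  expect_equal(tr$slope$values, slope, tolerance = 1e-12)
  expect_equal(tr$sen$values, slope, tolerance = 1e-12)
  expect_identical(as.vector(tr$class$values),
                   as.numeric(as.integer(classify_trend(as.vector(slope)))))
  expect_equal(sum(tr$class_area$total), 100, tolerance = 1e-9)
})

test_that("class-area table by type sums to 100 and excludes nodata", {
  cls <- make_grid(matrix(c(1, 5, 3, NA, 4, 4), 2))
  mask <- grass_mask(matrix(c(1, 1, 1, 1, 2, 2), 2))
  tab <- class_area_table(cls, mask)
  expect_equal(sum(tab$total), 100, tolerance = 1e-9)
  expect_equal(sum(tab$steppe), 100, tolerance = 1e-9)
  expect_equal(sum(tab$meadow), 100, tolerance = 1e-9)
  # steppe stratum: classes 1, 5, 3 of 3 valid pixels
  expect_equal(tab$steppe[c(1, 3, 5)], rep(100 / 3, 3))
  expect_equal(tab$meadow[4], 100)
})

test_that("regional series: constancy, single pixel, planted slope", {
  mask <- grass_mask(matrix(c(1, 1, 2, 2), 2))
  grids <- lapply(1:5, function(i) make_grid(matrix(c(2, 2, 3 + 0.1 * i,
                                                      5 + 0.1 * i), 2)))
  st <- grid_stack(grids, 2001:2005)
  se_st <- regional_series(st, mask, "steppe")
  expect_equal(se_st$mean_socd, rep(2, 5))
  se_md <- regional_series(st, mask, "meadow")
  # mean of two pixels with identical planted slope
  expect_equal(ols_slope(se_md$mean_socd), 0.1, tolerance = 1e-12)
  single <- grass_mask(matrix(c(1, 0, 0, 0), 2))
  se1 <- regional_series(st, single, "steppe")
  expect_equal(se1$mean_socd, rep(2, 5))
  expect_error(regional_series(st, single, "meadow"), "no pixels")
})

test_that("pixels with too few valid years become nodata", {
  g <- lapply(1:4, function(i) make_grid(matrix(c(1 * i, NA), 1)))
  g[[1]]$values[1, 2] <- 0.5; g[[2]]$values[1, 2] <- 0.7
  st <- grid_stack(g, 2001:2004)
  tr <- trend_raster(st)
  expect_false(is.na(tr$slope$values[1, 1]))
  expect_true(is.na(tr$slope$values[1, 2]))     # only 2 valid years
  expect_true(is.na(tr$class$values[1, 2]))
})
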