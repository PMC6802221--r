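make_stack <- function(arr, dates, pols = c("VV", "VH"), cellsize = 10) {
  structure(list(dates = as.Date(dates), pols = pols, values = arr,
                 grid = list(origin = c(0, 0), cellsize = cellsize,
                             dim = dim(arr)[1:2])),
            class = "backscatter_stack")
}

test_that("temporal composites take per-pixel medians within each window", {
  dates <- as.Date(c("2016-01-15", "2016-07-15", "2016-12-15"))
  arr <- array(0, dim = c(2, 2, 3, 2))
  arr[1, 1, , 1] <- c(-10, -12, -20) # VV series at one pixel
  arr[, , , 2] <- -15
  st <- make_stack(arr, dates)
  comp <- temporal_composites(st)
  expect_equal(comp$VV_year[1, 1], -12)
  expect_equal(comp$VV_summer[1, 1], -12)
  expect_equal(comp$VV_winter[1, 1], median(c(-10, -20)))
  expect_true(all(comp$VH_year == -15))

  # permuting acquisition order leaves composites unchanged
  perm <- make_stack(arr[, , c(2, 3, 1), , drop = FALSE], dates[c(2, 3, 1)])
  expect_equal(temporal_composites(perm)[1:6], comp[1:6])

  # a temporally constant stack reproduces the constant
  cst <- make_stack(array(-7, dim = c(2, 2, 3, 2)), dates)
  expect_true(all(temporal_composites(cst)$VV_year == -7))

  expect_error(temporal_composites(make_stack(arr[, , 2, , drop = FALSE],
                                              dates[2])), "winter")
})

test_that("seasonal differences stay in dB while the VV/VH ratio is linear", {
  dates <- as.Date(c("2016-01-15", "2016-07-15"))
  arr <- array(NA_real_, dim = c(2, 2, 2, 2))
  arr[, , , 1] <- -10 # VV
  arr[, , , 2] <- -20 # VH
  comp <- temporal_composites(make_stack(arr, dates))
  sp <- seasonal_pol_metrics(comp)
  expect_true(all(sp$VV_winter_summer_diff == 0))
  expect_true(all(sp$VH_winter_summer_diff == 0))
  expect_true(all(sp$VV_VH_diff == 10))
  expect_true(all(abs(sp$VV_VH_ratio - 10) < 1e-12))

  # equal polarisations: difference 0, ratio 1
  arr2 <- arr; arr2[, , , 2] <- -10
  sp2 <- seasonal_pol_metrics(temporal_composites(make_stack(arr2, dates)))
  expect_true(all(sp2$VV_VH_diff == 0))
  expect_true(all(abs(sp2$VV_VH_ratio - 1) < 1e-12))
})

test_that("focal statistics honour window truncation at edges", {
  m <- matrix(0, 3, 3); m[2, 2] <- 9
  fs <- focal_stats(m, window = 3)
  expect_equal(fs$mean[2, 2], 1)
  expect_equal(fs$sd[2, 2], sqrt(8), tolerance = 1e-12)
  # corner window sees 4 pixels only
  expect_equal(fs$mean[1, 1], 9 / 4)

  cst <- focal_stats(matrix(5, 4, 4), window = 3)
  expect_true(all(cst$sd == 0))
  expect_true(all(cst$mean == 5))

  expect_error(focal_stats(matrix(0, 2, 2), window = 5), "larger")
  expect_error(focal_stats(m, window = 4), "odd")
})

test_that("co-occurrence features match hand calculations", {
  # constant window: single occupied cell
  g <- glcm_features(matrix(3.3, 5, 5), levels = 32, window = 5)
  expect_true(all(g$dissimilarity == 0))
  expect_true(all(g$entropy == 0))

  # two-column min/max pattern, horizontal offset only: all pairs 31 apart
  m <- matrix(rep(c(0, 1), each = 5), 5, 2)
  g2 <- glcm_features(m, levels = 32, window = 9,
                      offsets = list(c(0L, 1L)))
  expect_true(all(abs(g2$dissimilarity - 31) < 1e-12))

  # texture bounds
  set.seed(7)
  r <- matrix(rnorm(100), 10, 10)
  gr <- glcm_features(r, levels = 32, window = 9)
  expect_true(all(gr$entropy <= 2 * log(32) + 1e-12))
  expect_true(all(gr$dissimilarity <= 31 + 1e-12))
})

test_that("co-occurrence features match the brute-force pair oracle", {
  set.seed(1)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (rep in 1:50) {
    win <- matrix(rnorm(64, -12, 3), 8, 8)
    mine <- glcm_features(win, levels = 32, window = 17, offsets = offsets)
    # window 17 > 8: the centre pixel's window is the full matrix
    o <- oracle_glcm(win, 32, offsets)
    expect_equal(mine$dissimilarity[4, 4], o[["dissimilarity"]],
                 tolerance = 1e-12)
    expect_equal(mine$entropy[4, 4], o[["entropy"]], tolerance = 1e-12)
  }
})

test_that("dB shifts move medians but not textures or focal SD", {
  set.seed(5)
  st <- generate_plots(1, 1, seed = 20)
  stack <- simulate_backscatter(st[1, ], seed = 21)
  shifted <- stack
  shifted$values <- shifted$values + 3
  a <- radar_metrics(stack)
  b <- radar_metrics(shifted)
  for (nm in c("VV_year", "VH_winter", "focal_mean_VV_year")) {
    expect_equal(b[[nm]], a[[nm]] + 3, tolerance = 1e-9)
  }
  for (nm in c("focal_sd_VV_year", "glcm_dissimilarity_VH_year",
               "glcm_entropy_VV_winter", "VV_winter_summer_diff",
               "VV_VH_diff")) {
    expect_equal(b[[nm]], a[[nm]], tolerance = 1e-9)
  }
})

test_that("plot aggregation averages pixel centres inside the footprint", {
  grid <- list(origin = c(0, 0), cellsize = 10, dim = c(10L, 10L))
  layers <- list(a = matrix(4, 10, 10), b = matrix(1:100, 10, 10))
  v <- aggregate_plot_metrics(layers, grid)
  expect_equal(unname(v["a"]), 4)
  expect_equal(unname(v["b"]), mean(1:100))

  # footprint half the raster: 50 pixels
  v2 <- aggregate_plot_metrics(layers, grid, footprint = c(0, 50, 0, 100))
  expect_equal(unname(v2["b"]), mean(matrix(1:100, 10)[, 1:5]))

  expect_error(aggregate_plot_metrics(layers, grid,
                                      footprint = c(200, 300, 200, 300)),
               "footprint")

  # NaN pixels are skipped and counted
  layers$a[1, 1] <- NaN
  v3 <- aggregate_plot_metrics(layers, grid)
  expect_equal(attr(v3, "n_skipped"), 1L)
  expect_equal(unname(v3["a"]), 4)
})

test_that("plot-level backscatter SD tracks heterogeneity over many plots", {
  st <- generate_plots(50, 1, seed = 30)
  sds <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    stack <- simulate_backscatter(st[i, ], seed = 300 + i, noise_sd = 0)
    comp <- temporal_composites(stack)
    sds[i] <- sd(as.vector(comp$VV_year))
  }
  expect_gt(cor(st$heterogeneity, sds, method = "spearman"), 0.9)
})
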