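test_that("region-stratified folds balance every region across folds", {
  regions <- rep(paste0("R", 1:5), each = 10)
  folds <- region_stratified_folds(regions, k = 5, seed = 1)
  expect_setequal(unique(folds), 1:5)
  tab <- table(regions, folds)
  expect_true(all(tab == 2))
  # union of folds = all plots, pairwise disjoint (one id per plot)
  expect_equal(length(folds), 50)
  expect_identical(folds, region_stratified_folds(regions, k = 5, seed = 1))
  expect_false(identical(folds,
                         region_stratified_folds(regions, k = 5, seed = 2)))
  expect_error(region_stratified_folds(regions, k = 1), "k")
  expect_warning(region_stratified_folds(rep(c("a", "b"), c(3, 20)), k = 5,
                                         seed = 1), "fewer")
})

test_that("cross-validation metrics match a hand computation on a toy model", {
  # a deliberately trivial configuration: y is an exact linear function,
  # so every fold's model converges to the truth and R2 is ~1, RMSE ~0
  set.seed(1)
  n <- 50
  d <- data.frame(x = runif(n, -1, 1))
  y <- 2 * d$x + 1
  folds <- rep_len(1:5, n)
  cv <- cross_validate(d, y, folds, list(bl_linear("x")),
                       grid = c(200), B = 3, seed = 2)
  expect_gt(cv$mean_r2, 0.999)
  expect_lt(cv$mean_rmse, 0.01)

  # hand recomputation of one fold's metrics from its own fit
  te <- folds == 1
  fit <- fit_boosted_gam(d[!te, , drop = FALSE], y[!te],
                         list(bl_linear("x")), mstop = 200)
  pred <- predict(fit, d[te, , drop = FALSE])
  r2_hand <- 1 - sum((y[te] - pred)^2) / sum((y[te] - mean(y[te]))^2)
  rmse_hand <- sqrt(mean((y[te] - pred)^2))
  expect_equal(cv$folds$r2[1], r2_hand, tolerance = 1e-12)
  expect_equal(cv$folds$rmse[1], rmse_hand, tolerance = 1e-12)

  # mean-only predictor on pure noise explains nothing
  set.seed(3)
  n2 <- 250
  d2 <- data.frame(x = runif(n2))
  y2 <- rnorm(n2)
  cv2 <- cross_validate(d2, y2, rep_len(1:5, n2), list(bl_spline("x")),
                        grid = c(10, 50, 100), B = 5, seed = 4)
  expect_lte(cv2$mean_r2, 0.05)
})

test_that("mixed-model scoring collapses when variance is pure region offsets", {
  set.seed(5)
  n <- 250
  region <- rep(paste0("R", 1:5), each = n / 5)
  offsets <- c(R1 = -2, R2 = -1, R3 = 0, R4 = 1, R5 = 2)
  d <- data.frame(x = runif(n), region = region, stringsAsFactors = FALSE)
  y <- offsets[region] + rnorm(n, 0, 0.1)
  folds <- region_stratified_folds(region, k = 5, seed = 6)
  learners <- list(bl_spline("x"), bl_ridge("region"))
  cv <- cross_validate(d, y, folds, learners, grid = c(100, 300), B = 5,
                       seed = 7, mixed = TRUE)
  expect_lte(cv$mean_r2, 0.05)

  # ...while on data without a true region effect the mixed fixed-only
  # score stays close to the fixed-model score
  y2 <- sin(2 * pi * d$x) + rnorm(n, 0, 0.2)
  cv_fixed <- cross_validate(d[, "x", drop = FALSE], y2, folds,
                             list(bl_spline("x")), grid = c(100), B = 5,
                             seed = 8)
  cv_mixed <- cross_validate(d, y2, folds, learners, grid = c(100), B = 5,
                             seed = 8, mixed = TRUE)
  expect_lte(cv_mixed$mean_r2, cv_fixed$mean_r2 + 0.05)
})

make_paired_data <- function(n = 60, n_sp = 30, seed = 1) {
  st <- generate_plots(n, 3, seed = seed)
  tr <- simulate_phylogeny(n_sp, seed = seed + 1)
  comm <- simulate_communities(st, tr, seed = seed + 2)
  X <- data.frame(m1 = st$maturity + rnorm(n, 0, 0.05),
                  m2 = st$heterogeneity + rnorm(n, 0, 0.05))
  list(states = st, comm = comm, X = X)
}

test_that("external validation handles the joint-ordination contract", {
  set.seed(9)
  dat <- make_paired_data(n = 80, seed = 20)
  occ <- dat$comm$occurrence
  # external set: plots 61..80; training 1..60
  tr_ix <- 1:60; ex_ix <- 61:80
  learners <- list(bl_spline("m1"), bl_spline("m2"))
  res <- external_validate(occ[tr_ix, ], occ[ex_ix, ],
                           dat$X[tr_ix, ], dat$X[ex_ix, ],
                           learners, k = 2, n_starts = 10,
                           grid = c(50, 150), B = 5, seed = 10)
  # strong couplings: held-out plots from the same generator predict well
  expect_gt(res$r2, 0.2)
  expect_gte(res$rmse, 0)
  expect_equal(length(res$predicted), 20)

  # species mismatch is reported with the offending columns
  expect_error(external_validate(occ[tr_ix, ], occ[ex_ix, 1:10],
                                 dat$X[tr_ix, ], dat$X[ex_ix, ], learners),
               "sp_")
  expect_error(external_validate(occ[tr_ix, ], occ[0, ],
                                 dat$X[tr_ix, ], dat$X[0, ], learners),
               "empty")

  # the projection strategy also returns finite scores
  res_p <- external_validate(occ[tr_ix, ], occ[ex_ix, ],
                             dat$X[tr_ix, ], dat$X[ex_ix, ],
                             learners, k = 2, n_starts = 10,
                             grid = c(50), B = 5, seed = 10,
                             strategy = "project")
  expect_true(is.finite(res_p$r2))
})

tiny_config <- function(seed = 1) {
  cfg <- default_benchmark_config(seed)
  cfg$simulate$n_plots <- 40L
  cfg$simulate$n_species <- 25L
  cfg$simulate$density <- 1
  cfg$responses <- c("NMDS1", "log_richness")
  cfg$models <- c("fixed")
  cfg$sensors <- c("als")
  cfg$nmds$n_starts <- 5L
  cfg$ses$n_null <- 49L
  cfg$cv$grid_from <- 50L; cfg$cv$grid_to <- 150L; cfg$cv$grid_by <- 50L
  cfg$cv$B <- 3L
  cfg
}

test_that("the pipeline runs end to end, validates config and is reproducible", {
  expect_error(run_pipeline(list(simulate = list())), "missing")
  bad <- tiny_config(); bad$cv <- NULL
  expect_error(run_pipeline(bad), "cv")

  out_dir <- tempfile("pipe")
  rep1 <- suppressWarnings(run_pipeline(tiny_config(3), output_dir = out_dir))
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(nrow(rep1$report), 2) # response x sensor x model rows
  expect_true(all(rep1$report$mean_r2 <= 1))
  expect_true(all(rep1$report$mean_rmse >= 0))
  expect_true(file.exists(file.path(out_dir, "report.csv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))

  out_dir2 <- tempfile("pipe")
  rep2 <- suppressWarnings(run_pipeline(tiny_config(3), output_dir = out_dir2))
  expect_identical(readLines(file.path(out_dir, "report.csv")),
                   readLines(file.path(out_dir2, "report.csv")))
  unlink(c(out_dir, out_dir2), recursive = TRUE)

  # YAML round trip of the config
  yml <- tempfile(fileext = ".yml")
  yaml::write_yaml(tiny_config(3), yml)
  cfg_back <- yaml::read_yaml(yml)
  expect_equal(cfg_back$simulate$n_plots, 40)
  unlink(yml)
})
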