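## Region-stratified cross-validation, external validation and the
## end-to-end synthetic benchmark pipeline.

#' Region-stratified fold assignment
#'
#' Within each region, plots are shuffled and dealt round-robin into `k`
#' folds; folds are the unions across regions, so every fold samples every
#' region and fold sizes per region differ by at most one.
#'
#' @param regions Per-plot region labels.
#' @param k Number of folds (>= 2), default 5.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per plot.
#' @export
region_stratified_folds <- function(regions, k = 5L, seed = 1L) {
  k <- assert_count(k, "k", min = 2L)
  regions <- as.factor(regions)
  small <- names(which(table(regions) < k))
  if (length(small)) {
    warning(sprintf("region(s) with fewer than %d plots: %s", k,
                    paste(small, collapse = ", ")))
  }
  folds <- integer(length(regions))
  with_seed(seed, {
    for (r in levels(regions)) {
      ix <- which(regions == r)
      folds[ix[sample.int(length(ix))]] <-
        rep_len(seq_len(k), length(ix))
    }
  })
  folds
}

r2_rmse <- function(obs, pred) {
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  c(r2 = 1 - sse / sst,
    r2_cor = if (stats::sd(pred) > 0) stats::cor(obs, pred)^2 else 0,
    rmse = sqrt(mean((obs - pred)^2)))
}

#' Cross-validate a boosted additive model
#'
#' For each fold: the stopping iteration is tuned on the training plots
#' with [cv_mstop()], the model refit at that `mstop`, and the held-out
#' plots predicted. `R^2` is `1 - SSE/SST` with SST about the test-set
#' mean (the squared observed-predicted correlation is reported
#' alongside). With `mixed = TRUE` the learner set should contain a
#' region ridge learner; the model is fit with it but scored with
#' fixed-effects-only predictions, excluding the variance explained by
#' region.
#'
#' @param data Data frame of predictors (plus the region column for mixed
#'   models).
#' @param y Numeric response.
#' @param folds Integer fold ids from [region_stratified_folds()].
#' @param learners Base-learner list.
#' @param nu,grid,B See [cv_mstop()].
#' @param seed Integer seed (one child seed per fold).
#' @param mixed Score with fixed-effects-only predictions, default FALSE.
#' @return List of class `cv_report`: `mean_r2`, `mean_r2_cor`,
#'   `mean_rmse`, `folds` (per-fold table with the tuned `mstop`).
#' @export
cross_validate <- function(data, y, folds, learners, nu = 0.1,
                           grid = seq(10L, 500L, by = 10L), B = 25L,
                           seed = 1L, mixed = FALSE) {
  ids <- sort(unique(folds))
  per <- data.frame(fold = ids, n_test = NA_integer_, mstop = NA_integer_,
                    r2 = NA_real_, r2_cor = NA_real_, rmse = NA_real_)
  for (i in seq_along(ids)) {
    f <- ids[i]
    te <- folds == f
    if (sum(te) < 5L) {
      warning(sprintf("fold %s has fewer than 5 test plots", f))
    }
    dtr <- data[!te, , drop = FALSE]
    dte <- data[te, , drop = FALSE]
    ms <- cv_mstop(dtr, y[!te], learners, nu = nu, grid = grid, B = B,
                   seed = child_seed(seed, i))
    fit <- fit_boosted_gam(dtr, y[!te], learners, nu = nu,
                           mstop = ms$mstop)
    pred <- predict(fit, dte, fixed_only = mixed)
    m <- r2_rmse(y[te], pred)
    per$n_test[i] <- sum(te)
    per$mstop[i] <- ms$mstop
    per$r2[i] <- m["r2"]
    per$r2_cor[i] <- m["r2_cor"]
    per$rmse[i] <- m["rmse"]
  }
  structure(list(mean_r2 = mean(per$r2), mean_r2_cor = mean(per$r2_cor),
                 mean_rmse = mean(per$rmse), folds = per),
            class = "cv_report")
}

#' External validation of an assemblage-composition model
#'
#' Default (`strategy = "joint"`): training and external communities are
#' ordinated together, the model is trained on the training plots only
#' (with mstop tuned by [cv_mstop()]), and the external plots' first
#' ordination axis is predicted from their structural metrics.
#' `strategy = "project"` ordinates the training plots alone and places
#' each external plot at the dissimilarity-weighted average of the
#' training scores before fitting the same model.
#'
#' @param occurrence,occurrence_ext Plot x species 0/1 matrices with
#'   identical species columns.
#' @param X,X_ext Metric tables for the training and external plots.
#' @param learners Base-learner list for the metric columns.
#' @param k,n_starts NMDS settings.
#' @param nu,grid,B Boosting settings.
#' @param seed Integer seed.
#' @param strategy `"joint"` (default) or `"project"`.
#' @return List: `r2`, `rmse` (external plots), `r2_train`, `mstop`,
#'   `observed`, `predicted`.
#' @export
external_validate <- function(occurrence, occurrence_ext, X, X_ext,
                              learners, k = 2L, n_starts = 30L, nu = 0.1,
                              grid = seq(10L, 500L, by = 10L), B = 25L,
                              seed = 1L, strategy = c("joint", "project")) {
  strategy <- match.arg(strategy)
  if (nrow(occurrence_ext) == 0L) {
    stop("external set is empty", call. = FALSE)
  }
  sp1 <- colnames(occurrence); sp2 <- colnames(occurrence_ext)
  if (!setequal(sp1, sp2)) {
    stop(sprintf("species columns differ: %s",
                 paste(union(setdiff(sp1, sp2), setdiff(sp2, sp1)),
                       collapse = ", ")), call. = FALSE)
  }
  occurrence_ext <- occurrence_ext[, sp1, drop = FALSE]
  n <- nrow(occurrence)
  if (strategy == "joint") {
    ord <- nmds(bray_curtis(rbind(occurrence, occurrence_ext)), k = k,
                n_starts = n_starts, seed = child_seed(seed, 1L))
    y_tr <- ord$points[seq_len(n), 1]
    y_ext <- ord$points[-seq_len(n), 1]
  } else {
    ord <- nmds(bray_curtis(occurrence), k = k, n_starts = n_starts,
                seed = child_seed(seed, 1L))
    y_tr <- ord$points[, 1]
    dmat <- as.matrix(bray_curtis(rbind(occurrence, occurrence_ext)))
    w <- 1 - dmat[-seq_len(n), seq_len(n), drop = FALSE]
    w <- w / pmax(rowSums(w), .Machine$double.eps)
    y_ext <- as.vector(w %*% y_tr)
  }
  ms <- cv_mstop(X, y_tr, learners, nu = nu, grid = grid, B = B,
                 seed = child_seed(seed, 2L))
  fit <- fit_boosted_gam(X, y_tr, learners, nu = nu, mstop = ms$mstop)
  pred <- predict(fit, X_ext)
  m <- r2_rmse(y_ext, pred)
  mtr <- r2_rmse(y_tr, predict(fit, X))
  list(r2 = unname(m["r2"]), rmse = unname(m["rmse"]),
       r2_train = unname(mtr["r2"]), mstop = ms$mstop,
       observed = y_ext, predicted = pred)
}

#' Default configuration of the synthetic benchmark
#'
#' The study conditions emulated at desk scale: 250 plots over 5 regions,
#' 60 species, strong maturity/heterogeneity couplings, monthly radar
#' acquisitions over one year, pulse density 5/m^2.
#'
#' @param seed Master seed of the run.
#' @return Nested configuration list, YAML-serialisable.
#' @export
default_benchmark_config <- function(seed = 1L) {
  list(
    simulate = list(n_plots = 250L, n_regions = 5L, n_species = 60L,
                    density = 5, noise_sd = 0.8, year = 2016L,
                    seed = as.integer(seed)),
    responses = c("NMDS1", "NMDS2", "log_richness", "ses_mpd"),
    sensors = c("als", "radar"),
    models = c("fixed", "mixed"),
    nmds = list(k = 2L, n_starts = 30L),
    ses = list(n_null = 999L),
    cv = list(k = 5L, grid_from = 10L, grid_to = 500L, grid_by = 10L,
              B = 25L),
    boosting = list(nu = 0.1, df = 4)
  )
}

#' Simulate a landscape and compute both sensor metric tables
#'
#' Loops over the plots, simulating a point cloud and a backscatter stack
#' per plot (deterministic child seeds) and reducing each to its metric
#' row immediately, so memory stays flat.
#'
#' @param states `plot_states` data frame.
#' @param density Lidar pulse density (returns per m^2).
#' @param calendar Radar acquisition dates.
#' @param noise_sd Radar speckle SD (dB).
#' @param seed Integer seed.
#' @param pc_params,bs_params Generator coefficient lists.
#' @return List with data frames `als` (13 columns) and `radar` (34
#'   columns), rows named by plot id.
#' @export
landscape_metrics <- function(states, density = 5,
                              calendar = monthly_calendar(),
                              noise_sd = 0.8, seed = 1L,
                              pc_params = point_cloud_params(),
                              bs_params = backscatter_params()) {
  n <- nrow(states)
  als <- vector("list", n)
  rad <- vector("list", n)
  for (i in seq_len(n)) {
    st <- states[i, ]
    pc <- simulate_point_cloud(st, density = density,
                               seed = child_seed(seed, 2L * i),
                               params = pc_params)
    als[[i]] <- als_metrics(pc)
    stack <- simulate_backscatter(st, calendar = calendar,
                                  seed = child_seed(seed, 2L * i + 1L),
                                  noise_sd = noise_sd, params = bs_params)
    rad[[i]] <- radar_metrics(stack)
  }
  als <- do.call(rbind, als)
  rad <- do.call(rbind, rad)
  rownames(als) <- rownames(rad) <- states$plot_id
  list(als = als, radar = rad)
}

spline_learners <- function(X, df = 4) {
  lapply(colnames(X), function(v) bl_spline(v, df = df))
}

validate_config <- function(config) {
  need <- c("simulate", "responses", "sensors", "models", "nmds", "ses",
            "cv", "boosting")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop(sprintf("config is missing block(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sim_need <- c("n_plots", "n_regions", "n_species", "density", "seed")
  missing <- setdiff(sim_need, names(config$simulate))
  if (length(missing)) {
    stop(sprintf("config$simulate is missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

#' Run the full synthetic benchmark pipeline
#'
#' simulate -> sensor metrics -> biodiversity responses -> canonical
#' correlation -> boosted-GAM cross-validation, producing one evaluation
#' row per response x sensor x model. Reruns with the same configuration
#' are byte-identical.
#'
#' @param config Configuration list (see [default_benchmark_config()]) or
#'   the path of a YAML file holding one.
#' @param output_dir Optional directory; when given, `report.csv`,
#'   `responses.csv` and `manifest.json` are written there.
#' @return A list of class `evaluation_report`: `report` (data frame with
#'   `response`, `sensor`, `model`, `mean_r2`, `mean_r2_cor`,
#'   `mean_rmse`), `ccoa`, `responses`, `metrics`, `states`,
#'   `communities`, `manifest`.
#' @export
run_pipeline <- function(config = default_benchmark_config(),
                         output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  sim <- config$simulate
  seed <- as.integer(sim$seed)

  states <- generate_plots(sim$n_plots, sim$n_regions,
                           seed = child_seed(seed, 1L),
                           region_shift = sim$region_shift %||% 0)
  tree <- simulate_phylogeny(sim$n_species, seed = child_seed(seed, 2L))
  comm <- simulate_communities(states, tree, seed = child_seed(seed, 3L))
  metrics <- landscape_metrics(
    states, density = sim$density,
    calendar = monthly_calendar(sim$year %||% 2016L),
    noise_sd = sim$noise_sd %||% 0.8, seed = child_seed(seed, 4L))

  ord <- nmds(bray_curtis(comm$occurrence), k = config$nmds$k,
              n_starts = config$nmds$n_starts,
              seed = child_seed(seed, 5L))
  dmat <- ape::cophenetic.phylo(tree)
  ses <- ses_mpd(comm$occurrence, dmat, pools = comm$pools,
                 regions = as.character(states$region),
                 n_null = config$ses$n_null, seed = child_seed(seed, 6L))
  responses <- data.frame(
    plot_id = states$plot_id, region = states$region,
    maturity = states$maturity, heterogeneity = states$heterogeneity,
    log_richness = log_richness(comm$occurrence),
    ses_mpd = ses$ses_mpd,
    coverage = sample_coverage(comm$abundance)
  )
  for (j in seq_len(config$nmds$k)) {
    responses[[paste0("NMDS", j)]] <- ord$points[, j]
  }

  cca_fit <- ccoa(metrics$als, metrics$radar)

  folds <- region_stratified_folds(states$region, k = config$cv$k,
                                   seed = child_seed(seed, 7L))
  grid <- seq(config$cv$grid_from, config$cv$grid_to,
              by = config$cv$grid_by)
  rows <- list()
  run_id <- 0L
  for (resp in config$responses) {
    y <- responses[[resp]]
    if (is.null(y)) stop(sprintf("unknown response '%s'", resp), call. = FALSE)
    ok <- is.finite(y)
    for (sensor in config$sensors) {
      X <- metrics[[sensor]]
      if (is.null(X)) stop(sprintf("unknown sensor '%s'", sensor), call. = FALSE)
      for (model in config$models) {
        run_id <- run_id + 1L
        lrn <- spline_learners(X, df = config$boosting$df)
        dat <- X[ok, , drop = FALSE]
        if (model == "mixed") {
          dat$region <- as.character(states$region)[ok]
          lrn <- c(lrn, list(bl_ridge("region")))
        }
        cv <- cross_validate(dat, y[ok], folds[ok], lrn,
                             nu = config$boosting$nu, grid = grid,
                             B = config$cv$B,
                             seed = child_seed(seed, 100L + run_id),
                             mixed = (model == "mixed"))
        rows[[run_id]] <- data.frame(
          response = resp, sensor = sensor, model = model,
          n = sum(ok), mean_r2 = cv$mean_r2,
          mean_r2_cor = cv$mean_r2_cor, mean_rmse = cv$mean_rmse)
      }
    }
  }
  report <- do.call(rbind, rows)
  manifest <- list(
    package = "forestdiv",
    version = as.character(utils::packageVersion("forestdiv")),
    seed = seed, config = config,
    n_plots = nrow(states),
    nmds_stress = ord$stress,
    canonical_correlations = cca_fit$cor
  )
  out <- structure(list(report = report, ccoa = cca_fit,
                        responses = responses, metrics = metrics,
                        states = states, communities = comm,
                        manifest = manifest),
                   class = "evaluation_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(output_dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(responses, file.path(output_dir, "responses.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
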