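## Synthetic forest landscape generator.
##
## Emulates the joint statistical structure of a multi-region temperate
## forest monitoring network: plots spread over regions along latent
## gradients of stand maturity and structural heterogeneity, lidar point
## clouds and radar backscatter stacks coupled to those gradients, and
## multi-species communities whose turnover follows maturity and whose
## richness follows heterogeneity.

#' Generate latent plot states
#'
#' Draws `n_plots` forest plots distributed over `n_regions` regions. Each
#' plot carries a latent maturity `M` and structural heterogeneity `Het`
#' (both uniform on \[0, 1\] by default, optionally with small region-level
#' mean shifts) plus a conifer fraction. These latent states drive every
#' downstream simulator, so recovery of the gradients can be tested.
#'
#' @param n_plots Number of plots (>= `n_regions`).
#' @param n_regions Number of regions; plots are dealt round-robin so
#'   region sizes differ by at most one.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param region_shift Standard deviation of optional region-level mean
#'   shifts added to maturity and heterogeneity (default 0 = off). Shifted
#'   values are clamped to \[0, 1\].
#' @return A data frame of class `plot_states` with columns `plot_id`,
#'   `region` (factor), `maturity`, `heterogeneity`, `conifer_ratio`.
#' @examples
#' st <- generate_plots(20, 4, seed = 1)
#' table(st$region)
#' @export
generate_plots <- function(n_plots, n_regions, seed = 1L, region_shift = 0) {
  assert_count(n_plots, "n_plots")
  assert_count(n_regions, "n_regions")
  if (n_plots < n_regions) {
    stop("`n_plots` must be at least `n_regions`", call. = FALSE)
  }
  assert_number(region_shift, "region_shift", lower = 0)
  with_seed(seed, {
    region <- factor(rep_len(paste0("R", seq_len(n_regions)), n_plots),
                     levels = paste0("R", seq_len(n_regions)))
    m_shift <- stats::rnorm(n_regions, 0, region_shift)
    h_shift <- stats::rnorm(n_regions, 0, region_shift)
    maturity <- stats::runif(n_plots) + m_shift[as.integer(region)]
    heterogeneity <- stats::runif(n_plots) + h_shift[as.integer(region)]
    out <- data.frame(
      plot_id = sprintf("plot_%03d", seq_len(n_plots)),
      region = region,
      maturity = pmin(pmax(maturity, 0), 1),
      heterogeneity = pmin(pmax(heterogeneity, 0), 1),
      conifer_ratio = stats::runif(n_plots),
      stringsAsFactors = FALSE
    )
    class(out) <- c("plot_states", "data.frame")
    out
  })
}

#' Default coupling coefficients for the point-cloud simulator
#'
#' Canopy top height follows `height_base + height_slope * M` metres; the
#' fraction of 1-m cells that are canopy gaps is `gap_coef * (1 - M)`;
#' cell-to-cell height relief and within-canopy vertical spread grow with
#' heterogeneity.
#'
#' @param height_base,height_slope Top-height law (m), default 5 + 30 M.
#' @param gap_coef Gap fraction coefficient, default 0.4.
#' @param relief_coef Maximum proportional cell-height reduction at
#'   `Het = 1`, default 0.6.
#' @param ground_frac Fraction of returns in vegetated cells that reach the
#'   ground, default 0.08.
#' @param understory_coef Probability that a vegetation return samples the
#'   understory (< 2 m) scales as `understory_coef * Het`, default 0.25.
#' @param plot_size Plot edge length (m), default 100.
#' @return Named list of coefficients.
#' @export
point_cloud_params <- function(height_base = 5, height_slope = 30,
                               gap_coef = 0.4, relief_coef = 0.6,
                               ground_frac = 0.08, understory_coef = 0.25,
                               plot_size = 100) {
  list(height_base = height_base, height_slope = height_slope,
       gap_coef = gap_coef, relief_coef = relief_coef,
       ground_frac = ground_frac, understory_coef = understory_coef,
       plot_size = plot_size)
}

#' Simulate a height-normalised lidar point cloud for one plot
#'
#' Returns are scattered uniformly over a square plot divided into 1-m
#' cells. A maturity-decreasing fraction of cells is gap (ground-only
#' returns, z = 0). Vegetated cells carry a canopy top height that scales
#' with maturity; vegetation return heights are drawn from a Beta profile
#' near the local top, with vertical spread, cell-to-cell relief and
#' understory occupancy all increasing with heterogeneity.
#'
#' @param state One row of [generate_plots()] output (or any list with
#'   `maturity` and `heterogeneity` in \[0, 1\]).
#' @param density Pulse density (returns per square metre), > 0. Expected
#'   return count is `density * plot_size^2`.
#' @param seed Integer seed.
#' @param params Coefficients from [point_cloud_params()].
#' @return A data frame of class `point_cloud` with columns `x`, `y`
#'   (metres within the plot), `z` (height above ground, >= 0; exactly 0
#'   for ground returns) and `cls` (`"ground"` or `"vegetation"`).
#' @examples
#' st <- generate_plots(1, 1, seed = 2)
#' pc <- simulate_point_cloud(st[1, ], density = 2, seed = 3)
#' range(pc$z)
#' @export
simulate_point_cloud <- function(state, density = 10, seed = 1L,
                                 params = point_cloud_params()) {
  assert_number(density, "density", lower = 1e-6)
  M <- assert_number(state$maturity, "state$maturity", 0, 1)
  Het <- assert_number(state$heterogeneity, "state$heterogeneity", 0, 1)
  sz <- params$plot_size
  ncell <- as.integer(sz) # 1-m cells per edge
  with_seed(seed, {
    top <- params$height_base + params$height_slope * M
    n_cells <- ncell * ncell
    relief <- stats::runif(n_cells)
    h_cell <- top * (1 - params$relief_coef * Het * relief)
    gap_frac <- params$gap_coef * (1 - M)
    is_gap <- stats::runif(n_cells) < gap_frac
    n <- max(1L, stats::rpois(1, density * sz^2))
    cell <- sample.int(n_cells, n, replace = TRUE)
    x <- (cell - 1L) %% ncell + stats::runif(n)
    y <- (cell - 1L) %/% ncell + stats::runif(n)
    ground <- is_gap[cell] | (stats::runif(n) < params$ground_frac)
    z <- numeric(n)
    veg <- !ground
    if (any(veg)) {
      under <- veg & (stats::runif(n) < params$understory_coef * Het)
      canopy <- veg & !under
      # Beta(s1, 5) profile: tight near the top when Het = 0, spreading
      # downwards as heterogeneity grows
      s1 <- 2 + 48 * (1 - 0.9 * Het)
      if (any(canopy)) {
        z[canopy] <- h_cell[cell[canopy]] * stats::rbeta(sum(canopy), s1, 5)
      }
      if (any(under)) {
        z[under] <- stats::runif(sum(under), 0, pmin(2, h_cell[cell[under]]))
      }
      z[veg] <- pmax(z[veg], 1e-3) # vegetation returns sit above ground
    }
    out <- data.frame(
      x = x, y = y, z = z,
      cls = ifelse(ground, "ground", "vegetation"),
      stringsAsFactors = FALSE
    )
    class(out) <- c("point_cloud", "data.frame")
    attr(out, "plot_size") <- sz
    out
  })
}

#' Season windows for backscatter composites
#'
#' @param summer,winter Integer months belonging to the summer and winter
#'   windows (defaults June-August and December-February).
#' @return Named list of month vectors.
#' @export
season_windows <- function(summer = 6:8, winter = c(12L, 1L, 2L)) {
  list(summer = as.integer(summer), winter = as.integer(winter))
}

#' A monthly acquisition calendar
#'
#' @param year Calendar year.
#' @return `Date` vector, the 15th of each month.
#' @export
monthly_calendar <- function(year = 2016) {
  as.Date(sprintf("%d-%02d-15", year, 1:12))
}

#' Simulate a dual-polarisation backscatter stack for one plot
#'
#' Produces gamma-naught backscatter (dB) on a 10-m grid for every date and
#' polarisation. Mean backscatter decreases with maturity (most strongly in
#' winter), a static spatial field with standard deviation proportional to
#' heterogeneity creates horizontal structure, the seasonal cycle has
#' amplitude proportional to the broadleaf fraction `1 - conifer_ratio`,
#' and speckle is emulated by additive Gaussian noise in dB.
#'
#' @param state One row of [generate_plots()] output.
#' @param calendar `Date` vector; must contain at least one date in each
#'   season window.
#' @param seed Integer seed.
#' @param noise_sd Speckle standard deviation in dB (default 0.8; 0 gives a
#'   noiseless stack).
#' @param seasons Season windows from [season_windows()].
#' @param params Named list of coupling coefficients: `base` (dB level per
#'   polarisation), `mat_slope` (yearly dB decrease per unit maturity),
#'   `winter_extra` (additional winter decrease), `season_amp` (seasonal
#'   amplitude at conifer ratio 0), `spatial_sd` (spatial field SD per unit
#'   heterogeneity), `dim` (raster rows/cols), `cellsize` (m).
#' @return A list of class `backscatter_stack` with elements `dates`,
#'   `pols`, `values` (4-d array row x col x date x pol, dB), and `grid`.
#' @export
simulate_backscatter <- function(state, calendar = monthly_calendar(),
                                 seed = 1L, noise_sd = 0.8,
                                 seasons = season_windows(),
                                 params = backscatter_params()) {
  if (length(calendar) == 0L) stop("`calendar` must be non-empty", call. = FALSE)
  calendar <- as.Date(calendar)
  mo <- as.integer(format(calendar, "%m"))
  for (w in names(seasons)) {
    if (!any(mo %in% seasons[[w]])) {
      stop(sprintf("calendar contains no date in the '%s' window (months %s)",
                   w, paste(seasons[[w]], collapse = ",")), call. = FALSE)
    }
  }
  M <- assert_number(state$maturity, "state$maturity", 0, 1)
  Het <- assert_number(state$heterogeneity, "state$heterogeneity", 0, 1)
  conifer <- assert_number(state$conifer_ratio %||% 0.5,
                           "state$conifer_ratio", 0, 1)
  assert_number(noise_sd, "noise_sd", lower = 0)
  d <- params$dim
  pols <- c("VV", "VH")
  nd <- length(calendar)
  with_seed(seed, {
    spatial <- matrix(stats::rnorm(d * d, 0, params$spatial_sd * Het), d, d)
    doy <- as.integer(format(calendar, "%j"))
    # +1 near midsummer (doy ~196), -1 near midwinter
    s <- cos(2 * pi * (doy - 196) / 365.25)
    winterness <- (1 - s) / 2
    vals <- array(NA_real_, dim = c(d, d, nd, 2L),
                  dimnames = list(NULL, NULL, as.character(calendar), pols))
    for (p in 1:2) {
      mu <- params$base[p] - params$mat_slope[p] * M +
        params$season_amp[p] * (1 - conifer) * s -
        params$winter_extra[p] * M * winterness
      for (t in seq_len(nd)) {
        layer <- mu[t] + spatial
        if (noise_sd > 0) layer <- layer + stats::rnorm(d * d, 0, noise_sd)
        vals[, , t, p] <- layer
      }
    }
    structure(list(
      dates = calendar, pols = pols, values = vals,
      grid = list(origin = c(0, 0), cellsize = params$cellsize, dim = c(d, d))
    ), class = "backscatter_stack")
  })
}

#' Default coupling coefficients for the backscatter simulator
#'
#' @param base Mean dB level at maturity 0 for VV and VH.
#' @param mat_slope Yearly dB decrease per unit maturity (VV, VH).
#' @param winter_extra Additional midwinter dB decrease per unit maturity.
#' @param season_amp Seasonal amplitude (dB) for a pure broadleaf stand.
#' @param spatial_sd Spatial-field SD (dB) per unit heterogeneity.
#' @param dim,cellsize Raster dimension (pixels per edge) and cell size (m).
#' @return Named list of coefficients.
#' @export
backscatter_params <- function(base = c(VV = -8, VH = -14.5),
                               mat_slope = c(VV = 3.5, VH = 4.5),
                               winter_extra = c(VV = 1.5, VH = 3),
                               season_amp = c(VV = 1, VH = 1.5),
                               spatial_sd = 1.5, dim = 10L, cellsize = 10) {
  list(base = base, mat_slope = mat_slope, winter_extra = winter_extra,
       season_amp = season_amp, spatial_sd = spatial_sd,
       dim = as.integer(dim), cellsize = cellsize)
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree with positive branch lengths, ultrametric.
#' @export
simulate_phylogeny <- function(n_species, seed = 1L) {
  assert_count(n_species, "n_species", min = 2L)
  with_seed(seed, {
    tr <- ape::rphylo(n_species, birth = 1, death = 0)
    tr$tip.label <- sprintf("sp_%03d", seq_len(n_species))
    tr
  })
}

#' Default coupling coefficients for the community simulator
#'
#' @param niche_sd Width of the Gaussian maturity response (default 0.15,
#'   i.e. tight niches and strong turnover along maturity).
#' @param p_max Peak occurrence probability at the species optimum.
#' @param het_mult_min Richness multiplier at heterogeneity 0; the
#'   multiplier rises linearly to 1 at heterogeneity 1.
#' @param abundance_mean Mean extra individuals per occurrence (abundance
#'   is `1 + Poisson(abundance_mean - 1)` given presence).
#' @param optimum_bm_sigma Brownian-motion rate used to evolve maturity
#'   optima on the tree (phylogenetic conservatism).
#' @return Named list of coefficients.
#' @export
community_params <- function(niche_sd = 0.15, p_max = 0.7,
                             het_mult_min = 0.4, abundance_mean = 3,
                             optimum_bm_sigma = 1) {
  list(niche_sd = niche_sd, p_max = p_max, het_mult_min = het_mult_min,
       abundance_mean = abundance_mean,
       optimum_bm_sigma = optimum_bm_sigma)
}

#' Expected occurrence probabilities before sampling
#'
#' Gaussian response curve in maturity around each species optimum, times a
#' richness multiplier increasing in heterogeneity.
#'
#' @param states `plot_states` data frame.
#' @param optima Named numeric vector of species maturity optima in \[0, 1\].
#' @param params [community_params()].
#' @return Plot x species probability matrix.
#' @export
occurrence_probability <- function(states, optima,
                                   params = community_params()) {
  mult <- params$het_mult_min +
    (1 - params$het_mult_min) * states$heterogeneity
  P <- params$p_max *
    exp(-outer(states$maturity, optima, function(m, o) (m - o)^2) /
          (2 * params$niche_sd^2)) * mult
  rownames(P) <- states$plot_id
  colnames(P) <- names(optima)
  P
}

#' Species maturity optima evolved on a phylogeny
#'
#' Brownian motion on the tree, mapped to \[0, 1\] by the standard-normal
#' distribution function so related species occupy nearby positions along
#' the maturity gradient (phylogenetic niche conservatism).
#'
#' @param tree `phylo` tree.
#' @param sigma Brownian rate.
#' @param seed Integer seed.
#' @return Named vector of optima in (0, 1) ordered as `tree$tip.label`.
#' @export
evolve_optima <- function(tree, sigma = 1, seed = 1L) {
  with_seed(seed, {
    z <- ape::rTraitCont(tree, model = "BM", sigma = sigma)
    s <- stats::sd(z)
    if (!is.finite(s) || s == 0) s <- 1
    opt <- stats::pnorm((z - mean(z)) / s)
    names(opt) <- tree$tip.label
    opt
  })
}

#' Simulate multi-species communities over the plots
#'
#' Occurrence is Bernoulli with probability from
#' [occurrence_probability()]; abundance is `1 + Poisson` given presence so
#' that `occurrence == (abundance > 0)` holds exactly. Regional species
#' pools collect every species observed in a region. A plot left empty by
#' sampling is redrawn once; a second empty draw is an error.
#'
#' @param states `plot_states` data frame.
#' @param tree `phylo` tree; its tips define the species set.
#' @param params [community_params()].
#' @param seed Integer seed.
#' @param optima Optional named vector of species maturity optima (as from
#'   [evolve_optima()]); supply the training optima when simulating an
#'   external set so the species keep their niches. Default: evolved on
#'   `tree` from the seed.
#' @return A list of class `community_set`: `occurrence` (0/1 matrix),
#'   `abundance` (count matrix), `prob` (pre-sampling probabilities),
#'   `optima`, `phylogeny`, `pools` (region -> species character vectors),
#'   `regions` (per-plot factor).
#' @export
simulate_communities <- function(states, tree, params = community_params(),
                                 seed = 1L, optima = NULL) {
  if (nrow(states) == 0L) stop("`states` must be non-empty", call. = FALSE)
  n_sp <- length(tree$tip.label)
  if (is.null(optima)) {
    optima <- evolve_optima(tree, sigma = params$optimum_bm_sigma,
                            seed = child_seed(seed, 1L))
  }
  if (!setequal(names(optima), tree$tip.label)) {
    stop("`optima` must cover exactly the tree's tips", call. = FALSE)
  }
  optima <- optima[tree$tip.label]
  P <- occurrence_probability(states, optima, params)
  with_seed(child_seed(seed, 2L), {
    n <- nrow(P)
    occ <- matrix(as.integer(stats::runif(n * n_sp) < P), n, n_sp,
                  dimnames = dimnames(P))
    empty <- rowSums(occ) == 0L
    if (any(empty)) {
      redraw <- matrix(as.integer(stats::runif(sum(empty) * n_sp) <
                                    P[empty, , drop = FALSE]),
                       sum(empty), n_sp)
      occ[empty, ] <- redraw
      still <- rowSums(occ) == 0L
      if (any(still)) {
        stop(sprintf("plot(s) %s empty after one resample; increase p_max or richness multiplier",
                     paste(rownames(P)[still], collapse = ", ")),
             call. = FALSE)
      }
    }
    extra <- matrix(stats::rpois(n * n_sp,
                                 max(params$abundance_mean - 1, 0)),
                    n, n_sp)
    abund <- occ * (1L + extra)
    dimnames(abund) <- dimnames(occ)
    pools <- lapply(split(seq_len(n), states$region), function(ix) {
      colnames(occ)[colSums(occ[ix, , drop = FALSE]) > 0L]
    })
    structure(list(
      occurrence = occ, abundance = abund, prob = P, optima = optima,
      phylogeny = tree, pools = pools, regions = states$region
    ), class = "community_set")
  })
}

#' Write / read a point cloud in the columnar text dialect
#'
#' Plain-text CSV with columns `x`, `y`, `z`, `cls`.
#'
#' @param pc A `point_cloud` data frame.
#' @param file Path.
#' @return `read_point_cloud()` returns a `point_cloud` data frame.
#' @export
write_point_cloud <- function(pc, file) {
  utils::write.csv(as.data.frame(pc)[, c("x", "y", "z", "cls")], file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "cls")
  if (!all(need %in% names(df))) {
    stop("point-cloud file must have columns x, y, z, cls", call. = FALSE)
  }
  df <- df[, need]
  class(df) <- c("point_cloud", "data.frame")
  df
}
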