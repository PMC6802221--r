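## Structural metrics from height-normalised lidar point clouds.
##
## Thirteen plot-level metrics: height distribution of vegetation returns,
## penetration ratios of the canopy sub-layers, foliage height diversity,
## canopy-gap area and edge length, and canopy-surface-model statistics.

veg_heights <- function(pc) {
  pc$z[pc$cls == "vegetation"]
}

#' Height metrics of the vegetation returns
#'
#' Mean, maximum, standard deviation (sample, n-1) and coefficient of
#' variation of the heights of vegetation-classified returns.
#'
#' @param pc A `point_cloud` data frame (`x`, `y`, `z`, `cls`).
#' @return Named numeric vector `H_mean`, `H_max`, `H_SD`, `H_CV`.
#' @export
height_metrics <- function(pc) {
  h <- veg_heights(pc)
  if (length(h) == 0L) stop("no vegetation returns in point cloud", call. = FALSE)
  m <- mean(h)
  s <- if (length(h) > 1L) stats::sd(h) else 0
  if (m <= 0) stop("mean vegetation height is zero; H_CV undefined", call. = FALSE)
  c(H_mean = m, H_max = max(h), H_SD = s, H_CV = s / m)
}

#' Penetration ratios and foliage height diversity
#'
#' Sub-layer penetration ratios divide the returns captured by a layer by
#' the returns that reached it: `PR_canopy = n(h > 5) / n_total`,
#' `PR_understory = n(2 < h <= 5) / n(h <= 5)`,
#' `PR_regen = n(0 < h <= 2) / n(h <= 2)` (ground returns stay in the
#' denominator), and canopy cover `PR_h2 = n(h > 2) / n_total`. Foliage
#' height diversity is the Shannon entropy of the vegetation-return
#' proportions in the three layers (canopy > 5 m, understory 2-5 m,
#' regeneration <= 2 m); empty layers contribute zero.
#'
#' Layer boundaries use half-open intervals `(lower, upper]`. An empty
#' denominator yields a ratio of 0.
#'
#' @param pc A `point_cloud` data frame.
#' @return Named vector `PR_canopy`, `PR_understory`, `PR_regen`, `PR_h2`,
#'   `FHD` (nats, in \[0, ln 3\]).
#' @export
penetration_metrics <- function(pc) {
  if (nrow(pc) == 0L) stop("empty point cloud", call. = FALSE)
  z <- pc$z
  n <- length(z)
  ratio <- function(num, den) if (den == 0L) 0 else num / den
  n_gt5 <- sum(z > 5)
  n_le5 <- n - n_gt5
  n_2to5 <- sum(z > 2 & z <= 5)
  n_le2 <- sum(z <= 2)
  veg <- pc$cls == "vegetation"
  n_regen <- sum(veg & z <= 2) # vegetation returns below 2 m (z > 0)
  p <- c(sum(veg & z > 5), sum(veg & z > 2 & z <= 5), n_regen)
  fhd <- 0
  if (sum(p) > 0L) {
    pr <- p[p > 0] / sum(p)
    fhd <- -sum(pr * log(pr))
  }
  c(PR_canopy = ratio(n_gt5, n),
    PR_understory = ratio(n_2to5, n_le5),
    PR_regen = ratio(n_regen, n_le2),
    PR_h2 = ratio(n - n_le2, n),
    FHD = fhd)
}

## 8- (or 4-) connected component labelling of a logical mask
label_mask <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0L) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cell - 1L) %% nr + 1L
      c <- (cell - 1L) %/% nr + 1L
      rr <- r + dr; cc <- c + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb) > 0L) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

## exposed rook-edge perimeter per labelled feature, in cell units
feature_perimeters <- function(lab) {
  ids <- seq_len(max(lab, 0L))
  if (length(ids) == 0L) return(numeric(0))
  nr <- nrow(lab); nc <- ncol(lab)
  per <- numeric(length(ids))
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  for (shift in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nbr <- pad[2:(nr + 1L) + shift[1], 2:(nc + 1L) + shift[2]]
    exposed <- core > 0L & nbr != core
    tab <- tabulate(core[exposed], nbins = length(ids))
    per <- per + tab
  }
  per
}

#' Canopy gap area and edge length
#'
#' A gap mask is built by computing, per grid cell, the penetration ratio
#' of the canopy-understory layer (`n(h > 2) / n_total`) and flagging cells
#' below `pr_threshold`. Neighbouring gap cells (8-connectivity by
#' default) are aggregated into gap features. Features smaller than
#' `min_area` or with perimeter-area ratio below `par_threshold` are
#' excluded (set `invert_par_rule = TRUE` to instead exclude features with
#' a ratio above the threshold; the elongation reading of the filter).
#' Cells without returns are treated as no-data and never enter the mask.
#'
#' @param pc A `point_cloud` data frame.
#' @param cell Cell size (m), default 1; must divide the plot edge.
#' @param pr_threshold Gap threshold on the cell-level canopy-cover
#'   penetration ratio, default 0.2.
#' @param min_area Minimum surviving feature area (m^2), default 50.
#' @param par_threshold Perimeter-area-ratio threshold (1/m), default 1.5.
#' @param connectivity 8 (default) or 4.
#' @param invert_par_rule Logical; flip the direction of the PAR filter.
#' @param plot_size Plot edge length (m); taken from the point cloud
#'   attribute when present.
#' @return List with `Gap_Area_sqrt` (sqrt of summed area, sqrt-m^2),
#'   `Gap_Edge_sqrt` (sqrt of summed exposed rook-edge length, sqrt-m),
#'   `features` (data frame: id, area, perimeter, par, kept) and
#'   `n_nodata` (count of return-free cells).
#' @export
gap_metrics <- function(pc, cell = 1, pr_threshold = 0.2, min_area = 50,
                        par_threshold = 1.5, connectivity = 8L,
                        invert_par_rule = FALSE,
                        plot_size = attr(pc, "plot_size") %||% 100) {
  assert_number(cell, "cell", lower = 1e-9)
  ncell <- plot_size / cell
  if (abs(ncell - round(ncell)) > 1e-9) {
    stop("`cell` must divide the plot edge length", call. = FALSE)
  }
  ncell <- as.integer(round(ncell))
  ix <- pmin(pmax(floor(pc$x / cell), 0), ncell - 1L)
  iy <- pmin(pmax(floor(pc$y / cell), 0), ncell - 1L)
  cid <- iy * ncell + ix + 1L
  n_tot <- tabulate(cid, nbins = ncell^2)
  n_hi <- tabulate(cid[pc$z > 2], nbins = ncell^2)
  nodata <- n_tot == 0L
  pr <- ifelse(nodata, NA_real_, n_hi / pmax(n_tot, 1L))
  mask <- matrix(!is.na(pr) & pr < pr_threshold, ncell, ncell)
  lab <- label_mask(mask, connectivity)
  nfeat <- max(lab, 0L)
  if (nfeat == 0L) {
    feats <- data.frame(id = integer(0), area = numeric(0),
                        perimeter = numeric(0), par = numeric(0),
                        kept = logical(0))
  } else {
    area <- tabulate(lab[lab > 0L], nbins = nfeat) * cell^2
    perim <- feature_perimeters(lab) * cell
    par <- perim / area
    kept <- area >= min_area &
      (if (invert_par_rule) par <= par_threshold else par >= par_threshold)
    feats <- data.frame(id = seq_len(nfeat), area = area,
                        perimeter = perim, par = par, kept = kept)
  }
  list(Gap_Area_sqrt = sqrt(sum(feats$area[feats$kept])),
       Gap_Edge_sqrt = sqrt(sum(feats$perimeter[feats$kept])),
       features = feats, n_nodata = sum(nodata))
}

## nearest-neighbour fill of NA cells in a matrix of cell values
nn_fill <- function(m) {
  empty <- which(is.na(m))
  if (length(empty) == 0L) return(m)
  filled <- which(!is.na(m))
  if (length(filled) == 0L) stop("all CHM cells empty", call. = FALSE)
  nr <- nrow(m)
  er <- (empty - 1L) %% nr + 1L; ec <- (empty - 1L) %/% nr + 1L
  fr <- (filled - 1L) %% nr + 1L; fc <- (filled - 1L) %/% nr + 1L
  for (k in seq_along(empty)) {
    d2 <- (fr - er[k])^2 + (fc - ec[k])^2
    m[empty[k]] <- m[filled[which.min(d2)]]
  }
  m
}

#' Rasterise a canopy surface model
#'
#' Highest return per cell; empty cells filled from the nearest non-empty
#' cell (a deliberately simple surface; no pit-free interpolation).
#'
#' @inheritParams gap_metrics
#' @param res Cell size (m), default 1.
#' @return Numeric matrix of canopy surface heights.
#' @export
rasterize_chm <- function(pc, res = 1,
                          plot_size = attr(pc, "plot_size") %||% 100) {
  assert_number(res, "res", lower = 1e-9)
  ncell <- as.integer(round(plot_size / res))
  ix <- pmin(pmax(floor(pc$x / res), 0), ncell - 1L)
  iy <- pmin(pmax(floor(pc$y / res), 0), ncell - 1L)
  cid <- iy * ncell + ix + 1L
  chm <- rep(NA_real_, ncell^2)
  agg <- tapply(pc$z, cid, max)
  chm[as.integer(names(agg))] <- agg
  nn_fill(matrix(chm, ncell, ncell))
}

## summed 3-d area of the triangulated surface over a lattice of cell
## centres with spacing `res`
surface_area <- function(z, res) {
  nr <- nrow(z); nc <- ncol(z)
  z00 <- z[-nr, -nc]; z10 <- z[-1, -nc]; z01 <- z[-nr, -1]; z11 <- z[-1, -1]
  # lower-left triangle (z00, z10, z01) and upper-right (z11, z01, z10)
  a1 <- 0.5 * res * sqrt((z10 - z00)^2 + (z01 - z00)^2 + res^2)
  a2 <- 0.5 * res * sqrt((z01 - z11)^2 + (z10 - z11)^2 + res^2)
  sum(a1) + sum(a2)
}

#' Canopy-surface-model metrics
#'
#' Standard deviation of the canopy surface heights and the ratio of the
#' triangulated 3-d canopy surface area to the flat area spanned by the
#' cell-centre lattice.
#'
#' @inheritParams rasterize_chm
#' @return Named vector `CSM_SD` (m) and `Surface_ratio` (>= 1).
#' @export
chm_metrics <- function(pc, res = 1,
                        plot_size = attr(pc, "plot_size") %||% 100) {
  chm <- rasterize_chm(pc, res = res, plot_size = plot_size)
  flat <- (nrow(chm) - 1) * (ncol(chm) - 1) * res^2
  c(CSM_SD = stats::sd(as.vector(chm)),
    Surface_ratio = surface_area(chm, res) / flat)
}

#' Names and order of the 13 ALS metrics
#' @return Character vector.
#' @export
als_metric_names <- function() {
  c("H_mean", "H_max", "H_SD", "H_CV",
    "PR_canopy", "PR_understory", "PR_regen", "PR_h2", "FHD",
    "Gap_Area_sqrt", "Gap_Edge_sqrt", "CSM_SD", "Surface_ratio")
}

#' All 13 ALS structural metrics for one plot
#'
#' @inheritParams gap_metrics
#' @param chm_res Canopy-surface-model resolution (m).
#' @param ... Passed to [gap_metrics()].
#' @return One-row data frame with the columns of [als_metric_names()].
#' @examples
#' st <- generate_plots(1, 1, seed = 5)
#' pc <- simulate_point_cloud(st[1, ], density = 2, seed = 5)
#' als_metrics(pc)
#' @export
als_metrics <- function(pc, cell = 1, chm_res = 1, ...) {
  hm <- height_metrics(pc)
  pm <- penetration_metrics(pc)
  gm <- gap_metrics(pc, cell = cell, ...)
  cm <- chm_metrics(pc, res = chm_res)
  out <- data.frame(t(c(hm, pm,
                        Gap_Area_sqrt = gm$Gap_Area_sqrt,
                        Gap_Edge_sqrt = gm$Gap_Edge_sqrt, cm)))
  out[, als_metric_names()]
}
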