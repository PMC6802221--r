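## Multi-temporal backscatter and texture metrics.
##
## Works on per-plot backscatter stacks (dB, 10-m grid): seasonal median
## composites, seasonal/polarisation differences and ratios, focal
## statistics, grey-level co-occurrence textures, and plot aggregation.

season_of <- function(dates, seasons) {
  mo <- as.integer(format(as.Date(dates), "%m"))
  list(year = rep(TRUE, length(mo)),
       summer = mo %in% seasons$summer,
       winter = mo %in% seasons$winter)
}

#' Temporal median composites
#'
#' Per-pixel median backscatter (dB) over the dates in each window:
#' whole-year, summer and winter, for both polarisations.
#'
#' @param stack A `backscatter_stack`.
#' @param seasons Season windows from [season_windows()].
#' @return A list of class `radar_composites` with six matrices named
#'   `VV_year`, `VH_year`, `VV_summer`, `VH_summer`, `VV_winter`,
#'   `VH_winter`, plus the grid metadata.
#' @export
temporal_composites <- function(stack, seasons = season_windows()) {
  win <- season_of(stack$dates, seasons)
  out <- list()
  for (w in names(win)) {
    if (!any(win[[w]])) {
      stop(sprintf("no dates fall in the '%s' window", w), call. = FALSE)
    }
    for (p in seq_along(stack$pols)) {
      v <- stack$values[, , win[[w]], p, drop = FALSE]
      out[[paste0(stack$pols[p], "_", w)]] <-
        apply(v, c(1, 2), stats::median)
    }
  }
  structure(c(out, list(grid = stack$grid)), class = "radar_composites")
}

#' Seasonal and polarisation difference/ratio layers
#'
#' Winter minus summer median (dB) per polarisation, the yearly VV minus VH
#' difference (dB), and the yearly VV/VH ratio on the linear power scale
#' (`10^(dB/10)`), keeping difference and ratio distinct quantities.
#'
#' @param comp A `radar_composites` list.
#' @return Named list of matrices `VV_winter_summer_diff`,
#'   `VH_winter_summer_diff`, `VV_VH_diff`, `VV_VH_ratio`.
#' @export
seasonal_pol_metrics <- function(comp) {
  need <- c("VV_year", "VH_year", "VV_summer", "VH_summer",
            "VV_winter", "VH_winter")
  if (!all(need %in% names(comp))) {
    stop("all six composites are required", call. = FALSE)
  }
  dims <- vapply(comp[need], dim, integer(2))
  if (any(dims != dims[, 1])) stop("composite grids differ", call. = FALSE)
  list(
    VV_winter_summer_diff = comp$VV_winter - comp$VV_summer,
    VH_winter_summer_diff = comp$VH_winter - comp$VH_summer,
    VV_VH_diff = comp$VV_year - comp$VH_year,
    VV_VH_ratio = 10^(comp$VV_year / 10) / 10^(comp$VH_year / 10)
  )
}

#' Focal mean and standard deviation
#'
#' Moving-window mean and population standard deviation per pixel; windows
#' are truncated at the raster edges (no padding).
#'
#' @param layer Numeric matrix.
#' @param window Odd window size in pixels, default 9.
#' @return List of matrices `mean` and `sd`.
#' @export
focal_stats <- function(layer, window = 9L) {
  window <- assert_count(window, "window", min = 3L)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  nr <- nrow(layer); nc <- ncol(layer)
  if (window > nr && window > nc) {
    stop("window larger than the raster in both dimensions", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  mu <- sdev <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - h):min(nr, i + h)
    for (j in seq_len(nc)) {
      v <- layer[ri, max(1L, j - h):min(nc, j + h)]
      v <- v[is.finite(v)]
      if (length(v) == 0L) next
      mu[i, j] <- mean(v)
      sdev[i, j] <- sd_pop(v)
    }
  }
  list(mean = mu, sd = sdev)
}

## quantise a numeric vector/matrix to 1..levels by min-max scaling
quantise_greys <- function(v, levels) {
  rng <- range(v, finite = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    out <- v
    out[is.finite(v)] <- 1L
    return(out)
  }
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  pmin(q, levels)
}

## co-occurrence features of one quantised window for one offset
glcm_pair_features <- function(q, dr, dc, levels) {
  nr <- nrow(q); nc <- ncol(q)
  if (nr - abs(dr) < 1L || nc - abs(dc) < 1L) return(NULL)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r1, c1]
  b <- q[r1 + dr, c1 + dc]
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) return(NULL)
  a <- as.integer(a[ok]); b <- as.integer(b[ok])
  # symmetric accumulation: count both (a,b) and (b,a)
  idx <- (c(a, b) - 1L) * levels + c(b, a)
  cnt <- tabulate(idx, nbins = levels * levels)
  nz <- which(cnt > 0L)
  p <- cnt[nz] / sum(cnt)
  ii <- (nz - 1L) %/% levels + 1L
  jj <- (nz - 1L) %% levels + 1L
  c(dissimilarity = sum(p * abs(ii - jj)),
    entropy = -sum(p * log(p)))
}

#' Grey-level co-occurrence texture layers
#'
#' Per pixel, the surrounding window (truncated at edges) is quantised to
#' `levels` grey levels by min-max scaling, and a symmetric co-occurrence
#' matrix is accumulated for each spatial offset. Dissimilarity
#' (`sum p_ij |i-j|`, contrast group) and entropy (`-sum p_ij log p_ij`,
#' orderliness group) are averaged over the offsets.
#'
#' @param layer Numeric matrix (dB).
#' @param levels Number of grey levels, default 32.
#' @param window Odd moving-window size, default 9.
#' @param offsets List of integer `c(dr, dc)` offsets; default the four
#'   directions right, down, down-right, down-left.
#' @return List of matrices `dissimilarity` and `entropy`.
#' @export
glcm_features <- function(layer, levels = 32L, window = 9L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L))) {
  levels <- assert_count(levels, "levels", min = 2L)
  window <- assert_count(window, "window", min = 3L)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  nr <- nrow(layer); nc <- ncol(layer)
  h <- (window - 1L) %/% 2L
  dis <- ent <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - h):min(nr, i + h)
    for (j in seq_len(nc)) {
      sub <- layer[ri, max(1L, j - h):min(nc, j + h), drop = FALSE]
      if (sum(is.finite(sub)) < 2L) next
      q <- matrix(quantise_greys(sub, levels), nrow(sub), ncol(sub))
      feats <- lapply(offsets,
                      function(o) glcm_pair_features(q, o[1], o[2], levels))
      feats <- feats[!vapply(feats, is.null, logical(1))]
      if (length(feats) == 0L) next
      fm <- do.call(rbind, feats)
      dis[i, j] <- mean(fm[, "dissimilarity"])
      ent[i, j] <- mean(fm[, "entropy"])
    }
  }
  list(dissimilarity = dis, entropy = ent)
}

#' Aggregate metric layers to plot level
#'
#' Mean of the pixels whose centres fall inside the plot footprint, per
#' layer. Non-finite pixels are skipped (their count is reported).
#'
#' @param layers Named list of numeric matrices on a common grid.
#' @param grid List with `origin` (x, y of the lower-left corner),
#'   `cellsize` and `dim` (rows, cols).
#' @param footprint `c(xmin, xmax, ymin, ymax)` in grid units; default the
#'   full raster extent.
#' @return Named numeric vector, one value per layer; attribute
#'   `n_skipped` counts non-finite pixels.
#' @export
aggregate_plot_metrics <- function(layers, grid, footprint = NULL) {
  d <- grid$dim
  cs <- grid$cellsize
  xc <- grid$origin[1] + (seq_len(d[2]) - 0.5) * cs
  yc <- grid$origin[2] + (seq_len(d[1]) - 0.5) * cs
  if (is.null(footprint)) {
    footprint <- c(grid$origin[1], grid$origin[1] + d[2] * cs,
                   grid$origin[2], grid$origin[2] + d[1] * cs)
  }
  inx <- xc >= footprint[1] & xc <= footprint[2]
  iny <- yc >= footprint[3] & yc <= footprint[4]
  if (!any(inx) || !any(iny)) {
    stop("no pixel centres inside the footprint", call. = FALSE)
  }
  skipped <- 0L
  out <- vapply(layers, function(m) {
    v <- m[iny, inx]
    bad <- !is.finite(v)
    skipped <<- skipped + sum(bad)
    mean(v[!bad])
  }, numeric(1))
  attr(out, "n_skipped") <- skipped
  out
}

#' Names and order of the radar metrics
#' @return Character vector (34 metrics).
#' @export
radar_metric_names <- function() {
  comps <- c("VV_year", "VH_year", "VV_summer", "VH_summer",
             "VV_winter", "VH_winter")
  c(comps,
    "VV_winter_summer_diff", "VH_winter_summer_diff",
    "VV_VH_diff", "VV_VH_ratio",
    paste0("focal_mean_", comps), paste0("focal_sd_", comps),
    paste0("glcm_dissimilarity_", comps), paste0("glcm_entropy_", comps))
}

#' All plot-level radar metrics for one backscatter stack
#'
#' Median composites, seasonal/polarisation differences and ratio, focal
#' mean/SD and co-occurrence textures of each composite, aggregated over
#' the plot footprint.
#'
#' @param stack A `backscatter_stack`.
#' @param seasons Season windows.
#' @param levels,window,offsets Texture settings, see [glcm_features()].
#' @return One-row data frame with the columns of [radar_metric_names()].
#' @export
radar_metrics <- function(stack, seasons = season_windows(), levels = 32L,
                          window = 9L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L))) {
  comp <- temporal_composites(stack, seasons)
  diffs <- seasonal_pol_metrics(comp)
  comps <- c("VV_year", "VH_year", "VV_summer", "VH_summer",
             "VV_winter", "VH_winter")
  layers <- c(comp[comps], diffs)
  for (nm in comps) {
    fs <- focal_stats(comp[[nm]], window = window)
    layers[[paste0("focal_mean_", nm)]] <- fs$mean
    layers[[paste0("focal_sd_", nm)]] <- fs$sd
    gf <- glcm_features(comp[[nm]], levels = levels, window = window,
                        offsets = offsets)
    layers[[paste0("glcm_dissimilarity_", nm)]] <- gf$dissimilarity
    layers[[paste0("glcm_entropy_", nm)]] <- gf$entropy
  }
  vals <- aggregate_plot_metrics(layers, comp$grid)
  out <- data.frame(t(vals))
  out[, radar_metric_names()]
}
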