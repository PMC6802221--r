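## Biodiversity response variables: assemblage-composition ordination,
## species richness, phylogenetic diversity and sample coverage.

#' Bray-Curtis dissimilarity on presence-absence data
#'
#' `d(A, B) = 1 - 2 |A intersect B| / (|A| + |B|)` over the species sets of
#' two plots.
#'
#' @param occurrence Plot x species 0/1 matrix; every row needs at least
#'   one presence.
#' @return A `dist` object.
#' @export
bray_curtis <- function(occurrence) {
  occurrence <- as.matrix(occurrence)
  s <- rowSums(occurrence > 0)
  if (any(s == 0)) {
    bad <- rownames(occurrence)[s == 0] %||% which(s == 0)
    stop(sprintf("plot(s) without any species: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  occ <- (occurrence > 0) + 0
  shared <- tcrossprod(occ)
  d <- 1 - 2 * shared / outer(s, s, `+`)
  diag(d) <- 0
  stats::as.dist(d)
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 over a `k`-dimensional configuration, taking
#' the best of `n_starts` random initialisations (plus a metric-scaling
#' start, and any configurations supplied through `init`). The winning
#' configuration is centred and rotated to its principal axes so the first
#' axis carries maximal variance.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param k Target dimension (>= 1).
#' @param n_starts Number of random starts, default 30.
#' @param seed Integer seed.
#' @param init Optional list of starting configurations (n x k matrices)
#'   tried in addition to the generated starts.
#' @param maxit Maximum iterations per start.
#' @return A list of class `nmds_fit`: `points` (n x k), `stress`
#'   (Kruskal stress-1, 0-1), `k`, `n_starts`, `converged`.
#' @export
nmds <- function(d, k, n_starts = 30L, seed = 1L, init = NULL,
                 maxit = 500L) {
  assert_count(k, "k")
  assert_count(n_starts, "n_starts")
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  labs <- attr(d, "Labels") %||% as.character(seq_len(n))
  starts <- list()
  # metric-scaling start; pad with noise if fewer positive eigenvalues
  with_seed(child_seed(seed, 0L), {
    cmd <- suppressWarnings(stats::cmdscale(d, k = k))
    if (ncol(cmd) < k) {
      cmd <- cbind(cmd, matrix(stats::rnorm(n * (k - ncol(cmd)), 0, 1e-3),
                               n, k - ncol(cmd)))
    }
    starts[[1L]] <- cmd
    for (s in seq_len(n_starts - 1L)) {
      starts[[s + 1L]] <- matrix(stats::runif(n * k, -1, 1), n, k)
    }
  })
  starts <- c(starts, init)
  best <- NULL
  for (y0 in starts) {
    fit <- vegan::monoMDS(d, y = as.matrix(y0), k = k, model = "global",
                          maxit = maxit)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  if (k > 1L) {
    pts <- stats::prcomp(pts, center = FALSE)$x[, seq_len(k), drop = FALSE]
  }
  dimnames(pts) <- list(labs, paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress, k = as.integer(k),
                 n_starts = as.integer(n_starts),
                 converged = isTRUE(best$icause %in% c(2L, 3L)) ||
                   best$stress < 1e-3),
            class = "nmds_fit")
}

#' Choose the NMDS dimensionality by the stress < 0.2 rule
#'
#' Fits NMDS for `k = 1..k_max` and returns the smallest dimension whose
#' best-of-starts stress falls below `stress_threshold`. To keep the
#' stress sequence non-increasing, each dimension also starts from the
#' previous winner padded with a small random axis. If no dimension
#' passes, `k_max` is returned with a warning.
#'
#' @inheritParams nmds
#' @param k_max Largest dimension tried, default 5.
#' @param stress_threshold Stress rule, default 0.2.
#' @return List: `k` (chosen), `stress` (per dimension), `fits` (per
#'   dimension `nmds_fit`), `passed` (logical).
#' @export
select_dimension <- function(d, k_max = 5L, n_starts = 30L, seed = 1L,
                             stress_threshold = 0.2, maxit = 500L) {
  assert_count(k_max, "k_max")
  fits <- vector("list", k_max)
  stresses <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    init <- NULL
    if (!is.null(prev)) {
      pad <- with_seed(child_seed(seed, 100L + k), {
        matrix(stats::rnorm(nrow(prev$points), 0, 1e-4 +
                              1e-4 * max(abs(prev$points))),
               nrow(prev$points), 1L)
      })
      init <- list(cbind(prev$points, pad))
    }
    fit <- nmds(d, k, n_starts = n_starts, seed = child_seed(seed, k),
                init = init, maxit = maxit)
    fits[[k]] <- fit
    stresses[k] <- fit$stress
    prev <- fit
    if (fit$stress < stress_threshold) {
      return(list(k = k, stress = stresses[seq_len(k)],
                  fits = fits[seq_len(k)], passed = TRUE))
    }
  }
  warning(sprintf("no dimension up to %d reached stress < %g; returning k_max",
                  k_max, stress_threshold))
  list(k = k_max, stress = stresses, fits = fits, passed = FALSE)
}

#' Log species richness
#'
#' Natural log of the per-plot species count.
#'
#' @param occurrence Plot x species 0/1 matrix; every plot needs >= 1
#'   species.
#' @return Named numeric vector.
#' @export
log_richness <- function(occurrence) {
  s <- rowSums(as.matrix(occurrence) > 0)
  if (any(s == 0)) {
    bad <- rownames(occurrence)[s == 0] %||% which(s == 0)
    stop(sprintf("plot(s) with zero species: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  log(s)
}

## mean pairwise distance among a set of species indices
mpd_of <- function(D, idx) {
  s <- length(idx)
  if (s < 2L) return(NA_real_)
  sub <- D[idx, idx]
  sum(sub) / (s * (s - 1))
}

#' Standardised effect size of mean pairwise phylogenetic distance
#'
#' For each plot, the observed mean pairwise patristic distance (MPD) over
#' its species is compared with a null distribution built from `n_null`
#' random assemblages of the same richness drawn without replacement from
#' the plot's regional species pool: `SES = (obs - mean(null)) / sd(null)`.
#' Plots with fewer than two species, or with a degenerate null
#' (`sd = 0`), are returned as `NA` and flagged.
#'
#' @param occurrence Plot x species 0/1 matrix (column names = species).
#' @param dist_mat Species x species patristic distance matrix (e.g.
#'   `ape::cophenetic.phylo`); must cover all occurring species.
#' @param pools Optional list mapping region name to a character vector of
#'   pool species. Default: one common pool of all columns.
#' @param regions Optional per-plot region labels (required with `pools`).
#' @param n_null Number of null assemblages, default 999.
#' @param seed Integer seed.
#' @return Data frame with `mpd`, `ses_mpd`, `richness` and `flag`
#'   (`"ok"`, `"single_species"` or `"degenerate_null"`).
#' @export
ses_mpd <- function(occurrence, dist_mat, pools = NULL, regions = NULL,
                    n_null = 999L, seed = 1L) {
  occurrence <- as.matrix(occurrence)
  assert_count(n_null, "n_null")
  sp <- colnames(occurrence)
  if (is.null(sp)) stop("`occurrence` needs species column names", call. = FALSE)
  missing_sp <- setdiff(sp[colSums(occurrence > 0) > 0], rownames(dist_mat))
  if (length(missing_sp) > 0L) {
    stop(sprintf("species without distances: %s",
                 paste(missing_sp, collapse = ", ")), call. = FALSE)
  }
  if (is.null(pools)) {
    pools <- list(all = sp)
    regions <- rep("all", nrow(occurrence))
  }
  if (is.null(regions) || length(regions) != nrow(occurrence)) {
    stop("`regions` must give one label per plot", call. = FALSE)
  }
  regions <- as.character(regions)
  n <- nrow(occurrence)
  out <- data.frame(mpd = rep(NA_real_, n), ses_mpd = NA_real_,
                    richness = rowSums(occurrence > 0), flag = "ok",
                    stringsAsFactors = FALSE)
  rownames(out) <- rownames(occurrence)
  with_seed(seed, {
    for (i in seq_len(n)) {
      occ_sp <- sp[occurrence[i, ] > 0]
      s <- length(occ_sp)
      if (s < 2L) {
        out$flag[i] <- "single_species"
        next
      }
      pool <- pools[[regions[i]]]
      if (is.null(pool)) {
        stop(sprintf("no pool for region '%s'", regions[i]), call. = FALSE)
      }
      pool <- union(pool, occ_sp) # pools cover their region's species
      if (length(pool) < s) {
        stop(sprintf("pool for region '%s' smaller than plot richness",
                     regions[i]), call. = FALSE)
      }
      pidx <- match(pool, rownames(dist_mat))
      Dp <- dist_mat[pidx, pidx]
      obs <- mpd_of(Dp, match(occ_sp, pool))
      np <- length(pool)
      null <- vapply(seq_len(n_null), function(b) {
        mpd_of(Dp, sample.int(np, s))
      }, numeric(1))
      mu <- mean(null); sg <- stats::sd(null)
      out$mpd[i] <- obs
      if (!is.finite(sg) || sg == 0) {
        out$flag[i] <- "degenerate_null"
      } else {
        out$ses_mpd[i] <- (obs - mu) / sg
      }
    }
  })
  out
}

#' Chao-Jost sample coverage
#'
#' Estimated proportion of the community's individuals that belong to
#' detected species:
#' `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`, with `f1`, `f2` the
#' singleton and doubleton counts and `n` the total abundance.
#'
#' @param abundance Plot x species count matrix; every plot needs total
#'   abundance >= 1.
#' @return Named numeric vector of coverages in \[0, 1\].
#' @export
sample_coverage <- function(abundance) {
  abundance <- as.matrix(abundance)
  apply(abundance, 1, function(a) {
    n <- sum(a)
    if (n < 1) stop("plot with zero total abundance", call. = FALSE)
    f1 <- sum(a == 1)
    f2 <- sum(a == 2)
    if (f1 == 0) return(1)
    denom <- (n - 1) * f1 + 2 * f2
    if (denom == 0) return(1 - f1 / n)
    1 - (f1 / n) * ((n - 1) * f1 / denom)
  })
}

#' Plots above a sample-coverage threshold
#'
#' @param abundance Plot x species count matrix.
#' @param threshold Minimum coverage (e.g. 0.9, 0.8, 0.7).
#' @return Logical vector: which plots to keep.
#' @export
coverage_subset <- function(abundance, threshold) {
  assert_number(threshold, "threshold", 0, 1)
  sample_coverage(abundance) > threshold
}
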