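# Independent brute-force oracles used to validate the package
# implementations. These deliberately share no code with R/: loops and
# first-principles formulas only.

# --- co-occurrence texture oracle: explicit pair enumeration -------------
oracle_glcm <- function(win, levels, offsets) {
  v <- as.vector(win)
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    q <- matrix(1L, nrow(win), ncol(win))
  } else {
    q <- matrix(pmin(floor((win - lo) / (hi - lo) * levels) + 1L, levels),
                nrow(win), ncol(win))
  }
  dis_all <- ent_all <- c()
  for (off in offsets) {
    counts <- matrix(0, levels, levels)
    for (i in seq_len(nrow(q))) {
      for (j in seq_len(ncol(q))) {
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
          a <- q[i, j]; b <- q[i2, j2]
          counts[a, b] <- counts[a, b] + 1
          counts[b, a] <- counts[b, a] + 1
        }
      }
    }
    if (sum(counts) == 0) next
    p <- counts / sum(counts)
    dis <- 0; ent <- 0
    for (a in seq_len(levels)) {
      for (b in seq_len(levels)) {
        if (p[a, b] > 0) {
          dis <- dis + p[a, b] * abs(a - b)
          ent <- ent - p[a, b] * log(p[a, b])
        }
      }
    }
    dis_all <- c(dis_all, dis); ent_all <- c(ent_all, ent)
  }
  c(dissimilarity = mean(dis_all), entropy = mean(ent_all))
}

# --- connected-component / gap-filter oracle: set-growing flood fill -----
oracle_gap_features <- function(mask, min_area = 50, par_threshold = 1.5,
                                cell = 1, invert_par_rule = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  feats <- list()
  for (si in seq_len(nr)) {
    for (sj in seq_len(nc)) {
      if (!mask[si, sj] || seen[si, sj]) next
      # grow the component one ring at a time (8-neighbourhood)
      comp <- matrix(c(si, sj), 1, 2)
      seen[si, sj] <- TRUE
      frontier <- comp
      while (nrow(frontier) > 0) {
        nxt <- NULL
        for (r in seq_len(nrow(frontier))) {
          for (di in -1:1) for (dj in -1:1) {
            if (di == 0 && dj == 0) next
            ii <- frontier[r, 1] + di; jj <- frontier[r, 2] + dj
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                mask[ii, jj] && !seen[ii, jj]) {
              seen[ii, jj] <- TRUE
              nxt <- rbind(nxt, c(ii, jj))
            }
          }
        }
        comp <- rbind(comp, nxt)
        frontier <- if (is.null(nxt)) matrix(0, 0, 2) else nxt
      }
      # perimeter: 4-neighbour sides facing outside the component
      per <- 0
      inset <- paste(comp[, 1], comp[, 2])
      for (r in seq_len(nrow(comp))) {
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- comp[r, 1] + d[1]; jj <- comp[r, 2] + d[2]
          if (!(paste(ii, jj) %in% inset)) per <- per + 1
        }
      }
      area <- nrow(comp) * cell^2
      per <- per * cell
      pr <- per / area
      keep <- area >= min_area &&
        (if (invert_par_rule) pr <= par_threshold else pr >= par_threshold)
      feats[[length(feats) + 1]] <-
        list(area = area, perimeter = per, par = pr, kept = keep)
    }
  }
  feats
}

# --- triangulated surface-area oracle: explicit 3-d cross products -------
oracle_surface_area <- function(z, res) {
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    0.5 * sqrt(sum(cr^2))
  }
  total <- 0
  for (i in seq_len(nrow(z) - 1)) {
    for (j in seq_len(ncol(z) - 1)) {
      p00 <- c((i - 1) * res, (j - 1) * res, z[i, j])
      p10 <- c(i * res, (j - 1) * res, z[i + 1, j])
      p01 <- c((i - 1) * res, j * res, z[i, j + 1])
      p11 <- c(i * res, j * res, z[i + 1, j + 1])
      total <- total + tri_area(p00, p10, p01) + tri_area(p11, p01, p10)
    }
  }
  total
}

# --- naive NMDS: direct numerical minimisation of Kruskal stress-1 -------
oracle_stress1 <- function(conf, delta) {
  d <- as.vector(dist(conf))
  dl <- as.vector(delta)
  ord <- order(dl)
  dhat <- numeric(length(d))
  dhat[ord] <- isoreg(d[ord])$yf
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

oracle_nmds_stress <- function(delta, k, n_tries = 8, seed = 42) {
  delta <- as.dist(delta)
  n <- attr(delta, "Size")
  best <- Inf
  set.seed(seed)
  for (t in seq_len(n_tries)) {
    x0 <- if (t == 1) {
      cm <- suppressWarnings(cmdscale(delta, k = k))
      if (ncol(cm) < k) cm <- cbind(cm, matrix(rnorm(n * (k - ncol(cm)),
                                                     0, 1e-3), n))
      cm
    } else {
      matrix(runif(n * k, -1, 1), n, k)
    }
    res <- optim(as.vector(x0),
                 function(p) oracle_stress1(matrix(p, n, k), delta),
                 method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    res2 <- optim(res$par,
                  function(p) oracle_stress1(matrix(p, n, k), delta),
                  method = "Nelder-Mead",
                  control = list(maxit = 2000))
    best <- min(best, res$value, res2$value)
  }
  best
}

# --- brute-force first canonical correlation for p = q = 2 ---------------
# for each direction a in the X plane, the best correlation over all b is
# the multiple correlation of Xa on Y (closed form)
oracle_cancor1 <- function(X, Y, n_grid = 4000) {
  Xs <- scale(X); Ys <- scale(Y)
  best <- 0
  for (theta in seq(0, pi, length.out = n_grid)) {
    u <- Xs %*% c(cos(theta), sin(theta))
    r2 <- summary(lm(u ~ Ys))$r.squared
    best <- max(best, sqrt(r2))
  }
  best
}

# point cloud whose per-cell canopy-cover penetration ratio is 0 on mask
# cells (ground-only) and 1 elsewhere; mask rows index y, columns x
make_mask_cloud <- function(mask, n_per_cell = 20) {
  nr <- nrow(mask)
  xs <- ys <- zs <- c()
  for (i in seq_len(nr)) {
    for (j in seq_len(ncol(mask))) {
      x <- (j - 1) + runif(n_per_cell)
      y <- (i - 1) + runif(n_per_cell)
      z <- if (mask[i, j]) rep(0, n_per_cell) else runif(n_per_cell, 10, 20)
      xs <- c(xs, x); ys <- c(ys, y); zs <- c(zs, z)
    }
  }
  toy_cloud(zs, x = xs, y = ys, plot_size = nr)
}

# small deterministic point-cloud builder for metric unit tests
toy_cloud <- function(z, cls = NULL, x = NULL, y = NULL, plot_size = 100) {
  n <- length(z)
  cls <- cls %||% ifelse(z > 0, "vegetation", "ground")
  pc <- data.frame(x = x %||% runif(n, 0, plot_size),
                   y = y %||% runif(n, 0, plot_size),
                   z = z, cls = cls, stringsAsFactors = FALSE)
  class(pc) <- c("point_cloud", "data.frame")
  attr(pc, "plot_size") <- plot_size
  pc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
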