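## Canonical correlation analysis between two standardised metric tables,
## with structure correlations, Wilks' lambda F-approximations and
## RDA-style redundancy indices.

## symmetric inverse square root with a stabilising ridge
inv_sqrt <- function(S, ridge) {
  S <- S + diag(ridge, nrow(S))
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Canonical correlation analysis of two metric tables
#'
#' Columns of both tables are standardised to zero mean and unit variance;
#' the canonical directions come from a singular value decomposition of
#' the whitened cross-covariance matrix. A small ridge on the within-set
#' covariances guards against near-singularity (its value is recorded in
#' the result). Each axis is oriented so that its largest-magnitude
#' structure correlation in the first table is positive.
#'
#' @param X,Y Numeric matrices or data frames (n plots x p and n x q
#'   metrics); columns must be non-constant, and by default `n` must
#'   exceed `max(p, q)`.
#' @param ridge Ridge added to the within-set covariances, default 1e-10.
#' @return A list of class `ccoa_fit`: `cor` (canonical correlations,
#'   non-increasing in \[0, 1\]), `xcoef`, `ycoef` (directions for the
#'   standardised variables), `xscores`, `yscores` (unit-variance axis
#'   scores), `xstructure`, `ystructure` (variable-axis correlations),
#'   `redundancy` (per-axis RDA-style indices for each set), `wilks`
#'   (sequential Lambda / F / p table), `n`, `p`, `q`, `ridge`.
#' @export
ccoa <- function(X, Y, ridge = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) stop("X and Y need the same rows", call. = FALSE)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  const <- c(colnames(X) %||% paste0("X", seq_len(p)))[apply(X, 2, stats::sd) == 0]
  constY <- c(colnames(Y) %||% paste0("Y", seq_len(q)))[apply(Y, 2, stats::sd) == 0]
  if (length(const) || length(constY)) {
    stop(sprintf("constant column(s): %s",
                 paste(c(const, constY), collapse = ", ")), call. = FALSE)
  }
  if (n <= max(p, q)) {
    stop("need more plots than variables in each set", call. = FALSE)
  }
  Xs <- scale(X); Ys <- scale(Y)
  Sxx <- crossprod(Xs) / (n - 1)
  Syy <- crossprod(Ys) / (n - 1)
  Sxy <- crossprod(Xs, Ys) / (n - 1)
  Wx <- inv_sqrt(Sxx, ridge)
  Wy <- inv_sqrt(Syy, ridge)
  sv <- svd(Wx %*% Sxy %*% Wy)
  d <- min(p, q, n - 1L)
  rho <- pmin(pmax(sv$d[seq_len(d)], 0), 1)
  A <- Wx %*% sv$u[, seq_len(d), drop = FALSE]
  B <- Wy %*% sv$v[, seq_len(d), drop = FALSE]
  xs <- Xs %*% A
  ys <- Ys %*% B
  # rescale scores to exactly unit variance
  sx <- apply(xs, 2, stats::sd); sy <- apply(ys, 2, stats::sd)
  xs <- sweep(xs, 2, sx, "/"); A <- sweep(A, 2, sx, "/")
  ys <- sweep(ys, 2, sy, "/"); B <- sweep(B, 2, sy, "/")
  # sign convention from the X-set structure correlations
  xstr <- stats::cor(Xs, xs)
  flip <- vapply(seq_len(d), function(i) {
    v <- xstr[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  A <- sweep(A, 2, flip, "*"); xs <- sweep(xs, 2, flip, "*")
  B <- sweep(B, 2, flip, "*"); ys <- sweep(ys, 2, flip, "*")
  axnames <- paste0("can", seq_len(d))
  dimnames(A) <- list(colnames(X), axnames)
  dimnames(B) <- list(colnames(Y), axnames)
  colnames(xs) <- paste0("X", axnames)
  colnames(ys) <- paste0("Y", axnames)
  fit <- structure(list(cor = rho, xcoef = A, ycoef = B,
                        xscores = xs, yscores = ys,
                        n = n, p = p, q = q, ridge = ridge),
                   class = "ccoa_fit")
  fit$xstructure <- structure_correlations(fit, X, "x")
  fit$ystructure <- structure_correlations(fit, Y, "y")
  fit$redundancy <- list(
    x = colMeans(fit$xstructure^2) * rho^2,
    y = colMeans(fit$ystructure^2) * rho^2
  )
  fit$wilks <- wilks_significance(rho, n, p, q)
  fit
}

#' Structure correlations of the original variables with canonical axes
#'
#' Pearson correlation of each (standardised) variable with each canonical
#' axis score of its own set.
#'
#' @param fit A `ccoa_fit`.
#' @param data The original table for the chosen `set`.
#' @param set `"x"` or `"y"`.
#' @param alpha Optional significance level; when given, an attribute
#'   `significant` marks correlations with `p < alpha`.
#' @return Variables x axes correlation matrix.
#' @export
structure_correlations <- function(fit, data, set = c("x", "y"),
                                   alpha = NULL) {
  set <- match.arg(set)
  scores <- if (set == "x") fit$xscores else fit$yscores
  data <- as.matrix(data)
  out <- stats::cor(data, scores)
  if (!is.null(alpha)) {
    n <- nrow(data)
    tstat <- out * sqrt((n - 2) / pmax(1 - out^2, .Machine$double.eps))
    pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
    attr(out, "significant") <- pval < alpha
  }
  out
}

#' Wilks' lambda sequential tests with Rao's F-approximation
#'
#' For each `k`, tests whether canonical correlations `k..d` are jointly
#' zero: `Lambda_k = prod(1 - rho_i^2)` for `i >= k`, approximated by an F
#' statistic with Rao's degrees of freedom.
#'
#' @param rho Canonical correlations (non-increasing).
#' @param n,p,q Sample size and numbers of variables in the two sets.
#' @return Data frame with `k`, `lambda`, `F`, `df1`, `df2`, `p_value`
#'   (`NA` with a warning when degrees of freedom are non-positive).
#' @export
wilks_significance <- function(rho, n, p, q) {
  d <- length(rho)
  out <- data.frame(k = seq_len(d), lambda = NA_real_, F = NA_real_,
                    df1 = NA_real_, df2 = NA_real_, p_value = NA_real_)
  for (k in seq_len(d)) {
    pk <- p - k + 1
    qk <- q - k + 1
    lam <- prod(1 - rho[k:d]^2)
    s2 <- (pk^2 * qk^2 - 4) / (pk^2 + qk^2 - 5)
    s <- if (is.finite(s2) && s2 > 0) sqrt(s2) else 1
    df1 <- pk * qk
    w <- n - 1 - (pk + qk + 1) / 2
    df2 <- w * s - pk * qk / 2 + 1
    out$lambda[k] <- lam
    out$df1[k] <- df1
    out$df2[k] <- df2
    if (df2 <= 0) {
      warning(sprintf("non-positive denominator df for k = %d", k))
      next
    }
    l1s <- lam^(1 / s)
    Fk <- if (l1s <= .Machine$double.eps) Inf else (1 - l1s) / l1s * df2 / df1
    out$F[k] <- Fk
    out$p_value[k] <- stats::pf(Fk, df1, df2, lower.tail = FALSE)
  }
  out
}
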