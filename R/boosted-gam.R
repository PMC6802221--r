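## Component-wise gradient boosting of additive models (L2 loss).
##
## Every iteration fits each base learner to the current residuals by
## penalised least squares, updates only the best one by a step-length
## nu, and records the risk reduction. P-spline learners provide the
## smooth terms; a penalised categorical (ridge) learner serves as the
## random-intercept surrogate for region effects; an unpenalised linear
## learner is available for reference fits.

#' Base learner specifications
#'
#' @param var Predictor column name.
#' @param knots Number of interior knots of the P-spline basis.
#' @param degree B-spline degree (3 = cubic).
#' @param diff_order Difference-penalty order.
#' @param df Effective degrees of freedom of one penalised fit; the ridge
#'   penalty is solved to match it. For `bl_ridge` the default is the
#'   number of levels minus one (one df per spare level).
#' @return A learner specification (list) consumed by
#'   [fit_boosted_gam()].
#' @export
bl_spline <- function(var, knots = 20L, degree = 3L, diff_order = 2L,
                      df = 4) {
  structure(list(kind = "spline", var = var, knots = as.integer(knots),
                 degree = as.integer(degree),
                 diff_order = as.integer(diff_order), df = df,
                 name = paste0("spline(", var, ")")),
            class = "bl_spec")
}

#' @rdname bl_spline
#' @export
bl_linear <- function(var) {
  structure(list(kind = "linear", var = var,
                 name = paste0("linear(", var, ")")),
            class = "bl_spec")
}

#' @rdname bl_spline
#' @export
bl_ridge <- function(var, df = NULL) {
  structure(list(kind = "ridge", var = var, df = df,
                 name = paste0("ridge(", var, ")")),
            class = "bl_spec")
}

## ridge penalty matching a target effective df:
## trace(Z (Z'Z + lambda P)^-1 Z') = df
lambda_for_df <- function(Z, P, df) {
  m <- ncol(Z)
  R <- chol(crossprod(Z) + diag(1e-8, m))
  Ri <- backsolve(R, diag(m))
  K <- t(Ri) %*% P %*% Ri
  ev <- pmax(eigen(K, symmetric = TRUE, only.values = TRUE)$values, 0)
  if (df >= m) return(0)
  floor_df <- sum(ev < 1e-12)
  if (df <= floor_df) {
    stop(sprintf("df = %g not reachable: penalty null space has dimension %d",
                 df, floor_df), call. = FALSE)
  }
  f <- function(loglam) sum(1 / (1 + exp(loglam) * ev)) - df
  exp(stats::uniroot(f, c(-25, 35), tol = 1e-10)$root)
}

ps_knots <- function(lo, hi, knots, degree) {
  lo + (hi - lo) / knots * seq(-degree, knots + degree)
}

ps_design <- function(x, kn, degree, lo, hi) {
  # clamp to the exact spline support (constant extrapolation beyond the
  # training range); kn is evenly spaced so support = [kn[d+1], kn[nk-d]]
  nk <- length(kn)
  splines::splineDesign(kn, pmin(pmax(x, kn[degree + 1L]), kn[nk - degree]),
                        ord = degree + 1L)
}

## instantiate a learner on training data: design matrix, penalised
## solver, and a design generator for new data
build_learner <- function(spec, data) {
  x <- data[[spec$var]]
  if (is.null(x)) {
    stop(sprintf("predictor '%s' not found", spec$var), call. = FALSE)
  }
  bl <- list(spec = spec, name = spec$name, kind = spec$kind)
  if (spec$kind == "spline") {
    x <- as.numeric(x)
    if (!all(is.finite(x))) stop(sprintf("missing values in '%s'", spec$var),
                                 call. = FALSE)
    if (stats::sd(x) == 0) {
      stop(sprintf("constant predictor for learner %s", spec$name),
           call. = FALSE)
    }
    lo <- min(x); hi <- max(x)
    kn <- ps_knots(lo, hi, spec$knots, spec$degree)
    Z <- ps_design(x, kn, spec$degree, lo, hi)
    Dm <- diff(diag(ncol(Z)), differences = spec$diff_order)
    P <- crossprod(Dm)
    lambda <- lambda_for_df(Z, P, spec$df)
    bl$newdesign <- local({
      kn <- kn; degree <- spec$degree; lo <- lo; hi <- hi
      function(newdata) ps_design(as.numeric(newdata[[spec$var]]),
                                  kn, degree, lo, hi)
    })
  } else if (spec$kind == "linear") {
    x <- as.numeric(x)
    if (!all(is.finite(x))) stop(sprintf("missing values in '%s'", spec$var),
                                 call. = FALSE)
    Z <- cbind(1, x)
    P <- matrix(0, 2, 2)
    lambda <- 0
    bl$newdesign <- function(newdata) cbind(1, as.numeric(newdata[[spec$var]]))
  } else if (spec$kind == "ridge") {
    f <- factor(x)
    lev <- levels(f)
    if (length(lev) < 2L) {
      stop(sprintf("learner %s needs >= 2 levels", spec$name), call. = FALSE)
    }
    Z <- stats::model.matrix(~ 0 + f)
    colnames(Z) <- lev
    P <- diag(length(lev))
    df <- spec$df %||% (length(lev) - 1)
    lambda <- lambda_for_df(Z, P, df)
    bl$newdesign <- local({
      lev <- lev
      function(newdata) {
        fnew <- as.character(newdata[[spec$var]])
        Zn <- matrix(0, length(fnew), length(lev))
        hit <- match(fnew, lev)
        ok <- !is.na(hit)
        Zn[cbind(which(ok), hit[ok])] <- 1 # unseen levels: zero row
        Zn
      }
    })
  } else {
    stop("unknown learner kind", call. = FALSE)
  }
  m <- ncol(Z)
  bl$Z <- Z
  bl$M0 <- crossprod(Z)
  bl$G <- chol2inv(chol(bl$M0 + lambda * P + diag(1e-10, m)))
  bl$lambda <- lambda
  bl
}

## core boosting loop; optionally tracks held-out predictions along the
## path and records held-out mean squared error at `grid` iterations.
## Learner selection uses the identity rss_j = |u|^2 - red_j with
## red_j = 2 c'Gc - c'GM0Gc, c = Z_j'u, so only one full-size
## cross-product per iteration is needed.
boost_core <- function(built, y, nu, mstop, Zte = NULL, yte = NULL,
                       grid = NULL) {
  n <- length(y)
  offset <- mean(y)
  fhat <- rep(offset, n)
  coefs <- lapply(built, function(b) numeric(ncol(b$Z)))
  J <- length(built)
  Zall <- do.call(cbind, lapply(built, `[[`, "Z"))
  mj <- vapply(built, function(b) ncol(b$Z), integer(1))
  iend <- cumsum(mj)
  istart <- iend - mj + 1L
  Gs <- lapply(built, `[[`, "G")
  As <- lapply(built, function(b) b$G %*% b$M0 %*% b$G)
  sel <- integer(mstop)
  risk <- numeric(mstop) # SSE after each iteration
  reduction <- numeric(mstop)
  track <- !is.null(Zte)
  if (track) {
    pte <- rep(offset, length(yte))
    grid_risk <- rep(NA_real_, length(grid))
  }
  sse <- sum((y - fhat)^2)
  for (it in seq_len(mstop)) {
    u <- y - fhat
    call <- crossprod(Zall, u)
    best <- 1L
    best_red <- -Inf
    for (j in seq_len(J)) {
      cj <- call[istart[j]:iend[j]]
      red <- 2 * sum(cj * (Gs[[j]] %*% cj)) - sum(cj * (As[[j]] %*% cj))
      if (red > best_red + 1e-12) {
        best_red <- red
        best <- j
      }
    }
    cb <- call[istart[best]:iend[best]]
    bj <- as.vector(Gs[[best]] %*% cb)
    fhat <- fhat + nu * as.vector(built[[best]]$Z %*% bj)
    coefs[[best]] <- coefs[[best]] + nu * bj
    sel[it] <- best
    new_sse <- sum((y - fhat)^2)
    reduction[it] <- sse - new_sse
    sse <- new_sse
    risk[it] <- sse
    if (track) {
      pte <- pte + nu * as.vector(Zte[[best]] %*% bj)
      hit <- which(grid == it)
      if (length(hit)) grid_risk[hit] <- mean((yte - pte)^2)
    }
  }
  out <- list(offset = offset, coefs = coefs, sel = sel, risk = risk,
              reduction = reduction, fitted = fhat)
  if (track) out$grid_risk <- grid_risk
  out
}

#' Fit a component-wise boosted additive model
#'
#' Gaussian (L2) loss. The offset is the response mean; each iteration
#' fits all base learners to the residuals by penalised least squares and
#' updates the one with the smallest residual sum of squares by a step of
#' length `nu`. Ties break in favour of the earlier learner in `learners`.
#' The fit is deterministic given its inputs.
#'
#' @param data Data frame of predictors (no missing values).
#' @param y Numeric response.
#' @param learners List of specifications from [bl_spline()],
#'   [bl_linear()], [bl_ridge()].
#' @param nu Step length, default 0.1.
#' @param mstop Number of boosting iterations (>= 0).
#' @return A list of class `boost_fit`: `offset`, `coefs` (aggregated
#'   coefficients per learner), `selections`, `risk` (in-sample SSE path,
#'   non-increasing), `reduction` (per-iteration risk reduction),
#'   `fitted`, `nu`, `mstop`, `learner_names`.
#' @examples
#' d <- data.frame(x = seq(0, 1, length.out = 50))
#' y <- sin(2 * pi * d$x) + rnorm(50, 0, 0.1)
#' fit <- fit_boosted_gam(d, y, list(bl_spline("x")), mstop = 50)
#' plot(d$x, predict(fit, d))
#' @export
fit_boosted_gam <- function(data, y, learners, nu = 0.1, mstop = 100L) {
  if (mstop < 0) stop("`mstop` must be >= 0", call. = FALSE)
  assert_number(nu, "nu", lower = 1e-9, upper = 1)
  if (!all(is.finite(y))) stop("missing values in `y`", call. = FALSE)
  built <- lapply(learners, build_learner, data = data)
  core <- boost_core(built, y, nu, as.integer(mstop))
  structure(list(
    offset = core$offset,
    coefs = core$coefs,
    selections = core$sel,
    risk = core$risk,
    reduction = core$reduction,
    fitted = core$fitted,
    nu = nu, mstop = as.integer(mstop),
    learner_names = vapply(built, `[[`, character(1), "name"),
    learner_kinds = vapply(built, `[[`, character(1), "kind"),
    built = lapply(built, function(b) b[c("newdesign", "kind", "name")])
  ), class = "boost_fit")
}

#' Predict from a boosted additive model
#'
#' Sum of the offset and the aggregated learner contributions evaluated at
#' the new data. With `fixed_only = TRUE` the categorical ridge (random
#' factor) learners are excluded, giving fixed-effects-only predictions.
#' Unseen factor levels contribute zero.
#'
#' @param object A `boost_fit`.
#' @param newdata Data frame with the predictor columns.
#' @param fixed_only Exclude ridge learners, default `FALSE`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.boost_fit <- function(object, newdata, fixed_only = FALSE, ...) {
  out <- rep(object$offset, nrow(newdata))
  for (j in seq_along(object$built)) {
    if (fixed_only && object$built[[j]]$kind == "ridge") next
    cf <- object$coefs[[j]]
    if (all(cf == 0)) next
    out <- out + as.vector(object$built[[j]]$newdesign(newdata) %*% cf)
  }
  out
}

#' Relative importance of the base learners
#'
#' Per learner, the total in-sample risk reduction accumulated over the
#' iterations in which it was selected, normalised to sum to one.
#'
#' @param fit A `boost_fit`.
#' @return Data frame `learner`, `reduction`, `share`, sorted by share
#'   (empty for `mstop = 0`).
#' @export
variable_importance <- function(fit) {
  if (fit$mstop == 0L) {
    return(data.frame(learner = character(0), reduction = numeric(0),
                      share = numeric(0)))
  }
  red <- vapply(seq_along(fit$learner_names), function(j) {
    sum(fit$reduction[fit$selections == j])
  }, numeric(1))
  total <- sum(red)
  share <- if (total > 0) red / total else rep(0, length(red))
  out <- data.frame(learner = fit$learner_names, reduction = red,
                    share = share)
  out[order(-out$share), ]
}

#' Select the stopping iteration by bootstrap cross-validation
#'
#' Draws `B` bootstrap resamples, fits the boosting path on each in-bag
#' set up to `max(grid)` iterations, evaluates squared-error risk on the
#' out-of-bag plots along the path, and returns the grid point with the
#' smallest risk averaged over resamples (smallest iteration on ties).
#' An empty out-of-bag set is redrawn.
#'
#' @inheritParams fit_boosted_gam
#' @param grid Candidate `mstop` values, default 10 to 500 in steps of 10.
#' @param B Number of bootstrap resamples, default 25.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A list of class `cv_mstop`: `mstop` (selected), `grid`,
#'   `risk` (mean out-of-bag risk per grid point), `risk_matrix` (B x
#'   grid).
#' @export
cv_mstop <- function(data, y, learners, nu = 0.1,
                     grid = seq(10L, 500L, by = 10L), B = 25L, seed = 1L) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  assert_count(B, "B")
  grid <- sort(unique(as.integer(grid)))
  mmax <- max(grid)
  n <- length(y)
  risk_mat <- matrix(NA_real_, B, length(grid))
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        inbag <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(inbag))
        if (length(oob) > 0L) break
      }
      dtr <- data[inbag, , drop = FALSE]
      dte <- data[oob, , drop = FALSE]
      built <- lapply(learners, build_learner, data = dtr)
      Zte <- lapply(built, function(bl) bl$newdesign(dte))
      core <- boost_core(built, y[inbag], nu, mmax, Zte = Zte,
                         yte = y[oob], grid = grid)
      risk_mat[b, ] <- core$grid_risk
    }
  })
  mean_risk <- colMeans(risk_mat)
  structure(list(mstop = grid[which.min(mean_risk)], grid = grid,
                 risk = mean_risk, risk_matrix = risk_mat),
            class = "cv_mstop")
}
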