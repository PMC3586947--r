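# Polynomial and cubic-spline regression model fitting indices (R^2) as
# pairwise association measures. The R^2 of regressing gene j on gene i is in
# general different from the reverse direction; the resulting non-symmetric
# matrix is symmetrized by entry-wise min, average, or max.

#' Positive part ("hockey stick") function
#'
#' `max(s, 0)`, applied component-wise.
#'
#' @param s Numeric vector.
#' @return Non-negative vector.
#' @export
hockey_stick <- function(s) pmax(s, 0)

#' Rule-of-thumb knot count for spline regression
#'
#' 5 knots when m > 100, 3 knots when m < 30, otherwise 4.
#'
#' @param m Number of samples, at least 10.
#' @return Integer knot count.
#' @export
auto_knot_count <- function(m) {
  if (m < 10) stop("need m >= 10 samples for spline regression")
  if (m > 100) 5L else if (m < 30) 3L else 4L
}

# Interior knots at equally spaced quantiles of x, e.g. 3 knots at the
# 25/50/75% quantiles. Duplicate placements (heavily tied x) reduce the knot
# count with a warning; knots must remain strictly inside the range of x.
.place_knots <- function(x, n_knots) {
  k <- stats::quantile(x, probs = seq_len(n_knots) / (n_knots + 1),
                       names = FALSE)
  k <- k[k > min(x) & k < max(x)]
  k <- unique(k)
  if (length(k) < n_knots)
    warning("reduced knot count to ", length(k),
            " (duplicate or boundary quantile placements)")
  if (!length(k)) stop("no valid interior knots can be placed")
  k
}

# Least squares of y on design matrix M via QR, rank-aware. R^2 is the
# squared correlation of y with the fitted values, defined as 0 when either
# is constant (a constant fit explains no variation).
.fit_ls <- function(M, y) {
  qrm <- qr(M)
  Q <- qr.Q(qrm)[, seq_len(qrm$rank), drop = FALSE]
  fitted <- drop(Q %*% crossprod(Q, y))
  coef <- qr.coef(qrm, y)
  coef[is.na(coef)] <- 0
  r2 <- if (stats::sd(fitted) == 0 || stats::sd(y) == 0) 0
        else min(max(stats::cor(y, fitted)^2, 0), 1)
  list(r_squared = r2, coefficients = unname(coef), fitted = fitted)
}

#' Polynomial regression fit and R-squared
#'
#' Regresses `y` on the design `[1, x, ..., x^degree]` by least squares and
#' reports the fitting index R^2 = cor(y, fitted)^2.
#'
#' @param x,y Numeric vectors of equal length; `x` non-constant.
#' @param degree Polynomial degree, at least 1 (default 3).
#' @return List with `r_squared`, `coefficients`, `fitted`.
#' @export
fit_poly <- function(x, y, degree = 3) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (degree < 1) stop("degree must be at least 1")
  if (max(x) == min(x)) stop("degenerate input: constant predictor")
  .fit_ls(outer(x, 0:degree, `^`), y)
}

#' Cubic spline regression fit and R-squared
#'
#' Truncated-power cubic basis: `[1, x, x^2, x^3, (x - knot_1)+^3, ...]` with
#' interior knots at equally spaced quantiles of `x` (or user-supplied knot
#' values). With `n_knots = "auto"` the knot count follows
#' [auto_knot_count()]. Zero knots reduce exactly to [fit_poly()] with
#' degree 3.
#'
#' @inheritParams fit_poly
#' @param n_knots Number of knots, `"auto"`, or 0 for a plain cubic.
#' @param knots Optional explicit knot values (overrides `n_knots`), strictly
#'   inside the range of `x`.
#' @return List with `r_squared`, `coefficients`, `fitted`.
#' @export
fit_spline <- function(x, y, n_knots = "auto", knots = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (max(x) == min(x)) stop("degenerate input: constant predictor")
  if (is.null(knots)) {
    if (identical(n_knots, "auto")) n_knots <- auto_knot_count(length(x))
    knots <- if (n_knots == 0) numeric(0) else .place_knots(x, n_knots)
  } else {
    if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
    if (any(knots <= min(x) | knots >= max(x)))
      stop("knots must lie strictly inside the range of x")
  }
  M <- outer(x, 0:3, `^`)
  for (k in knots) M <- cbind(M, hockey_stick(x - k)^3)
  .fit_ls(M, y)
}

#' Pairwise regression R-squared association matrix
#'
#' Entry (i, j) is the R^2 of regressing gene j on gene i; entry (j, i) the
#' reverse. The matrix is in general non-symmetric; use [symmetrize()] to
#' obtain an adjacency. For each predictor gene the orthonormal basis of its
#' design matrix is computed once and all targets are fitted in a single
#' matrix product, which reproduces the looped pairwise fits exactly.
#'
#' @param expr Validated expression matrix (genes x samples).
#' @param model `"poly"` or `"spline"`.
#' @param degree Polynomial degree (poly model), default 3.
#' @param n_knots Spline knot count or `"auto"` (spline model).
#' @return Matrix with entries in \[0, 1\] and unit diagonal; attribute
#'   `measure` records the model.
#' @export
r2_matrix <- function(expr, model = c("poly", "spline"), degree = 3,
                      n_knots = "auto") {
  model <- match.arg(model)
  expr <- validate_expression(expr)
  rng <- apply(expr, 1, function(x) max(x) - min(x))
  if (any(rng == 0))
    stop("constant gene rows: ", paste(rownames(expr)[rng == 0], collapse = ", "))
  n <- nrow(expr)
  Y <- t(expr)                       # samples x genes (targets)
  Yc <- sweep(Y, 2, colMeans(Y))
  ssy <- colSums(Yc^2)
  R2 <- matrix(1, n, n)
  for (i in seq_len(n)) {
    x <- expr[i, ]
    M <- if (model == "poly") {
      outer(x, 0:degree, `^`)
    } else {
      nk <- if (identical(n_knots, "auto")) auto_knot_count(length(x)) else n_knots
      Mi <- outer(x, 0:3, `^`)
      if (nk > 0) for (k in .place_knots(x, nk)) Mi <- cbind(Mi, hockey_stick(x - k)^3)
      Mi
    }
    qrm <- qr(M)
    Q <- qr.Q(qrm)[, seq_len(qrm$rank), drop = FALSE]
    Fit <- Q %*% crossprod(Q, Y)
    Fc <- sweep(Fit, 2, colMeans(Fit))
    ssf <- colSums(Fc^2)
    r2 <- colSums(Fc * Yc)^2 / (ssf * ssy)
    r2[ssf <= .Machine$double.eps * ssy] <- 0
    R2[i, ] <- r2
  }
  R2[R2 < 0] <- 0
  R2[R2 > 1] <- 1
  diag(R2) <- 1
  dimnames(R2) <- list(rownames(expr), rownames(expr))
  attr(R2, "measure") <- paste0(model, "_r2")
  R2
}

#' Symmetrize a square association matrix
#'
#' Entry-wise `min(S_ij, S_ji)`, `(S_ij + S_ji) / 2`, or `max(S_ij, S_ji)`.
#'
#' @param S Square matrix.
#' @param method `"max"` (default), `"ave"`, or `"min"`.
#' @return Symmetric matrix.
#' @export
symmetrize <- function(S, method = c("max", "ave", "min")) {
  method <- match.arg(method)
  .check_square(S)
  out <- switch(method,
    min = pmin(S, t(S)),
    ave = (S + t(S)) / 2,
    max = pmax(S, t(S)))
  attr(out, "measure") <- attr(S, "measure")
  out
}
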