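# Correlation-type association measures: Pearson, Spearman, and the biweight
# midcorrelation (bicor), plus asymptotic p-values and the z-score screen for
# pairs where correlation and mutual information disagree.

.check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: constant vector")
  invisible(NULL)
}

#' Pearson product-moment correlation of two vectors
#'
#' @param x,y Numeric vectors of equal length (at least 3), non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  .check_pair(x, y)
  stats::cor(x, y)
}

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks; ties receive the average rank.
#'
#' @inheritParams pearson_cor
#' @return Correlation in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  .check_pair(x, y)
  stats::cor(x, y, method = "spearman")
}

# Internal workhorse: the weighted, median-centred, normalised vector whose
# cross-products give bicor. Weights use Tukey's biweight on
# u = (x - med(x)) / (9 mad(x)) with the unscaled mad; a point with
# |u| >= 1 (i.e. further than 9 mad from the median) gets weight 0.
# max_p_outliers caps, per side of the median, the proportion of points that
# can receive weight 0: u on each side is rescaled by the magnitude of its
# max_p_outliers-quantile whenever that magnitude exceeds 1.
# If mad(x) = 0 but sd(x) > 0 the vector falls back to Pearson-style terms
# (mean-centred, unit weights); a fully constant vector is an error.
.bicor_prep <- function(x, max_p_outliers = 0.02) {
  med <- stats::median(x)
  madx <- stats::median(abs(x - med))
  if (madx == 0) {
    if (stats::sd(x) == 0)
      stop("degenerate input: constant vector (mad = 0 and sd = 0)")
    xt <- x - mean(x)
    return(xt / sqrt(sum(xt^2)))
  }
  u <- (x - med) / (9 * madx)
  qlo <- stats::quantile(u, probs = max_p_outliers, names = FALSE)
  qhi <- stats::quantile(u, probs = 1 - max_p_outliers, names = FALSE)
  neg <- u < 0; pos <- u > 0
  u[neg] <- u[neg] / max(1, abs(qlo))
  u[pos] <- u[pos] / max(1, abs(qhi))
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - med) * w
  nrm <- sqrt(sum(xt^2))
  if (nrm == 0) stop("degenerate input: all weights zero")
  xt / nrm
}

#' Biweight midcorrelation (bicor)
#'
#' Robust correlation based on median centring and Tukey biweight
#' down-weighting: points further than 9 unscaled median absolute deviations
#' from the median receive weight zero. The `max_p_outliers` cap limits the
#' proportion of observations per side of the median that may be assigned
#' zero weight (default 0.02).
#'
#' @inheritParams pearson_cor
#' @param max_p_outliers Maximum proportion of zero-weight outliers per side
#'   of the median, in (0, 0.5].
#' @return Correlation in \[-1, 1\].
#' @export
bicor <- function(x, y, max_p_outliers = 0.02) {
  if (!(max_p_outliers > 0 && max_p_outliers <= 0.5))
    stop("max_p_outliers must lie in (0, 0.5]")
  .check_pair(x, y)
  r <- sum(.bicor_prep(x, max_p_outliers) * .bicor_prep(y, max_p_outliers))
  min(max(r, -1), 1)
}

#' Pairwise correlation matrix over all gene rows
#'
#' Computes the n x n matrix of pairwise correlations between gene expression
#' profiles (rows). Entry (i, j) equals the corresponding pairwise call;
#' bicor is computed via normalised weighted cross-products, which is exactly
#' the pairwise formula because the biweight weights depend only on the
#' vector's own median and mad.
#'
#' @param expr Validated expression matrix (genes x samples).
#' @param method One of `"pearson"`, `"spearman"`, `"bicor"`.
#' @param max_p_outliers Outlier cap for bicor, see [bicor()].
#' @return Symmetric matrix with unit diagonal; attribute `measure` records
#'   the method and `signed` is `TRUE`.
#' @export
cor_matrix <- function(expr, method = c("pearson", "spearman", "bicor"),
                       max_p_outliers = 0.02) {
  method <- match.arg(method)
  expr <- validate_expression(expr)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene rows: ", paste(rownames(expr)[sds == 0], collapse = ", "))
  C <- switch(method,
    pearson  = stats::cor(t(expr)),
    spearman = stats::cor(t(expr), method = "spearman"),
    bicor    = {
      B <- t(apply(expr, 1, .bicor_prep, max_p_outliers = max_p_outliers))
      tcrossprod(B)
    })
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(rownames(expr), rownames(expr))
  attr(C, "measure") <- method
  attr(C, "signed") <- TRUE
  C
}

#' Two-sided asymptotic p-value for a correlation coefficient
#'
#' Uses the Student-t transform `t = r * sqrt((m - 2) / (1 - r^2))` with
#' m - 2 degrees of freedom.
#'
#' @param r Correlation in \[-1, 1\].
#' @param m Number of samples, at least 4.
#' @return p-value in \[0, 1\]; 0 when |r| = 1.
#' @export
cor_pvalue <- function(r, m) {
  if (m < 4) stop("need m >= 4 samples")
  if (abs(r) > 1) stop("correlation must lie in [-1, 1]")
  ifelse(abs(r) == 1, 0, {
    t <- r * sqrt((m - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = m - 2)
  })
}

#' Screen for pairs where correlation and MI adjacency disagree
#'
#' Standardizes |cor| and the MI adjacency over all upper-triangle pairs into
#' z-scores, then returns (a) the pair maximizing the MI z-score among pairs
#' whose correlation z-score is below `z_threshold`, and (b) the pair
#' maximizing the correlation z-score among pairs whose MI z-score is below
#' `z_threshold`. Ties are broken lexicographically by (id_a, id_b).
#'
#' @param cor_mat Signed correlation matrix (as from [cor_matrix()]).
#' @param mi_adj MI-based adjacency with the same ids in the same order.
#' @param z_threshold Significance cutoff on the competing z-score
#'   (default 1.9).
#' @return Data frame with one row per screen direction (`type` is
#'   `"mi_not_cor"` or `"cor_not_mi"`; zero rows for a direction when no pair
#'   satisfies its constraint) and columns `id_a`, `id_b`, `z_cor`, `z_mi`,
#'   `cor_value`, `mi_adjacency_value`.
#' @export
discordance_screen <- function(cor_mat, mi_adj, z_threshold = 1.9) {
  .check_square(cor_mat, "correlation matrix")
  .check_square(mi_adj, "MI adjacency")
  if (nrow(cor_mat) < 2) stop("need at least 2 genes")
  if (!identical(dim(cor_mat), dim(mi_adj)) ||
      !identical(rownames(cor_mat), rownames(mi_adj)))
    stop("matrices must share ids and ordering")
  ids <- rownames(cor_mat)
  ut <- which(upper.tri(cor_mat), arr.ind = TRUE)
  a <- abs(cor_mat[upper.tri(cor_mat)])
  b <- mi_adj[upper.tri(mi_adj)]
  z_cor <- (a - mean(a)) / stats::sd(a)
  z_mi <- (b - mean(b)) / stats::sd(b)
  pick <- function(score, constraint) {
    cand <- which(constraint)
    if (!length(cand)) return(integer(0))
    best <- cand[score[cand] == max(score[cand])]
    if (length(best) > 1) {
      key <- order(ids[ut[best, 1]], ids[ut[best, 2]])
      best <- best[key[1]]
    }
    best
  }
  rows <- list(
    mi_not_cor = pick(z_mi, z_cor < z_threshold),
    cor_not_mi = pick(z_cor, z_mi < z_threshold))
  out <- do.call(rbind, lapply(names(rows), function(ty) {
    k <- rows[[ty]]
    if (!length(k)) return(NULL)
    data.frame(type = ty, id_a = ids[ut[k, 1]], id_b = ids[ut[k, 2]],
               z_cor = z_cor[k], z_mi = z_mi[k], cor_value = cor_mat[ut[k, , drop = FALSE]],
               mi_adjacency_value = mi_adj[ut[k, , drop = FALSE]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(type = character(0), id_a = character(0),
                      id_b = character(0), z_cor = numeric(0), z_mi = numeric(0),
                      cor_value = numeric(0), mi_adjacency_value = numeric(0))
  rownames(out) <- NULL
  out
}
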