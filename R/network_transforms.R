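# Turning association matrices into adjacencies: hard thresholding, soft
# (power) thresholding in signed and unsigned flavours, the general
# bounds-rescaling construction, and the topological overlap transformation.

#' Hard-threshold (unweighted) adjacency
#'
#' `A_ij = 1` if the similarity is at least `tau` (inclusive), else 0;
#' diagonal 1.
#'
#' @param sim Similarity matrix with entries in \[0, 1\].
#' @param tau Hard threshold in \[0, 1\].
#' @return Binary adjacency matrix.
#' @export
hard_threshold <- function(sim, tau) {
  .check_square(sim, "similarity matrix")
  if (min(sim) < 0 || max(sim) > 1) stop("similarities must lie in [0, 1]")
  A <- (sim >= tau) * 1
  diag(A) <- 1
  A
}

#' Soft-threshold (weighted) adjacency from a signed correlation matrix
#'
#' Unsigned: `|cor|^beta` (default beta 6); signed:
#' `(0.5 + 0.5 cor)^beta` (default beta 12). In a signed network strongly
#' negatively correlated genes are treated as unconnected; in an unsigned
#' network they are as connected as strongly positively correlated ones.
#'
#' @param cor_mat Correlation matrix with entries in \[-1, 1\].
#' @param type `"unsigned"` or `"signed"`.
#' @param beta Soft-threshold power, at least 1; defaults 6 (unsigned) or
#'   12 (signed).
#' @return Adjacency matrix with unit diagonal.
#' @export
soft_adjacency <- function(cor_mat, type = c("unsigned", "signed"),
                           beta = NULL) {
  type <- match.arg(type)
  .check_square(cor_mat, "correlation matrix")
  if (min(cor_mat) < -1 || max(cor_mat) > 1)
    stop("correlations must lie in [-1, 1]")
  if (is.null(beta)) beta <- if (type == "signed") 12 else 6
  if (beta < 1) stop("beta must be at least 1")
  A <- if (type == "signed") (0.5 + 0.5 * cor_mat)^beta else abs(cor_mat)^beta
  diag(A) <- 1
  A
}

#' General bounds-rescaling adjacency
#'
#' `A = ((S - lower) / (upper - lower))^beta` entry-wise, then unit diagonal.
#' With lower -1, upper 1 this reproduces the signed soft adjacency exactly;
#' with lower 0, upper `(H_i + H_j) / 2` and beta 1 it reproduces the
#' symmetric-uncertainty MI adjacency.
#'
#' @param S Symmetric association matrix.
#' @param lower,upper Scalar or matrix bounds with `lower < upper` everywhere.
#' @param beta Power, at least 1 (default 1).
#' @return Adjacency matrix clamped into \[0, 1\] with unit diagonal.
#' @export
rescale_adjacency <- function(S, lower, upper, beta = 1) {
  .check_square(S)
  rng <- upper - lower
  if (any(rng <= 0)) stop("upper bound must exceed lower bound everywhere")
  A <- ((S - lower) / rng)
  A[A < 0] <- 0
  A[A > 1] <- 1
  A <- A^beta
  diag(A) <- 1
  A
}

#' Topological overlap matrix (TOM) transformation
#'
#' Replaces each adjacency by a measure of shared-neighbour overlap:
#' `TOM_ij = (sum_{l != i,j} A_il A_lj + A_ij) /
#' (min(k_i, k_j) - A_ij + 1)` with `k_i = sum_{l != i} A_il`. The shared
#' neighbour sums are evaluated with one matrix product (the naive triple
#' loop is the test oracle); the diagonal is 1 and the output satisfies the
#' adjacency axioms.
#'
#' @param adj Adjacency matrix (validated against the axioms).
#' @return TOM adjacency matrix.
#' @export
tom <- function(adj) {
  adj <- validate_adjacency(adj)
  k <- rowSums(adj) - 1               # sum over l != i (diag is 1)
  L <- adj %*% adj - 2 * adj          # subtract l = i and l = j terms (A_ii = A_jj = 1)
  num <- L + adj
  den <- outer(k, k, pmin) - adj + 1
  T <- num / den
  diag(T) <- 1
  T[T < 0] <- 0
  T[T > 1] <- 1
  T <- (T + t(T)) / 2
  dimnames(T) <- dimnames(adj)
  T
}
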