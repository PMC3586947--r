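# Entropy-normalized mutual information adjacencies (symmetric uncertainty
# and the two "universal" versions) and the empirical cor-MI function that
# predicts the universal version 2 adjacency from a correlation coefficient.

.mi_entropies <- function(mi, entropies) {
  if (is.null(entropies)) entropies <- attr(mi, "entropies")
  if (is.null(entropies))
    stop("per-gene entropies required (pass them or use a mi_matrix() result)")
  if (length(entropies) != nrow(mi))
    stop("entropies length must match matrix dimension")
  if (any(entropies <= 0))
    stop("degenerate input: zero-entropy gene(s) ",
         paste(which(entropies <= 0), collapse = ", "))
  entropies
}

.clamp01 <- function(A) {
  A[A < 0] <- 0
  A[A > 1] <- 1
  A
}

#' Symmetric-uncertainty MI adjacency
#'
#' `2 MI_ij / (H_i + H_j)`, the mean-entropy normalization of mutual
#' information. Values are clamped into \[0, 1\] (the Miller-Madow estimator
#' can push the ratio marginally outside) and the diagonal is 1.
#'
#' @param mi Pairwise MI matrix (as from [mi_matrix()]).
#' @param entropies Per-gene entropies; taken from the `entropies` attribute
#'   of `mi` when omitted.
#' @return Adjacency matrix satisfying the adjacency axioms.
#' @export
asu_adjacency <- function(mi, entropies = NULL) {
  .check_square(mi, "MI matrix")
  H <- .mi_entropies(mi, entropies)
  A <- .clamp01(2 * mi / outer(H, H, `+`))
  diag(A) <- 1
  dimnames(A) <- dimnames(mi)
  A
}

#' Universal MI adjacency, version 1
#'
#' The monotone transform `ASU / (2 - ASU)` of the symmetric-uncertainty
#' adjacency; `1 - AUV1` is a universal distance (it satisfies the triangle
#' inequality).
#'
#' @param asu Symmetric-uncertainty adjacency from [asu_adjacency()].
#' @return Adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
auv1_adjacency <- function(asu) {
  .check_square(asu, "ASU adjacency")
  A <- asu / (2 - asu)
  diag(A) <- 1
  A
}

#' Universal MI adjacency, version 2
#'
#' `MI_ij / max(H_i, H_j)`, the max-entropy normalization; `1 - AUV2` is also
#' a universal distance.
#'
#' @inheritParams asu_adjacency
#' @return Adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
auv2_adjacency <- function(mi, entropies = NULL) {
  .check_square(mi, "MI matrix")
  H <- .mi_entropies(mi, entropies)
  A <- .clamp01(mi / outer(H, H, pmax))
  diag(A) <- 1
  dimnames(A) <- dimnames(mi)
  A
}

#' Universal dissimilarity of a universal MI adjacency
#'
#' `1 - A` entry-wise, with zero diagonal.
#'
#' @param adj AUV1 or AUV2 adjacency.
#' @return Dissimilarity matrix in \[0, 1\] with zero diagonal.
#' @export
universal_dissimilarity <- function(adj) {
  .check_square(adj, "adjacency")
  d <- 1 - adj
  diag(d) <- 0
  d
}

#' Parameters of the cor-MI prediction function
#'
#' `omega = 0.43 m^-0.30` and `epsilon = omega^2.2`; the constraint
#' `0 < epsilon <= omega < 1` is asserted.
#'
#' @param m Number of samples, at least 4.
#' @return List with `omega`, `epsilon`, `m`.
#' @export
cor_mi_params <- function(m) {
  if (m < 4) stop("need m >= 4 samples")
  omega <- 0.43 * m^(-0.30)
  epsilon <- omega^2.2
  stopifnot(epsilon > 0, epsilon <= omega, omega < 1)
  list(omega = omega, epsilon = epsilon, m = m)
}

#' The cor-MI function
#'
#' `F(s) = log(1 + epsilon - s^2) / log(epsilon) * (1 - omega) + omega`, a
#' monotonically increasing map of \[0, 1\] onto a subinterval of \[0, 1\] with
#' F(1) = 1. Under bivariate normality with square-root equal-width binning
#' it approximates the universal version 2 MI adjacency of a pair with
#' correlation `s`.
#'
#' @param s Correlation magnitude(s) in \[0, 1\].
#' @param params Parameter list from [cor_mi_params()].
#' @return Predicted adjacency value(s) in \[0, 1\].
#' @export
f_cor_mi <- function(s, params) {
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  eps <- params$epsilon; om <- params$omega
  f <- log(1 + eps - s^2) / log(eps) * (1 - om) + om
  pmin(pmax(f, 0), 1)                  # guard floating-point spill at s = 1
}

#' Predict the AUV2 adjacency from a correlation matrix
#'
#' Applies the cor-MI function to the absolute values of a signed correlation
#' matrix, with parameters derived from the sample count.
#'
#' @param cor_mat Correlation matrix with entries in \[-1, 1\].
#' @param m Number of samples used to compute `cor_mat`.
#' @return Predicted adjacency matrix with unit diagonal.
#' @export
predict_auv2_from_cor <- function(cor_mat, m) {
  .check_square(cor_mat, "correlation matrix")
  if (any(abs(cor_mat) > 1)) stop("correlations must lie in [-1, 1]")
  p <- cor_mi_params(m)
  A <- f_cor_mi(abs(cor_mat), p)
  diag(A) <- 1
  A
}
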