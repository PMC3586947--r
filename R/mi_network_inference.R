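# Mutual-information network inference: RELNET (thresholding), CLR
# (row-background z-scores), MRNET (maximum relevance / minimum redundancy
# forward selection), and ARACNE (data processing inequality pruning).

#' RELNET: relevance network thresholding
#'
#' Off-diagonal entries with MI at least `tau` keep their value, the rest are
#' set to 0. The diagonal is untouched.
#'
#' @param mi Symmetric MI matrix.
#' @param tau Threshold (inclusive retention), default 0.
#' @return Thresholded association matrix.
#' @export
relnet <- function(mi, tau = 0) {
  .check_square(mi, "MI matrix")
  out <- mi
  off <- row(mi) != col(mi)
  out[off & mi < tau] <- 0
  out
}

#' CLR: context likelihood of relatedness
#'
#' For each pair (i, j), `z_i = max(0, (MI_ij - mu_i) / sigma_i)` where
#' `mu_i`, `sigma_i` are the mean and standard deviation of row i's
#' off-diagonal MI values (its empirical background); the pair score is
#' `sqrt(z_i^2 + z_j^2)`. A zero-variance row contributes z = 0 with a
#' warning.
#'
#' @param mi Symmetric MI matrix with at least 3 genes.
#' @return Symmetric score matrix with zero diagonal.
#' @export
clr <- function(mi) {
  .check_square(mi, "MI matrix")
  n <- nrow(mi)
  if (n < 3) stop("CLR needs at least 3 genes")
  off <- mi
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sig <- apply(off, 1, stats::sd, na.rm = TRUE)
  zero <- sig == 0
  if (any(zero)) {
    warning("zero-variance row(s) in CLR background: ",
            paste(which(zero), collapse = ", "), "; their z set to 0")
    sig[zero] <- Inf
  }
  Z <- (mi - mu) / sig                # row-wise: Z[i, j] uses row i background
  Z[Z < 0] <- 0
  out <- sqrt(Z^2 + t(Z)^2)
  diag(out) <- 0
  dimnames(out) <- dimnames(mi)
  out
}

#' MRNET: maximum relevance / minimum redundancy network
#'
#' For each target gene a full MRMR forward-selection ordering of the other
#' genes is computed: the first predictor maximizes MI with the target and is
#' scored by that MI; each later predictor maximizes relevance minus
#' redundancy, `MI(x_k, y) - mean_{x in S} MI(x_k, x)` over the already
#' selected set S, and is scored by that criterion at entry. The final pair
#' score is the maximum of the two directional scores, floored at 0.
#' Argmax ties break toward the lowest gene index.
#'
#' @param mi Symmetric MI matrix with at least 2 genes.
#' @return Symmetric non-negative score matrix with zero diagonal.
#' @export
mrnet <- function(mi) {
  .check_square(mi, "MI matrix")
  n <- nrow(mi)
  if (n < 2) stop("MRNET needs at least 2 genes")
  D <- matrix(0, n, n)                 # D[k, t] = score of k when t is target
  for (t in seq_len(n)) {
    red <- numeric(n)                  # running sum of MI to the selected set
    cand <- rep(TRUE, n)
    cand[t] <- FALSE
    selected <- 0L
    while (any(cand)) {
      idx <- which(cand)
      score <- if (selected == 0L) mi[idx, t] else mi[idx, t] - red[idx] / selected
      w <- which.max(score)            # first max: ties break to lowest index
      k <- idx[w]
      D[k, t] <- score[w]
      cand[k] <- FALSE
      selected <- selected + 1L
      red <- red + mi[, k]
    }
  }
  out <- pmax(pmax(D, t(D)), 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(mi)
  out
}

#' ARACNE: data processing inequality pruning
#'
#' Starts from the graph of edges with MI strictly above `tau`. Every triplet
#' of surviving edges is then examined against the original post-threshold
#' matrix: edge (i, j) is flagged when
#' `MI_ij <= min(MI_ik, MI_kj) - dpi_tolerance` for some k, and all flagged
#' edges are removed simultaneously after the full scan (order-independent).
#' Surviving edges keep their MI value.
#'
#' @param mi Symmetric MI matrix.
#' @param tau Initial edge threshold (edges with MI <= tau are removed
#'   first), default 0.
#' @param dpi_tolerance The DPI tolerance in \[0, 1\]; larger values preserve
#'   more edges. Default 0.
#' @return Pruned association matrix (diagonal untouched).
#' @export
aracne <- function(mi, tau = 0, dpi_tolerance = 0) {
  .check_square(mi, "MI matrix")
  if (dpi_tolerance < 0 || dpi_tolerance > 1)
    stop("dpi_tolerance must lie in [0, 1]")
  n <- nrow(mi)
  present <- mi > tau
  diag(present) <- FALSE
  flagged <- matrix(FALSE, n, n)
  for (k in seq_len(n)) {
    pk <- present[, k]
    if (sum(pk) < 2) next
    a <- mi[, k]
    minik <- outer(a, a, pmin)         # min(MI_ik, MI_kj) at (i, j)
    both <- outer(pk, pk, `&`)
    flagged <- flagged | (present & both & (mi <= minik - dpi_tolerance))
  }
  out <- mi
  off <- row(mi) != col(mi)
  out[off & (!present | flagged)] <- 0
  out
}

#' Rescale an inferred association matrix into an adjacency
#'
#' Bounds rescaling with lower bound 0, upper bound the maximum off-diagonal
#' entry, and power 1; the diagonal is set to 1.
#'
#' @param S Symmetric non-negative association matrix.
#' @return Adjacency matrix.
#' @export
inferred_to_adjacency <- function(S) {
  .check_square(S)
  if (min(S) < 0) stop("association matrix must be non-negative")
  off <- S[row(S) != col(S)]
  mx <- max(off)
  if (mx == 0) stop("all off-diagonal entries are zero; cannot rescale")
  A <- S / mx
  A[A > 1] <- 1
  diag(A) <- 1
  A
}
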