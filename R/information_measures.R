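# Discretization, entropy (plug-in and Miller-Madow), mutual information and
# the likelihood-ratio-test identity MI = LRT / (2m). All entropies and MI
# values are in nats (natural logarithm).

#' Default number of equal-width bins
#'
#' The square-root rule: `round(sqrt(m))`, rounded half away from zero, with
#' a floor of 2.
#'
#' @param m Number of samples, at least 4.
#' @return Integer number of bins.
#' @export
default_n_bins <- function(m) {
  if (m < 4) stop("need m >= 4 samples")
  max(2L, as.integer(floor(sqrt(m) + 0.5)))
}

#' Equal-width discretization of a numeric vector
#'
#' Partitions `[min(x), max(x)]` into `n_bins` bins of equal width. Bins are
#' right-open except the last, which is closed so that `max(x)` is assigned.
#'
#' @param x Numeric vector, non-constant.
#' @param n_bins Number of bins, at least 2.
#' @return List of class `"discretized"` with components `bins` (integer
#'   vector in 1..n_bins), `n_bins`, and `bin_edges` (length n_bins + 1).
#' @export
equal_width_discretize <- function(x, n_bins) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  lo <- min(x); hi <- max(x)
  if (lo == hi) stop("degenerate input: constant vector cannot be discretized")
  w <- (hi - lo) / n_bins
  bins <- floor((x - lo) / w) + 1L
  bins <- pmin.int(pmax.int(bins, 1L), as.integer(n_bins))
  structure(list(bins = as.integer(bins), n_bins = as.integer(n_bins),
                 bin_edges = lo + w * (0:n_bins)),
            class = "discretized")
}

.as_bins <- function(dx) {
  if (inherits(dx, "discretized")) return(dx)
  bins <- as.integer(dx)
  if (any(bins < 1)) stop("bin labels must be positive integers")
  structure(list(bins = bins, n_bins = max(bins), bin_edges = NULL),
            class = "discretized")
}

# Entropy of a count vector, in nats. Empty cells contribute 0; the
# Miller-Madow estimator adds (number of non-empty cells - 1) / (2m).
.entropy_counts <- function(counts, m, estimator) {
  p <- counts[counts > 0] / m
  h <- -sum(p * log(p))
  if (estimator == "miller_madow") h <- h + (length(p) - 1) / (2 * m)
  list(value = h, n_nonempty = length(p))
}

#' Entropy of a discretized vector
#'
#' Plug-in estimator `-sum(p log p)` over bin frequencies, or the Miller-Madow
#' bias-corrected version, plug-in + (B - 1) / (2m) with B the number of
#' non-empty bins.
#'
#' @param dx A `"discretized"` object (or an integer vector of bin labels).
#' @param estimator `"plugin"` or `"miller_madow"`.
#' @return List with `value` (nats), `estimator`, `n_nonempty_bins`.
#' @export
entropy <- function(dx, estimator = c("plugin", "miller_madow")) {
  estimator <- match.arg(estimator)
  dx <- .as_bins(dx)
  m <- length(dx$bins)
  e <- .entropy_counts(tabulate(dx$bins, nbins = dx$n_bins), m, estimator)
  list(value = e$value, estimator = estimator, n_nonempty_bins = e$n_nonempty)
}

# Joint cell counts of two discretized vectors, as a flat vector.
.joint_counts <- function(dx, dy) {
  if (length(dx$bins) != length(dy$bins)) stop("length mismatch")
  tabulate((dx$bins - 1L) * dy$n_bins + dy$bins,
           nbins = dx$n_bins * dy$n_bins)
}

#' Joint entropy of two discretized vectors
#'
#' Entropy of the joint cell distribution; for Miller-Madow the non-empty
#' count B is taken over joint cells.
#'
#' @param dx,dy `"discretized"` objects (or integer bin vectors) of equal
#'   length.
#' @inheritParams entropy
#' @return List with `value`, `estimator`, `n_nonempty_bins`.
#' @export
joint_entropy <- function(dx, dy, estimator = c("plugin", "miller_madow")) {
  estimator <- match.arg(estimator)
  dx <- .as_bins(dx); dy <- .as_bins(dy)
  m <- length(dx$bins)
  e <- .entropy_counts(.joint_counts(dx, dy), m, estimator)
  list(value = e$value, estimator = estimator, n_nonempty_bins = e$n_nonempty)
}

#' Mutual information of two discretized vectors
#'
#' Computed through the entropy identity `MI = H(dx) + H(dy) - H(dx, dy)`
#' with the chosen estimator, clamped at 0 from below. For the plug-in
#' estimator this equals the direct double sum over joint frequencies.
#'
#' @inheritParams joint_entropy
#' @return Mutual information in nats (non-negative).
#' @export
mutual_information <- function(dx, dy, estimator = c("plugin", "miller_madow")) {
  estimator <- match.arg(estimator)
  dx <- .as_bins(dx); dy <- .as_bins(dy)
  hx <- entropy(dx, estimator)$value
  hy <- entropy(dy, estimator)$value
  hxy <- joint_entropy(dx, dy, estimator)$value
  max(hx + hy - hxy, 0)
}

#' Likelihood-ratio (G) statistic of independence
#'
#' Multinomial likelihood-ratio statistic `2 * sum O log(O / E)` on the
#' contingency table of the two discretized vectors. Satisfies
#' `LRT = 2 m MI_plugin` exactly.
#'
#' @inheritParams joint_entropy
#' @return Non-negative statistic.
#' @export
lrt_statistic <- function(dx, dy) {
  dx <- .as_bins(dx); dy <- .as_bins(dy)
  if (length(dx$bins) != length(dy$bins)) stop("length mismatch")
  m <- length(dx$bins)
  O <- matrix(.joint_counts(dx, dy), nrow = dx$n_bins, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / m
  keep <- O > 0
  2 * sum(O[keep] * log(O[keep] / E[keep]))
}

#' Pairwise mutual information matrix over all gene rows
#'
#' Each gene row is discretized with the same equal-width rule, then MI is
#' computed for every pair via the entropy identity. The diagonal holds the
#' per-gene entropy; per-gene entropies, the bin count and the estimator are
#' attached as attributes (`entropies`, `n_bins`, `estimator`) for the MI
#' adjacency constructors.
#'
#' @param expr Validated expression matrix (genes x samples).
#' @param n_bins Number of bins, or `NULL` for the square-root default.
#' @param estimator `"plugin"` or `"miller_madow"` (the default, matching the
#'   estimator used throughout the benchmark comparisons).
#' @return Symmetric non-negative matrix of pairwise MI in nats.
#' @export
mi_matrix <- function(expr, n_bins = NULL,
                      estimator = c("miller_madow", "plugin")) {
  estimator <- match.arg(estimator)
  expr <- validate_expression(expr)
  n <- nrow(expr); m <- ncol(expr)
  if (is.null(n_bins)) n_bins <- default_n_bins(m)
  rng <- apply(expr, 1, function(x) max(x) - min(x))
  if (any(rng == 0))
    stop("constant gene rows: ", paste(rownames(expr)[rng == 0], collapse = ", "))
  D <- matrix(0L, n, m)
  for (i in seq_len(n)) D[i, ] <- equal_width_discretize(expr[i, ], n_bins)$bins
  H <- numeric(n)
  for (i in seq_len(n))
    H[i] <- .entropy_counts(tabulate(D[i, ], nbins = n_bins), m, estimator)$value
  MI <- matrix(0, n, n)
  nb <- as.integer(n_bins)
  for (i in seq_len(n - 1)) {
    di <- (D[i, ] - 1L) * nb
    for (j in (i + 1):n) {
      hxy <- .entropy_counts(tabulate(di + D[j, ], nbins = nb * nb), m, estimator)$value
      MI[i, j] <- MI[j, i] <- max(H[i] + H[j] - hxy, 0)
    }
  }
  diag(MI) <- H
  dimnames(MI) <- list(rownames(expr), rownames(expr))
  attr(MI, "measure") <- "mi"
  attr(MI, "entropies") <- stats::setNames(H, rownames(expr))
  attr(MI, "n_bins") <- nb
  attr(MI, "estimator") <- estimator
  MI
}
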