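# Module detection: average-linkage hierarchical clustering of the
# dissimilarity 1 - A, a deterministic branch cut, and Rand-index agreement
# between partitions. The same clustering settings are applied regardless of
# which association measure produced the adjacency, so that measures are
# compared on an equal footing.

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' @param dissim Symmetric matrix with zero diagonal and entries in \[0, 1\].
#' @return An object of class `hclust` (merge heights are non-decreasing for
#'   average linkage).
#' @export
average_linkage <- function(dissim) {
  .check_square(dissim, "dissimilarity matrix")
  if (max(abs(dissim - t(dissim))) > 1e-8) stop("dissimilarity must be symmetric")
  if (max(abs(diag(dissim))) > 1e-8) stop("dissimilarity must have zero diagonal")
  if (min(dissim) < 0 || max(dissim) > 1 + 1e-12)
    stop("dissimilarities must lie in [0, 1]")
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  # average linkage is monotone; exact ties can leave sub-epsilon height
  # inversions that cutree(h =) rejects, so restore monotonicity
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  hc
}

# Newman-Girvan modularity of a hard partition of a weighted network.
# A0 must have a zero diagonal; S = sum(A0), k = rowSums(A0).
.modularity <- function(A0, labs, S, k) {
  q <- 0
  for (c in unique(labs)) {
    idx <- labs == c
    q <- q + sum(A0[idx, idx]) / S - (sum(k[idx]) / S)^2
  }
  q
}

#' Cut a dendrogram into modules
#'
#' Cuts the tree at `cut_height` and keeps branches with at least
#' `min_module_size` leaves as modules, labeled 1..K in decreasing size
#' order; all other leaves get label 0 (unassigned).
#'
#' With `cut_height = "auto"` the cut height is chosen adaptively, standing
#' in for the dynamic branch-cutting used with such trees. When the
#' `adjacency` that generated the dissimilarity is supplied, every distinct
#' cut height of the tree is scored by the Newman-Girvan modularity of the
#' partition it induces and the best-scoring cut is kept; genes whose mean
#' adjacency to their own module falls below `strip_ratio` times the
#' module's mean internal adjacency are then unassigned (iterated to a fixed
#' point). This picks up branches that join tightly relative to the network
#' background whatever the dynamic range of the measure. Without an
#' adjacency the tree is cut at the midpoint of the largest gap between
#' consecutive merge heights.
#'
#' @param tree An `hclust` object.
#' @param cut_height Numeric height in (0, 1\], or `"auto"`.
#' @param min_module_size Minimum leaves per module (default 20).
#' @param adjacency Optional adjacency matrix (same leaf order as the tree)
#'   enabling the modularity-based auto cut.
#' @param strip_ratio Weak-membership threshold for the cleanup pass
#'   (default 0.5); only used by the modularity-based auto cut.
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
cut_modules <- function(tree, cut_height = "auto", min_module_size = 20,
                        adjacency = NULL, strip_ratio = 0.5) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust object")
  if (identical(cut_height, "auto") && !is.null(adjacency)) {
    labs <- .modularity_cut(tree, adjacency, strip_ratio)
  } else {
    if (identical(cut_height, "auto")) {
      h <- sort(tree$height)
      if (length(h) < 2) {
        cut_height <- max(h)
      } else {
        gaps <- diff(h)
        i <- which.max(gaps)
        cut_height <- (h[i] + h[i + 1]) / 2
      }
    }
    labs <- stats::cutree(tree, h = cut_height)
  }
  sizes <- table(labs[labs != 0])
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  out <- integer(length(labs))
  names(out) <- tree$labels
  if (length(keep)) {
    ord <- keep[order(-sizes[as.character(keep)], keep)]
    for (k in seq_along(ord)) out[labs == ord[k]] <- k
  }
  out
}

# Modularity-maximizing tree cut with weak-member stripping. Returns raw
# cluster labels (possibly including small clusters; size filtering happens
# in the caller).
.modularity_cut <- function(tree, adjacency, strip_ratio) {
  A0 <- adjacency
  diag(A0) <- 0
  S <- sum(A0)
  if (S <= 0) return(seq_len(nrow(A0)))   # empty network: all singletons
  k <- rowSums(A0)
  h <- sort(unique(tree$height))
  cands <- c((h[-length(h)] + h[-1]) / 2, max(h) + 1e-8)
  best <- NULL
  bq <- -Inf
  for (cc in cands) {
    labs <- stats::cutree(tree, h = cc)
    q <- .modularity(A0, labs, S, k)
    if (q > bq) {
      bq <- q
      best <- labs
    }
  }
  labs <- best
  repeat {
    changed <- FALSE
    for (c in unique(labs[labs != 0])) {
      idx <- which(labs == c)
      if (length(idx) < 3) next
      B <- A0[idx, idx]
      within <- mean(B[upper.tri(B)])
      conn <- rowSums(B) / (length(idx) - 1)
      drop <- idx[conn < strip_ratio * within]
      if (length(drop) && length(drop) < length(idx)) {
        labs[drop] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labs
}

#' Rand index between two partitions
#'
#' The unadjusted Rand index: the fraction of the n-choose-2 element pairs on
#' which the partitions agree (both together or both apart). Label 0 is
#' treated as an ordinary label.
#'
#' @param p1,p2 Integer label vectors of equal length (and matching names, if
#'   named).
#' @return Agreement in \[0, 1\].
#' @export
rand_index <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions must have equal length")
  if (!is.null(names(p1)) && !is.null(names(p2)) &&
      !identical(names(p1), names(p2)))
    stop("partitions must share ids and ordering")
  n <- length(p1)
  tab <- table(p1, p2)
  s <- function(x) sum(choose(x, 2))
  (choose(n, 2) + 2 * s(tab) - s(rowSums(tab)) - s(colSums(tab))) / choose(n, 2)
}

#' End-to-end module detection pipeline
#'
#' Composes association measure, adjacency transform (optionally TOM),
#' dissimilarity 1 - A, average-linkage clustering and branch cutting. The
#' clustering and cutting settings are identical for every measure.
#'
#' Available measures: `"bicor-tom"` (signed bicor adjacency, beta 12, then
#' TOM), `"bicor-signed"`, `"bicor-unsigned"`, `"pearson-signed"`, `"auv2"`,
#' `"asu"`, `"auv1"`, `"poly"`, `"spline"`, `"relnet"`, `"clr"`, `"mrnet"`,
#' `"aracne"`.
#'
#' @param expr Validated expression matrix.
#' @param measure Association measure / network construction, see Details.
#' @param beta Soft-threshold power override (defaults 12 signed, 6 unsigned).
#' @param max_p_outliers Bicor outlier cap.
#' @param n_bins Bins for MI-based measures (`NULL` for square-root rule).
#' @param estimator Entropy estimator for MI-based measures.
#' @param degree Polynomial degree.
#' @param n_knots Spline knots or `"auto"`.
#' @param r2_symmetrize Symmetrization for the R^2 matrix (default `"max"`).
#' @param tau RELNET/ARACNE threshold.
#' @param dpi_tolerance ARACNE DPI tolerance.
#' @param cut_height Branch cut height or `"auto"`.
#' @param min_module_size Minimum module size.
#' @return Named integer module labels; the adjacency used is attached as
#'   attribute `"adjacency"` and the settings as `"settings"`.
#' @export
modules_pipeline <- function(expr, measure = c("bicor-tom", "bicor-signed",
                                               "bicor-unsigned", "pearson-signed",
                                               "auv2", "asu", "auv1",
                                               "poly", "spline",
                                               "relnet", "clr", "mrnet", "aracne"),
                             beta = NULL, max_p_outliers = 0.02,
                             n_bins = NULL, estimator = "miller_madow",
                             degree = 3, n_knots = "auto",
                             r2_symmetrize = "max",
                             tau = 0, dpi_tolerance = 0,
                             cut_height = "auto", min_module_size = 20) {
  measure <- match.arg(measure)
  expr <- validate_expression(expr)
  A <- switch(measure,
    "bicor-tom" = tom(soft_adjacency(cor_matrix(expr, "bicor", max_p_outliers),
                                     "signed", beta %||% 12)),
    "bicor-signed" = soft_adjacency(cor_matrix(expr, "bicor", max_p_outliers),
                                    "signed", beta %||% 12),
    "bicor-unsigned" = soft_adjacency(cor_matrix(expr, "bicor", max_p_outliers),
                                      "unsigned", beta %||% 6),
    "pearson-signed" = soft_adjacency(cor_matrix(expr, "pearson"),
                                      "signed", beta %||% 12),
    "auv2" = auv2_adjacency(mi_matrix(expr, n_bins, estimator)),
    "asu" = asu_adjacency(mi_matrix(expr, n_bins, estimator)),
    "auv1" = auv1_adjacency(asu_adjacency(mi_matrix(expr, n_bins, estimator))),
    "poly" = ,
    "spline" = {
      S <- symmetrize(r2_matrix(expr, model = measure, degree = degree,
                                n_knots = n_knots), r2_symmetrize)
      diag(S) <- 1
      S
    },
    "relnet" = inferred_to_adjacency(relnet(mi_matrix(expr, n_bins, estimator), tau)),
    "clr" = inferred_to_adjacency(clr(mi_matrix(expr, n_bins, estimator))),
    "mrnet" = inferred_to_adjacency(mrnet(mi_matrix(expr, n_bins, estimator))),
    "aracne" = inferred_to_adjacency(aracne(mi_matrix(expr, n_bins, estimator),
                                            tau, dpi_tolerance)))
  A <- validate_adjacency(A, tol = 1e-8)
  d <- 1 - A
  diag(d) <- 0
  tree <- average_linkage(d)
  labels <- cut_modules(tree, cut_height, min_module_size, adjacency = A)
  attr(labels, "adjacency") <- A
  attr(labels, "settings") <- list(measure = measure, cut_height = cut_height,
                                   min_module_size = min_module_size,
                                   linkage = "average")
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a
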