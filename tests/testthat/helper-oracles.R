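# Independent brute-force oracles. Each is a deliberately naive, literal
# transcription of the defining formula, kept free of any code path used by
# the package implementation.

# Direct double-sum mutual information over joint frequencies (plug-in).
oracle_mi_direct <- function(bx, by) {
  m <- length(bx)
  mi <- 0
  for (r in unique(bx)) for (c in unique(by)) {
    prc <- sum(bx == r & by == c) / m
    if (prc > 0) {
      pr <- sum(bx == r) / m
      pc <- sum(by == c) / m
      mi <- mi + prc * log(prc / (pr * pc))
    }
  }
  mi
}

# Entry-wise triple-loop topological overlap.
oracle_tom <- function(A) {
  n <- nrow(A)
  T <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- A[i, j]
    for (l in seq_len(n)) if (l != i && l != j) num <- num + A[i, l] * A[l, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    T[i, j] <- num / (min(ki, kj) - A[i, j] + 1)
  }
  T
}

# Per-pair CLR with explicit row background statistics.
oracle_clr <- function(mi) {
  n <- nrow(mi)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    bi <- mi[i, -i]; bj <- mi[j, -j]
    zi <- max(0, (mi[i, j] - mean(bi)) / sd(bi))
    zj <- max(0, (mi[i, j] - mean(bj)) / sd(bj))
    out[i, j] <- sqrt(zi^2 + zj^2)
  }
  out
}

# Literal MRMR forward selection, recomputing the redundancy sum from
# scratch at every step.
oracle_mrnet <- function(mi) {
  n <- nrow(mi)
  D <- matrix(0, n, n)
  for (t in seq_len(n)) {
    S <- integer(0)
    cand <- setdiff(seq_len(n), t)
    while (length(cand)) {
      scores <- sapply(cand, function(k) {
        if (!length(S)) mi[k, t]
        else mi[k, t] - mean(sapply(S, function(s) mi[k, s]))
      })
      w <- which(scores == max(scores))[1]
      D[cand[w], t] <- scores[w]
      S <- c(S, cand[w])
      cand <- cand[-w]
    }
  }
  out <- pmax(D, t(D))
  out[out < 0] <- 0
  diag(out) <- 0
  out
}

# All-triplets DPI scan with simultaneous removal.
oracle_aracne <- function(mi, tau = 0, eps = 0) {
  n <- nrow(mi)
  present <- mi > tau
  diag(present) <- FALSE
  flag <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (length(unique(c(i, j, k))) < 3) next
    if (present[i, j] && present[i, k] && present[k, j] &&
        mi[i, j] <= min(mi[i, k], mi[k, j]) - eps)
      flag[i, j] <- TRUE
  }
  out <- mi
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && (!present[i, j] || flag[i, j])) out[i, j] <- 0
  out
}

# Naive UPGMA agglomeration; returns the sorted merge heights.
oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- mean(d[clusters[[a]], clusters[[b]]])
      if (h < bh) { bh <- h; best <- c(a, b) }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Least squares through the SVD pseudoinverse (Moore-Penrose), reported as
# the squared correlation of y with the fitted values.
oracle_pinv_r2 <- function(M, y) {
  sv <- svd(M)
  keep <- sv$d > max(dim(M)) * .Machine$double.eps * max(sv$d)
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  fitted <- drop(M %*% beta)
  if (sd(fitted) == 0 || sd(y) == 0) return(list(r2 = 0, fitted = fitted))
  list(r2 = cor(y, fitted)^2, fitted = fitted)
}

# Literal transcription of the biweight midcorrelation definition with the
# per-side outlier-proportion cap.
oracle_bicor <- function(x, y, maxp = 0.02) {
  side_scaled_u <- function(v) {
    med <- median(v)
    u <- (v - med) / (9 * median(abs(v - med)))
    qlo <- quantile(u, maxp, names = FALSE)
    qhi <- quantile(u, 1 - maxp, names = FALSE)
    for (i in seq_along(u)) {
      if (u[i] < 0) u[i] <- u[i] / max(1, abs(qlo))
      if (u[i] > 0) u[i] <- u[i] / max(1, abs(qhi))
    }
    u
  }
  wgt <- function(u) {
    w <- numeric(length(u))
    for (i in seq_along(u))
      w[i] <- if (1 - abs(u[i]) > 0) (1 - u[i]^2)^2 else 0
    w
  }
  u <- side_scaled_u(x); v <- side_scaled_u(y)
  wx <- wgt(u); wy <- wgt(v)
  num <- sum((x - median(x)) * wx * (y - median(y)) * wy)
  den <- sqrt(sum(((x - median(x)) * wx)^2)) * sqrt(sum(((y - median(y)) * wy)^2))
  num / den
}

# Random symmetric non-negative "MI-like" matrix with a constant diagonal.
random_mi_matrix <- function(n, scale = 1) {
  M <- matrix(runif(n * n, 0, scale), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- scale
  M
}

# Random valid adjacency matrix.
random_adjacency <- function(n) {
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

# Random pair of discretized vectors (as integer bin labels).
random_bins <- function(m, R) sample.int(R, m, replace = TRUE)

# Small expression matrix with random Gaussian rows.
random_expr <- function(n, m) {
  X <- matrix(rnorm(n * m), n, m)
  dimnames(X) <- list(paste0("g", seq_len(n)), paste0("s", seq_len(m)))
  X
}
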