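test_that("pearson and spearman match their defining formulas", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  # brute-force sum-of-products
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y), num / den)

  expect_equal(spearman_cor(c(1, 2, 3), c(1, 8, 27)), 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(9, 4, 1)), -1)
  # ties: rank-then-pearson oracle
  x <- c(1, 1, 2, 3); y <- c(4, 4, 5, 6)
  expect_equal(spearman_cor(x, y), pearson_cor(rank(x), rank(y)))

  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:3, 1:4), "equal length")
})

test_that("bicor handles exact linear relations and planted outliers", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(bicor(x, 2 * x), 1)
  expect_equal(bicor(x, -x), -1)
  # planted outlier: the literal step-by-step transcription is the oracle
  xo <- c(1, 2, 3, 4, 100); yo <- c(1, 2, 3, 4, 5)
  expect_equal(bicor(xo, yo), oracle_bicor(xo, yo), tolerance = 1e-12)
  # the outlier gets weight 0: u = (100 - 3)/(9 * 1) > 1, so with the
  # per-side cap disabled (max_p_outliers = 0.5, quantile at the median)
  # the value is invariant to the outlier's magnitude
  expect_equal(bicor(xo, yo, max_p_outliers = 0.5),
               bicor(c(1, 2, 3, 4, 1e6), yo, max_p_outliers = 0.5),
               tolerance = 1e-12)
  expect_error(bicor(rep(1, 5), x), "degenerate|constant")
  expect_error(bicor(x, x, max_p_outliers = 0), "max_p_outliers")
})

test_that("bicor equals its literal definition on random data", {
  set.seed(21)
  for (rep in 1:25) {
    m <- sample(10:60, 1)
    x <- rnorm(m); y <- 0.5 * x + rnorm(m)
    if (rep %% 3 == 0) x[1] <- x[1] + 20   # planted outlier
    expect_equal(bicor(x, y), oracle_bicor(x, y), tolerance = 1e-12)
  }
})

test_that("bicor is affine-invariant and sign-equivariant", {
  set.seed(22)
  for (rep in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    r <- bicor(x, y)
    expect_equal(bicor(3 * x + 7, y), r, tolerance = 1e-12)
    expect_equal(bicor(x, 0.1 * y - 2), r, tolerance = 1e-12)
    expect_equal(bicor(-x, y), -r, tolerance = 1e-12)
    expect_gte(r, -1); expect_lte(r, 1)
  }
})

test_that("cor_matrix agrees with looped pairwise calls for all methods", {
  set.seed(23)
  X <- random_expr(5, 40)
  X[2, 1] <- X[2, 1] + 15            # outlier to engage the biweight
  pairwise <- function(fun) {
    n <- nrow(X)
    M <- diag(n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      M[i, j] <- M[j, i] <- fun(X[i, ], X[j, ])
    M
  }
  for (meth in c("pearson", "spearman", "bicor")) {
    fun <- switch(meth, pearson = pearson_cor, spearman = spearman_cor,
                  bicor = bicor)
    C <- cor_matrix(X, meth)
    expect_equal(C, pairwise(fun), tolerance = 1e-10, ignore_attr = TRUE)
    expect_identical(unname(diag(C)), rep(1, 5))
  }
  Xc <- X; Xc[3, ] <- 2
  expect_error(cor_matrix(Xc, "pearson"), "g3")
})

test_that("two identical gene rows give off-diagonal 1 for all methods", {
  set.seed(24)
  X <- rbind(g1 = rnorm(20), g2 = NA)
  X[2, ] <- X[1, ]
  colnames(X) <- paste0("s", 1:20)
  for (meth in c("pearson", "spearman", "bicor"))
    expect_equal(cor_matrix(X, meth)[1, 2], 1, tolerance = 1e-12)
})

test_that("cor_pvalue matches the t test of a correlation", {
  expect_equal(cor_pvalue(0, 10), 1)
  expect_equal(cor_pvalue(1, 10), 0)
  expect_equal(cor_pvalue(-1, 10), 0)
  set.seed(25)
  for (rep in 1:10) {
    m <- sample(10:50, 1)
    x <- rnorm(m); y <- rnorm(m)
    ct <- cor.test(x, y)              # independent oracle
    expect_equal(cor_pvalue(cor(x, y), m), ct$p.value, tolerance = 1e-10)
  }
  expect_error(cor_pvalue(0.5, 3), "m >= 4")
})

test_that("discordance screen finds MI-only and cor-only extreme pairs", {
  set.seed(26)
  m <- 60
  e <- rnorm(m)
  X <- rbind(
    g1 = e + 0.1 * rnorm(m),          # strongly correlated pair (g1, g2)
    g2 = e + 0.1 * rnorm(m),
    g3 = rnorm(m),                    # outlier-driven MI pair (g3, g4)
    g4 = rnorm(m),
    g5 = rnorm(m))
  X[3, 1] <- X[4, 1] <- 40            # shared extreme sample inflates MI
  colnames(X) <- paste0("s", 1:m)
  C <- cor_matrix(X, "bicor")
  A <- auv2_adjacency(mi_matrix(X))
  res <- discordance_screen(C, A, z_threshold = 1.9)
  mi_row <- res[res$type == "mi_not_cor", ]
  expect_identical(sort(c(mi_row$id_a, mi_row$id_b)), c("g3", "g4"))
  cor_row <- res[res$type == "cor_not_mi", ]
  expect_true(nrow(cor_row) <= 1)

  # vacuous constraint reduces the screen to global argmaxes
  inf <- discordance_screen(C, A, z_threshold = Inf)
  ut <- upper.tri(C)
  ids <- rownames(C)
  idx <- which(ut, arr.ind = TRUE)
  best_mi <- which.max(A[ut])
  expect_identical(sort(c(inf$id_a[inf$type == "mi_not_cor"],
                          inf$id_b[inf$type == "mi_not_cor"])),
                   sort(ids[idx[best_mi, ]]))
  best_cor <- which.max(abs(C)[ut])
  expect_identical(sort(c(inf$id_a[inf$type == "cor_not_mi"],
                          inf$id_b[inf$type == "cor_not_mi"])),
                   sort(ids[idx[best_cor, ]]))
  expect_error(discordance_screen(C[1:2, 1:2], A), "ids")
})
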