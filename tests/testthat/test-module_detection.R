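test_that("average linkage reproduces hand-computed and oracle UPGMA trees", {
  # two leaves merge at their dissimilarity
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  hc <- average_linkage(d2)
  expect_equal(hc$height, 0.4)

  # two well-separated pairs: pairs first, then the average cross-dissimilarity
  d4 <- matrix(0.8, 4, 4)
  d4[1, 2] <- d4[2, 1] <- 0.1
  d4[3, 4] <- d4[4, 3] <- 0.2
  diag(d4) <- 0
  hc4 <- average_linkage(d4)
  expect_equal(sort(hc4$height), c(0.1, 0.2, 0.8))

  set.seed(81)
  for (rep in 1:50) {
    n <- sample(5:8, 1)
    d <- matrix(runif(n * n), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    expect_equal(sort(average_linkage(d)$height), oracle_upgma_heights(d),
                 tolerance = 1e-10)
  }
  expect_true(all(diff(average_linkage(d)$height) >= -1e-12))  # monotone heights
  dbad <- d; dbad[1, 2] <- dbad[2, 1] + 0.2
  expect_error(average_linkage(dbad), "symmetric")
})

test_that("branch cutting respects height, minimum size and size ordering", {
  # all dissimilarities 1: nothing merges below the cut
  d <- matrix(1, 10, 10); diag(d) <- 0
  hc <- average_linkage(d)
  expect_true(all(cut_modules(hc, cut_height = 0.9, min_module_size = 2) == 0))

  # two clean blocks of 25
  n <- 50
  d <- matrix(0.9, n, n)
  d[1:25, 1:25] <- 0.1
  d[26:50, 26:50] <- 0.1
  diag(d) <- 0
  hc <- average_linkage(d)
  labs <- cut_modules(hc, cut_height = 0.5, min_module_size = 20)
  expect_identical(sort(unique(labs)), c(1L, 2L))
  expect_identical(as.integer(table(labs)), c(25L, 25L))
  expect_true(all(labs[1:25] == labs[1]) && all(labs[26:50] == labs[26]))
  # the adaptive cut lands in the big gap and finds the same partition
  expect_identical(cut_modules(hc, "auto", 20), labs)

  # min size larger than n: everything unassigned
  expect_true(all(cut_modules(hc, 0.5, min_module_size = 60) == 0))

  # labels 1..K in decreasing size order
  d3 <- matrix(0.9, 30, 30)
  d3[1:8, 1:8] <- 0.1; d3[9:30, 9:30] <- 0.1
  diag(d3) <- 0
  labs3 <- cut_modules(average_linkage(d3), 0.5, min_module_size = 5)
  expect_identical(unname(labs3[9]), 1L)   # the block of 22 is module 1
  expect_identical(unname(labs3[1]), 2L)
})

test_that("the modularity-based auto cut joins interlinked branches and strips noise", {
  # two sub-blocks tied at 0.3 form one true module; a second tight module;
  # weak background genes must end up unassigned
  n <- 50
  A <- matrix(0.02, n, n)
  A[1:10, 1:10] <- 0.6                  # sub-block 1
  A[11:20, 11:20] <- 0.6                # sub-block 2
  A[1:10, 11:20] <- A[11:20, 1:10] <- 0.3
  A[21:40, 21:40] <- 0.6                # second module
  diag(A) <- 1
  d <- 1 - A
  diag(d) <- 0
  tree <- average_linkage(d)
  labs <- cut_modules(tree, "auto", min_module_size = 10, adjacency = A)
  expect_identical(unname(labs[1:20]), rep(labs[[1]], 20))   # sub-blocks joined
  expect_identical(unname(labs[21:40]), rep(labs[[21]], 20))
  expect_false(labs[[1]] == labs[[21]])
  expect_true(all(labs[41:50] == 0))    # background stripped / unassigned
  # a plain fixed-height cut below the 0.7 join keeps the sub-blocks apart
  fixed <- cut_modules(tree, 0.55, min_module_size = 10)
  expect_false(fixed[[1]] == fixed[[11]])
})

test_that("the Rand index counts pair agreements and ignores labeling", {
  expect_equal(rand_index(c(1, 1, 2), c(1, 1, 2)), 1)
  expect_equal(rand_index(c(1L, 1L, 2L), c(1L, 2L, 2L)), 1 / 3)
  set.seed(82)
  p <- sample(0:3, 40, replace = TRUE)
  expect_equal(rand_index(p, p), 1)
  relabeled <- ifelse(p == 1, 2L, ifelse(p == 2, 1L, p))
  expect_equal(rand_index(p, relabeled), 1)
  q <- sample(0:3, 40, replace = TRUE)
  expect_equal(rand_index(p, q), rand_index(q, p))
  # brute force over all pairs
  brute <- {
    agree <- 0; n <- length(p)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      agree <- agree + ((p[i] == p[j]) == (q[i] == q[j]))
    agree / choose(n, 2)
  }
  expect_equal(rand_index(p, q), brute)
  expect_error(rand_index(1:3, 1:4), "equal length")
})

test_that("the pipeline recovers strong linear modules for every measure class", {
  sim <- simulate_module_data(n_genes = 70, m = 60, n_modules = 2,
                              module_sizes = c(25, 25), quadratic_fraction = 0,
                              noise_sd = 0.3, seed = 101)
  for (meas in c("bicor-signed", "bicor-tom", "auv2", "poly", "spline")) {
    labs <- modules_pipeline(sim$expr, measure = meas)
    expect_equal(rand_index(labs, sim$labels), 1,
                 label = paste("Rand for", meas))
    st <- attr(labs, "settings")
    expect_identical(st[c("cut_height", "min_module_size", "linkage")],
                     list(cut_height = "auto", min_module_size = 20,
                          linkage = "average"))
  }
  # the pruning-based inference networks yield sparse backbones rather than
  # dense blocks; the pipeline must still return a valid partition for them
  for (meas in c("clr", "mrnet", "aracne", "relnet")) {
    labs <- modules_pipeline(sim$expr, measure = meas)
    expect_identical(length(labs), nrow(sim$expr))
    expect_true(all(labs >= 0))
    expect_silent(validate_adjacency(attr(labs, "adjacency"), tol = 1e-8))
  }
})
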