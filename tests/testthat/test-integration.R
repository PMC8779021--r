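random_metrics <- function(n = 6, p = 9) {
  m <- matrix(rnorm(n * p), n, p)
  colnames(m) <- reactor_variables[seq_len(p)]
  m
}

test_that("z-scoring gives mean 0, sd 1 with the n-1 denominator", {
  z <- zscore_metrics(cbind(a = c(1, 2, 3), b = c(5, 9, 7)))
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z[, "b"], c(-1, 1, 0), ignore_attr = TRUE)
  set.seed(51)
  z2 <- zscore_metrics(random_metrics())
  expect_true(all(abs(colMeans(z2)) < 1e-12))
  expect_true(all(abs(apply(z2, 2, sd) - 1) < 1e-12))
})

test_that("constant columns and missing cells are rejected by name", {
  m <- cbind(TOC = c(1, 1, 1), CH4 = c(1, 2, 3))
  expect_error(zscore_metrics(m), "constant column.*TOC")
  m2 <- cbind(TOC = c(1, NA, 3), CH4 = c(1, 2, 3))
  expect_error(zscore_metrics(m2), "missing")
})

test_that("two perfectly correlated variables put 100% of variance on PC1", {
  x <- cbind(a = c(1, 2, 3, 5), b = 2 * c(1, 2, 3, 5) + 1)
  p <- reactor_pca(x, k = 1)
  expect_equal(p$variance_explained[1], 1)
  expect_equal(p$eigenvalues[1], 2)
})

test_that("eigenvalues and loadings match a brute-force correlation eigensolve", {
  set.seed(52)
  for (rep in 1:10) {
    m <- random_metrics(6, 9)
    p <- reactor_pca(m, k = 2)
    ref <- eigen(stats::cov(scale(m)), symmetric = TRUE)
    npos <- sum(ref$values > 1e-12)
    expect_equal(p$eigenvalues[seq_len(npos)], ref$values[seq_len(npos)],
                 tolerance = 1e-8)
    expect_equal(sum(p$eigenvalues), 9, tolerance = 1e-8)
    for (j in 1:2) {
      ev <- ref$vectors[, j]
      ev <- ev * sign(ev[which.max(abs(ev))])
      expect_equal(p$loadings[, j], ev, tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("variance fractions sum to one and scores reconstruct from loadings", {
  set.seed(53)
  m <- random_metrics(8, 9)
  p <- reactor_pca(m, k = 2)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-12)
  z <- zscore_metrics(m)
  expect_equal(p$scores, z %*% p$loadings, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA is invariant to reactor order and deterministic in sign", {
  set.seed(54)
  m <- random_metrics(7, 9)
  p1 <- reactor_pca(m, k = 2)
  perm <- sample(nrow(m))
  p2 <- reactor_pca(m[perm, ], k = 2)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  expect_equal(p1$loadings, p2$loadings, tolerance = 1e-8)
  expect_equal(p1$scores[perm, ], p2$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  p3 <- reactor_pca(m, k = 2)
  expect_identical(p1$loadings, p3$loadings)
})

test_that("k bounds are enforced", {
  set.seed(55)
  m <- random_metrics(6, 9)
  expect_error(reactor_pca(m, k = 0), "'k'")
  expect_error(reactor_pca(m, k = 6), "'k'")
  expect_error(biplot_table(reactor_pca(m, k = 1)), "k = 2")
})

test_that("the biplot table lists 9 variable arrows and the reactor points", {
  set.seed(56)
  m <- random_metrics(6, 9)
  tbl <- biplot_table(reactor_pca(m, k = 2))
  expect_identical(nrow(tbl), 15L)
  expect_identical(sum(tbl$type == "variable"), 9L)
  expect_identical(sum(tbl$type == "reactor"), 6L)
  expect_setequal(tbl$name[tbl$type == "variable"], reactor_variables)

  # rank-1 toy: all arrows colinear on axis 1
  x <- cbind(a = c(1, 2, 3, 5), b = 2 * c(1, 2, 3, 5), c = -c(1, 2, 3, 5))
  t1 <- biplot_table(reactor_pca(x, k = 2))
  arr <- t1[t1$type == "variable", ]
  expect_true(all(abs(arr$y) < 1e-8))
})

test_that("the planted two-factor model is recovered", {
  m <- simulate_reactor_metrics(n_reactors = 24, seed = 57)
  planted <- attr(m, "planted")
  expect_equal(planted$eigenvalues[1:2], c(4.69, 2.05), tolerance = 1e-12)
  p <- reactor_pca(m, k = 2)
  expect_equal(p$eigenvalues[1:2], c(4.69, 2.05), tolerance = 1e-8)
  share <- sum(p$variance_explained[1:2])
  expect_lt(abs(share - planted$share2), 0.05)

  # noisy (non-exact) draws still land near the planted share
  m2 <- simulate_reactor_metrics(n_reactors = 500, exact = FALSE, seed = 58)
  p2 <- reactor_pca(m2, k = 2)
  expect_lt(abs(sum(p2$variance_explained[1:2]) - planted$share2), 0.05)
})

test_that("metrics CSV round-trips through read_reactor_metrics", {
  d <- withr::local_tempdir()
  m <- simulate_reactor_metrics(n_reactors = 12, seed = 59)
  df <- data.frame(reactor = rownames(m), m, check.names = FALSE)
  f <- file.path(d, "metrics.csv")
  write.csv(df, f, row.names = FALSE)
  back <- read_reactor_metrics(f)
  expect_equal(back, m, tolerance = 1e-12, ignore_attr = TRUE)
  df2 <- df[, -which(names(df) == "GST")]
  f2 <- file.path(d, "bad.csv")
  write.csv(df2, f2, row.names = FALSE)
  expect_error(read_reactor_metrics(f2), "GST")
})
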