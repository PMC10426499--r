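# synthetic training data with a controllable number of informative features
make_train <- function(n_per_class = 15, d = 12, n_inform = 3, delta = 2,
                       seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, sprintf("f%02d", 1:d)))
  for (j in seq_len(n_inform)) X[y == 1, j] <- X[y == 1, j] + delta
  list(X = scale(X), y = y)
}

test_that("p-value selection keeps discriminative features only", {
  tr <- make_train(n_inform = 2, delta = 3, seed = 2)
  res <- select_pvalue(tr$X, tr$y)
  expect_true(all(c("f01", "f02") %in% res$retained))

  # a feature identical in both groups is never retained
  X2 <- tr$X; X2[, "f05"] <- rep(seq_len(15), 2)
  res2 <- select_pvalue(X2, tr$y)
  expect_false("f05" %in% res2$retained)

  # alpha = 1 retains every (continuous) feature
  expect_length(select_pvalue(tr$X, tr$y, alpha = 1)$retained, ncol(tr$X))
  expect_error(select_pvalue(tr$X, rep(1, nrow(tr$X))), "single-class")
})

test_that("LASSO keeps a perfectly predictive feature across seeds", {
  for (seed in 1:5) {
    tr <- make_train(d = 10, n_inform = 1, delta = 4, seed = seed)
    res <- select_lasso(tr$X, tr$y)
    expect_true("f01" %in% res$retained)
    expect_true(all(res$retained %in% colnames(tr$X)))
  }
})

test_that("ssLASSO composes screening with LASSO", {
  tr <- make_train(n_inform = 3, delta = 3, seed = 4)
  pv <- select_pvalue(tr$X, tr$y)
  ss <- select_sslasso(tr$X, tr$y)
  expect_true(all(ss$retained %in% pv$retained))  # nested-subset property

  # every feature significant -> identical to plain LASSO on the same fold
  tr2 <- make_train(d = 4, n_inform = 4, delta = 3, seed = 5)
  expect_length(select_pvalue(tr2$X, tr2$y)$retained, 4L)
  expect_identical(select_sslasso(tr2$X, tr2$y)$retained,
                   select_lasso(tr2$X, tr2$y)$retained)

  # nothing significant -> empty selection with a warning
  set.seed(6)
  Xn <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, c("a", "b", "c")))
  yn <- rep(0:1, each = 10)
  pvn <- select_pvalue(Xn, yn, alpha = 1e-6)
  expect_length(pvn$retained, 0L)
  expect_warning(ssn <- select_sslasso(Xn, yn, alpha = 1e-6), "no significant")
  expect_length(ssn$retained, 0L)
})

test_that("PCA picks the 95%-variance component count", {
  # all points on one line -> a single component
  set.seed(7)
  t <- rnorm(30)
  X1 <- cbind(a = t, b = 2 * t, c = -t)
  expect_equal(fit_pca(X1)$projection$k, 1L)

  # isotropic noise: eigenvalue equipartition puts k near 0.95 * d
  set.seed(8)
  Xi <- matrix(rnorm(500 * 10), 500, 10, dimnames = list(NULL, letters[1:10]))
  expect_lte(abs(fit_pca(Xi)$projection$k - 9.5), 2)

  # training scores reproduce the eigenvalues
  res <- fit_pca(Xi)
  sc <- apply_pca(res, Xi)
  expect_equal(apply(sc, 2, var),
               unname(res$projection$sdev[seq_len(res$projection$k)]^2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fit_pca(matrix(1, 5, 3, dimnames = list(NULL, c("a", "b", "c")))),
               "zero-variance")
})

test_that("ssPCA composes screening with PCA", {
  tr <- make_train(n_inform = 3, delta = 3, seed = 9)
  res <- select_sspca(tr$X, tr$y)
  pv <- select_pvalue(tr$X, tr$y)
  expect_identical(rownames(res$projection$rotation), pv$retained)
  expect_lte(res$projection$k, length(pv$retained))
  expect_warning(em <- select_sspca(tr$X, tr$y, alpha = 1e-12),
                 "no significant")
  expect_length(em$retained, 0L)
})

test_that("SFS adds the dominant feature then stops on small improvements", {
  tr <- make_train(d = 8, n_inform = 1, delta = 5, seed = 10)
  res <- select_sfs(tr$X, tr$y, classifier = "LR")
  expect_equal(res$retained[1], "f01")
  expect_lte(length(res$retained), 3L)

  # a threshold of 1.0 cannot be met by any addition -> exactly one feature
  res1 <- select_sfs(tr$X, tr$y, classifier = "LR",
                     improvement_threshold = 1.0)
  expect_length(res1$retained, 1L)

  # deterministic
  expect_identical(res$retained,
                   select_sfs(tr$X, tr$y, classifier = "LR")$retained)
})

test_that("selector transforms are pure functions of the training data", {
  tr <- make_train(seed = 11)
  for (m in c("p-value", "LASSO", "ssLASSO", "PCA", "ssPCA")) {
    r1 <- radiostab:::fit_selector(m, tr$X, tr$y)
    r2 <- radiostab:::fit_selector(m, tr$X, tr$y)
    expect_identical(r1$retained, r2$retained)
    expect_equal(r1$projection, r2$projection)
    # applying to permuted test subjects permutes rows, nothing else
    set.seed(12)
    Xte <- matrix(rnorm(6 * ncol(tr$X)), 6,
                  dimnames = list(NULL, colnames(tr$X)))
    p <- c(3, 1, 6, 2, 5, 4)
    expect_equal(apply_selector(r1, Xte)[p, , drop = FALSE],
                 apply_selector(r1, Xte[p, , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("selected-set sizes follow the expected method ordering", {
  # many weakly-informative correlated features: the screening-type selector
  # retains the most, sparse penalised selectors the fewest, and PCA counts
  # are small and stable
  sizes <- list()
  for (seed in 1:3) {
    set.seed(seed)
    n <- 30; d <- 30
    y <- rep(0:1, each = n / 2)
    # five strong latent factors -> heavy redundancy, low intrinsic dimension
    B <- matrix(rnorm(n * 5), n, 5)
    X <- B[, rep(1:5, 6)] + matrix(rnorm(n * d, sd = 0.2), n, d)
    X[y == 1, 1:15] <- X[y == 1, 1:15] + 1.2
    colnames(X) <- sprintf("f%02d", 1:d)
    X <- scale(X)
    sizes[[seed]] <- suppressWarnings(c(
      pvalue = length(select_pvalue(X, y)$retained),
      lasso = length(select_lasso(X, y)$retained),
      sslasso = length(select_sslasso(X, y)$retained),
      pca = fit_pca(X)$projection$k))
  }
  m <- colMeans(do.call(rbind, sizes))
  expect_gte(m["pvalue"], m["lasso"])
  expect_gte(m["lasso"], m["sslasso"])
  ks <- vapply(sizes, `[[`, 0, "pca")
  expect_lte(diff(range(ks)), 3)  # PCA count small and stable across draws
  expect_lt(max(ks), 15)
})
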