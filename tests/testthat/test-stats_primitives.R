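test_that("pearson_test handles exact and frozen cases", {
  x <- c(1.2, 2.5, 3.1, 4.8)
  r1 <- pearson_test(x, x)
  expect_equal(r1$statistic, 1)
  expect_equal(r1$p.value, 0)
  r2 <- pearson_test(x, -x)
  expect_equal(r2$statistic, -1)
  expect_equal(r2$p.value, 0)
  # frozen from the closed-form t transformation (cross-checked oracle)
  r3 <- pearson_test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r3$statistic, 0.8, tolerance = 1e-12)
  expect_equal(r3$p.value, 0.104088038661828, tolerance = 1e-12)
  expect_equal(r3$df, 3)
})

test_that("pearson_test signals degenerate input and rejects short vectors", {
  res <- pearson_test(c(1, 1, 1), c(1, 2, 3))
  expect_true(res$undefined)
  expect_true(is.na(res$p.value))
  expect_error(pearson_test(c(1, 2), c(3, 4)), "n >= 3")
  expect_error(pearson_test(c(1, 2, NA), c(1, 2, 3)), "missing")
})

test_that("pearson is invariant under positive affine maps and p symmetric in |r|", {
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    a <- pearson_test(x, y)
    b <- pearson_test(2.5 * x + 3, 0.7 * y - 1)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
    flipped <- pearson_test(x, -y)
    expect_equal(flipped$statistic, -a$statistic, tolerance = 1e-12)
    expect_equal(flipped$p.value, a$p.value, tolerance = 1e-12)
  }
})

test_that("paired_t matches frozen oracle value and is antisymmetric", {
  nrm <- c(0, 0, 0, 0)
  tum <- c(1.0, 1.2, 0.8, 1.0)
  res <- paired_t(tum, nrm)
  expect_equal(res$statistic, 12.2474487139159, tolerance = 1e-10)
  expect_equal(res$p.value, 0.00117221644471689, tolerance = 1e-10)
  expect_equal(res$df, 3)
  swapped <- paired_t(nrm, tum)
  expect_equal(swapped$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swapped$p.value, res$p.value, tolerance = 1e-12)
})

test_that("paired_t signals zero-variance differences and handles constant shift", {
  x <- c(1, 2, 3)
  expect_true(paired_t(x, x)$undefined)
  shifted <- paired_t(x + 2, x)   # constant non-zero difference
  expect_false(shifted$undefined)
  expect_equal(shifted$p.value, 0)
  expect_error(paired_t(1, 2), "n >= 2")
})

test_that("welch_t matches frozen oracle, is shift-invariant, identical groups give t=0 p=1", {
  res <- welch_t(c(1, 2, 3), c(2, 4, 6, 8))
  expect_equal(res$statistic, -2.12132034355964, tolerance = 1e-10)
  expect_equal(res$df, 4.07547169811321, tolerance = 1e-10)
  expect_equal(res$p.value, 0.0999128643118009, tolerance = 1e-10)
  a <- c(1, 2, 3, 4)
  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  set.seed(7)
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(welch_t(x + 10, y + 10)$statistic, welch_t(x, y)$statistic,
               tolerance = 1e-9)
  expect_true(welch_t(c(2, 2), c(2, 2))$undefined)
})

test_that("three tests agree with independent base-R oracles on random instances", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    ct <- cor.test(x, y)
    mine <- pearson_test(x, y)
    expect_equal(mine$statistic, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(mine$p.value, ct$p.value, tolerance = 1e-10)

    tt <- t.test(x, y, paired = TRUE)
    pt_mine <- paired_t(x, y)
    expect_equal(pt_mine$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pt_mine$p.value, tt$p.value, tolerance = 1e-10)
    # paired t equals the one-sample t on differences
    ot <- t.test(x - y)
    expect_equal(pt_mine$p.value, ot$p.value, tolerance = 1e-12)

    m <- sample(2:10, 1)
    b <- rnorm(m)
    wt <- t.test(x, b, var.equal = FALSE)
    wt_mine <- welch_t(x, b)
    expect_equal(wt_mine$statistic, unname(wt$statistic), tolerance = 1e-10)
    expect_equal(wt_mine$df, unname(wt$parameter), tolerance = 1e-8)
    expect_equal(wt_mine$p.value, wt$p.value, tolerance = 1e-10)
  }
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 10), 0.1)
  expect_equal(bonferroni(0.5, 10), 1.0)
  expect_equal(bonferroni(0.37, 1), 0.37)
  expect_equal(bonferroni(c(0.001, 0.2), 6), c(0.006, 1))
  expect_error(bonferroni(0.01, 0), "positive integer")
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
})

test_that("bh_fdr reproduces step-up arithmetic and both independent oracles", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(20)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("bh_fdr is monotone, dominates p, and is permutation-equivariant", {
  set.seed(12)
  for (i in 1:20) {
    p <- runif(15)
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    perm <- sample(15)
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-15)
  }
})
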