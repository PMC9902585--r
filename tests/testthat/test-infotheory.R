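test_that("preprocessing follows the zero-to-one / total / log2 recipe", {
  expect_equal(preprocess_for_entropy(c(0, 2, 2)), log2(c(0.2, 0.4, 0.4)))
  expect_equal(preprocess_for_entropy(rep(3, 5)), rep(log2(1 / 5), 5))
  # strictly positive input: zero-replacement is a no-op
  x <- c(1.5, 2, 7)
  expect_equal(preprocess_for_entropy(x), log2(x / sum(x)))
  expect_error(preprocess_for_entropy(c(0, 0)), "all-zero")
  expect_error(preprocess_for_entropy(c(-1, 2)), "non-negative")
})

test_that("equal-frequency discretization is monotone, tie-safe and rank-invariant", {
  set.seed(11)
  x <- rnorm(100)
  d <- discretize(x, 10)
  expect_equal(unname(table(d)), rep(10L, 10), ignore_attr = TRUE)
  # monotone
  expect_true(all(diff(d[order(x)]) >= 0))
  # strictly increasing transform leaves labels unchanged
  expect_equal(as.integer(discretize(exp(x), 10)), as.integer(d))
  # ties share a bin
  xt <- c(rep(1, 50), rep(2, 50))
  dt <- discretize(xt, 10)
  expect_length(unique(dt[xt == 1]), 1)
  # constant input collapses to a single flagged level
  dc <- discretize(rep(4, 20), 10)
  expect_equal(attr(dc, "n_levels"), 1L)
  expect_true(attr(dc, "constant"))
  expect_equal(shannon_entropy(dc), 0)
})

test_that("entropy matches closed forms", {
  expect_equal(shannon_entropy(as_disc(rep(1:4, 25))), 2.0)
  expect_equal(shannon_entropy(as_disc(rep(c(1, 1, 2, 3), 10))), 1.5)
  x <- as_disc(rep(1:3, c(5, 3, 2)))
  expect_equal(shannon_entropy(list(x, x)), shannon_entropy(x))
  expect_error(shannon_entropy(list(as_disc(1:4), as_disc(1:5))), "same number")
})

test_that("mutual information reproduces closed-form checkpoints", {
  x <- as_disc(rep(1:2, 50))
  self <- mutual_information(x, x)
  expect_equal(self$mi, 1.0)
  expect_equal(self$nmi, 1.0)
  # independent balanced 2x2
  a <- as_disc(rep(c(1, 1, 2, 2), 25))
  b <- as_disc(rep(c(1, 2, 1, 2), 25))
  expect_equal(mutual_information(a, b)$mi, 0)
  # XOR: synergy, co-information -1 bit
  z <- as_disc(1L + as.integer(xor(a == 2, b == 2)), 2)
  expect_equal(mutual_information(a, b, z)$mi, -1.0)
  # triple copy: redundancy, nmi 1
  t3 <- mutual_information(x, x, x)
  expect_equal(t3$mi, 1.0)
  expect_equal(t3$nmi, 1.0)
})

test_that("inclusion-exclusion MI equals the direct plugin oracle on random tables", {
  set.seed(71)
  for (rep in 1:200) {
    n <- sample(20:60, 1)
    Lx <- sample(2:4, 1); Ly <- sample(2:4, 1)
    x <- as_disc(sample.int(Lx, n, replace = TRUE), Lx)
    y <- as_disc(sample.int(Ly, n, replace = TRUE), Ly)
    mi <- mutual_information(x, y)$mi
    expect_lt(abs(mi - oracle_mi2(x, y)), 1e-12)  # absolute, in bits
    expect_gte(mi, -1e-12)
    if (rep %% 2 == 0) {
      Lz <- sample(2:4, 1)
      z <- as_disc(sample.int(Lz, n, replace = TRUE), Lz)
      expect_lt(abs(mutual_information(x, y, z)$mi - oracle_coinfo(x, y, z)),
                1e-12)
    }
  }
})

test_that("entropies and MI are invariant to relabeling bins", {
  set.seed(5)
  x <- as_disc(sample.int(4, 80, replace = TRUE), 4)
  y <- as_disc(sample.int(3, 80, replace = TRUE), 3)
  perm <- sample(4)
  xp <- as_disc(perm[as.integer(x)], 4)
  expect_equal(shannon_entropy(xp), shannon_entropy(x))
  expect_equal(mutual_information(xp, y)$mi, mutual_information(x, y)$mi)
})

test_that("joint entropy is subadditive with equality iff independent", {
  set.seed(6)
  for (i in 1:20) {
    x <- as_disc(sample.int(3, 60, replace = TRUE), 3)
    y <- as_disc(sample.int(3, 60, replace = TRUE), 3)
    expect_lte(shannon_entropy(list(x, y)),
               shannon_entropy(x) + shannon_entropy(y) + 1e-12)
  }
  # exact independence on a balanced design: equality
  a <- as_disc(rep(c(1, 1, 2, 2), 25))
  b <- as_disc(rep(c(1, 2, 1, 2), 25))
  expect_equal(shannon_entropy(list(a, b)),
               shannon_entropy(a) + shannon_entropy(b))
})

test_that("normalized MI handles zero-entropy marginals", {
  expect_equal(normalized_mi(0.5, c(1, 0)), 0)
  expect_equal(normalized_mi(1, c(1, 1)), 1)
  expect_equal(normalized_mi(1, c(2, 2)), 0.5)
})

test_that("permutation p-values obey the add-one formula and seed stability", {
  set.seed(2)
  x <- discretize(rnorm(200), 10)
  # perfect dependence: no permutation beats the observed statistic
  p <- permutation_pvalue(x, x, n_perm = 999, seed = 4)
  expect_equal(p$p_value, 1 / 1000)
  # determinism
  p2 <- permutation_pvalue(x, x, n_perm = 999, seed = 4)
  expect_identical(p, p2)
  # triple variant returns the co-information statistic
  y <- discretize(rnorm(200), 10)
  p3 <- permutation_pvalue(x, x, y, n_perm = 199, seed = 4)
  expect_equal(p3$statistic, "co_information")
  expect_lte(p3$p_value, 0.05)  # x strongly dependent on anchor x
  expect_error(permutation_pvalue(x, x, n_perm = 10), "99")
})

test_that("C++ permutation engine agrees with the R inclusion-exclusion path", {
  set.seed(9)
  g <- discretize(rnorm(150), 8)
  a <- discretize(rnorm(150), 10)
  b <- discretize(rnorm(150), 10)
  res <- withr::with_seed(1, coassoc:::perm_coassoc_cpp(
    as.integer(g), 8L, as.integer(a), attr(a, "n_levels"),
    as.integer(b), attr(b, "n_levels"), 99L))
  expect_equal(res$mi1, mutual_information(g, a)$mi, tolerance = 1e-12)
  expect_equal(res$mi2, mutual_information(g, b)$mi, tolerance = 1e-12)
  expect_equal(res$ci, mutual_information(g, a, b)$mi, tolerance = 1e-12)
  expect_equal(res$h_target, shannon_entropy(g), tolerance = 1e-12)
})
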