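test_that("overlap coefficient: identity, disjoint, nesting, undefined", {
  a <- binary_mask(array(c(rep(1, 8), rep(0, 19)), c(3, 3, 3)))
  expect_equal(overlap_coefficient(a, a), 1)

  arr_b <- array(0, c(3, 3, 3)); arr_b[3, 3, 3] <- 1
  b <- binary_mask(arr_b)
  expect_equal(overlap_coefficient(a, b), 0)

  # smaller set strictly inside the larger -> 1 even though sets differ
  inner <- array(0, c(3, 3, 3)); inner[1:2, 1, 1] <- 1
  expect_equal(overlap_coefficient(a, binary_mask(inner)), 1)

  empty <- binary_mask(array(0, c(3, 3, 3)))
  expect_true(is.na(overlap_coefficient(a, empty)))
  expect_warning(overlap_coefficient(binary_mask(inner), a,
                                     expect_b_smaller = TRUE), "smaller")
})

test_that("dice: identity, explicit counts, undefined for two empties", {
  a <- rand_mask(c(4, 4, 4), 0.4)
  expect_equal(dice(a, a), 1)
  arr1 <- array(0, c(3, 3, 3)); arr1[1:4] <- 1
  arr2 <- array(0, c(3, 3, 3)); arr2[3:6] <- 1   # |A|=|B|=4, |A^B|=2
  expect_equal(dice(binary_mask(arr1), binary_mask(arr2)), 0.5)
  empty <- binary_mask(array(0, c(3, 3, 3)))
  expect_true(is.na(dice(empty, empty)))
})

test_that("OC and Dice match brute-force oracles on random masks", {
  set.seed(10)
  for (i in 1:20) {
    dims <- rep(sample(8:10, 1), 3)
    a <- rand_mask(dims, runif(1, 0.1, 0.6))
    b <- rand_mask(dims, runif(1, 0.1, 0.6))
    expect_equal(overlap_coefficient(a, b), oc_oracle(a, b))
    expect_equal(dice(a, b), dice_oracle(a, b))
    # OC >= Dice whenever both are defined
    oc <- overlap_coefficient(a, b); dc <- dice(a, b)
    if (!is.na(oc) && !is.na(dc)) expect_gte(oc, dc - 1e-12)
  }
})

test_that("OC and Dice are invariant under a shared voxel permutation", {
  set.seed(12)
  a <- rand_mask(c(6, 6, 6), 0.3)
  b <- rand_mask(c(6, 6, 6), 0.3)
  perm <- sample(216)
  pa <- binary_mask(array(a$data[perm], c(6, 6, 6)))
  pb <- binary_mask(array(b$data[perm], c(6, 6, 6)))
  expect_equal(overlap_coefficient(a, b), overlap_coefficient(pa, pb))
  expect_equal(dice(a, b), dice(pa, pb))
})

test_that("concordance table validates keys and aggregates per cohort", {
  rows <- data.frame(subject = rep(1:3, each = 3),
                     method = "uncseg",
                     klass = rep(c("+M1+", "-M1+", "-M1-"), 3),
                     oc = c(0.9, 0.1, 0, 0.8, 0, 0, NA, 0.2, 0.1))
  tab <- concordance_table(rows)
  agg <- cohort_mean_oc(tab, "uncseg", "+M1+")
  expect_equal(agg$mean, mean(c(0.9, 0.8)))  # NA excluded
  expect_equal(agg$n, 2)
  single <- cohort_mean_oc(concordance_table(rows[1, ]), "uncseg", "+M1+")
  expect_equal(single$mean, 0.9)
  expect_equal(single$sd, 0)
  expect_error(concordance_table(rows[c(1, 1), ]), "duplicate")
})

test_that("oc_ordering_check allows ties only where values agree", {
  expect_true(oc_ordering_check(c(0.83, 0.31, 0.01)))
  expect_true(oc_ordering_check(c(0.5, 0, 0)))       # tie at zero is fine
  expect_false(oc_ordering_check(c(0.2, 0.5, 0.1)))
  expect_false(oc_ordering_check(c(0.5, 0.1, 0.3)))
  expect_true(is.na(oc_ordering_check(c(0.5, NA, 0))))
  expect_error(oc_ordering_check(c(0.5, 0.1)), "three")
})

test_that("wilcoxon signed rank: degenerate, exact, enumeration oracle", {
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "nonzero")

  # n = 6, distinct |differences|: exact branch equals full enumeration
  set.seed(21)
  for (i in 1:10) {
    x <- runif(6); y <- x + sample(c(-1, 1), 6, TRUE) * runif(6, 0.05, 1)
    got <- wilcoxon_signed_rank(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
  }
  # agreement with the enumeration oracle for several n <= 10
  for (n in c(5, 8, 10)) {
    x <- runif(n); y <- x + sample(c(-1, 1), n, TRUE) * runif(n, 0.05, 1)
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("wilcoxon falls back to tie-corrected normal approximation", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(2, 1, 5, 2, 7, 4, 9)   # |d| = 1 1 2 2 2 2 2 -> heavy ties
  got <- wilcoxon_signed_rank(x, y)
  expect_identical(got$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             correct = FALSE))
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("spearman: monotone limits, ties, and small-n permutation", {
  d <- 1:20
  u_dec <- 30 - 2 * d
  expect_equal(spearman_cor(u_dec, d)$rho, -1)
  expect_equal(spearman_cor(d, d)$rho, 1)

  # hand-checked average-rank case: d=(1,2,2,3), u=(2,1,4,3)
  got <- spearman_cor(c(2, 1, 4, 3), c(1, 2, 2, 3))
  ru <- rank(c(2, 1, 4, 3)); rd <- rank(c(1, 2, 2, 3))
  expect_equal(got$rho, stats::cor(ru, rd))
  expect_identical(got$method, "exact-permutation")
  ref <- suppressWarnings(stats::cor.test(c(2, 1, 4, 3), c(1, 2, 2, 3),
                                          method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate))

  # t-approximation branch agrees with cor.test at moderate n
  set.seed(31)
  u <- runif(40); dd <- runif(40)
  gotl <- spearman_cor(u, dd)
  refl <- stats::cor.test(u, dd, method = "spearman", exact = FALSE)
  expect_equal(gotl$rho, unname(refl$estimate), tolerance = 1e-12)
  expect_equal(gotl$p_value, refl$p.value, tolerance = 1e-9)

  expect_error(spearman_cor(rep(1, 5), 1:5), "variance")
})

test_that("linear trend recovers exact lines and matches normal equations", {
  d <- c(0, 1, 2, 5, 9)
  u <- 3 - 0.5 * d
  tr <- linear_trend(u, d)
  expect_equal(tr$slope, -0.5)
  expect_equal(tr$intercept, 3)

  tr0 <- linear_trend(rep(2.5, 4), c(1, 2, 3, 4))
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$intercept, 2.5)

  set.seed(32)
  uu <- runif(30); dd <- runif(30)
  tr2 <- linear_trend(uu, dd)
  X <- cbind(1, dd)
  beta <- solve(t(X) %*% X, t(X) %*% uu)   # closed-form normal equations
  expect_equal(tr2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(tr2$slope, beta[2], tolerance = 1e-10)
  expect_error(linear_trend(1:3, rep(1, 3)), "distinct")
})
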