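test_that("spearman_rho matches the rank-difference formula and its invariances", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with d = (1,1,1,1,0), sum d^2 = 4
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 1 - 6 * 4 / (5 * 24))
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)

  set.seed(11)
  for (i in 1:20) {
    x <- stats::rnorm(15); y <- stats::rnorm(15)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(y, x), r)                       # symmetry
    expect_equal(spearman_rho(exp(x), y), r)                  # monotone invariance
    expect_equal(spearman_rho(x, 3 * y - 7), r)
    expect_equal(spearman_rho(rank(x), y), r)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("t_test reproduces the pooled-variance formula and conventions", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # pooled by hand: sp2 = 1, t = (2-5)/sqrt(1*(1/3+1/3))
  t_hand <- (mean(a) - mean(b)) / sqrt(1 * (1 / 3 + 1 / 3))
  res <- t_test(a, b, "student")
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(t_hand, 4), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-3)

  same <- c(1, 3, 5)
  id <- t_test(same, same)
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)

  # degenerate conventions
  expect_equal(t_test(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(t_test(c(2, 2), c(3, 3)), "zero variance")

  # welch differs from student under unequal variances
  set.seed(2)
  x <- stats::rnorm(10); y <- stats::rnorm(25, sd = 4)
  expect_false(isTRUE(all.equal(t_test(x, y, "welch")$df,
                                t_test(x, y, "student")$df)))
})

test_that("t_test type-I error is calibrated under the null", {
  set.seed(301)
  p <- replicate(200, t_test(stats::rnorm(5), stats::rnorm(5))$p_value)
  expect_gt(mean(p <= 0.05), 0.01)
  expect_lt(mean(p <= 0.05), 0.10)
})

test_that("wilcoxon_rank_sum is exact at small n and approximates well beyond", {
  # enumerate all C(4,2) = 6 assignments: rank sums {3,4,5,5,6,7}; W = 3
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(3, 4), c(1, 2))$p_value, 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 3, 5), c(1, 3, 5))$p_value, 1)

  # tie-free exact p agrees with the distribution-based oracle
  set.seed(21)
  for (i in 1:20) {
    x <- sample(1:50, 5); y <- sample(51:100, 6)  # no cross-group ties
    got <- wilcoxon_rank_sum(x, y)$p_value
    expect_equal(got, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # exact vs continuity-corrected normal approximation agree within 0.02
  set.seed(22)
  for (i in 1:20) {
    x <- stats::rnorm(6); y <- stats::rnorm(6, 0.5)
    r <- rank(c(x, y))
    exact <- wilcoxon_rank_sum(x, y)$p_value
    e_w <- 6 * 13 / 2
    v <- 36 / 12 * 13  # no ties
    z <- max(0, (abs(sum(r[1:6]) - e_w) - 0.5)) / sqrt(v)
    approx <- 2 * stats::pnorm(-z)
    expect_lt(abs(exact - min(1, approx)), 0.02)
  }

  # large-sample path with heavy ties stays a valid p-value
  set.seed(23)
  x <- sample(0:3, 20, TRUE); y <- sample(0:4, 20, TRUE)
  p <- wilcoxon_rank_sum(x, y)$p_value
  expect_gte(p, 0)
  expect_lte(p, 1)
})

test_that("bh_adjust equals the classical step-up rule and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(31)
  for (i in 1:100) {
    p <- stats::runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # q monotone non-decreasing in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    # rejection set q <= alpha == classical step-up set
    for (alpha in c(0.01, 0.05, 0.2))
      expect_identical(q <= alpha, bh_stepup_reject(p, alpha))
  }
})

test_that("chi_square_test matches the closed form and clamps under Yates", {
  # 2x2 closed form n(ad-bc)^2 / (r1 r2 c1 c2)
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(sample(1:20, 4, TRUE), 2)
    got <- chi_square_test(tab, yates = FALSE)
    n <- sum(tab)
    want <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      prod(rowSums(tab)) / prod(colSums(tab))
    expect_equal(got$statistic, want, tolerance = 1e-10)
    expect_equal(got$df, 1)
    expect_equal(got$p_value, stats::pchisq(want, 1, lower.tail = FALSE))
  }

  prop <- rbind(c(10, 20, 30), c(5, 10, 15))  # proportional rows
  res <- chi_square_test(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2)

  # Yates correction is capped at |O - E|, so X2 clamps at zero
  clamp <- chi_square_test(rbind(c(6, 9), c(6, 10)), yates = TRUE)
  expect_equal(clamp$statistic, 0)
  expect_equal(clamp$p_value, 1)
  expect_error(chi_square_test(rbind(c(1, 2, 3), c(4, 5, 6)), yates = TRUE),
               "2x2")
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("fisher_exact equals full enumeration on random 2x2 tables", {
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  # margins (2,2)/(2,2): tables a=0,1,2 with probs 1/6, 4/6, 1/6
  expect_equal(fisher_exact(rbind(c(2, 0), c(0, 2)))$p_value, 1 / 3)
  expect_equal(fisher_exact(rbind(c(0, 0), c(3, 4)))$p_value, 1)  # zero margin

  set.seed(51)
  for (i in 1:100) {
    repeat {
      tab <- matrix(stats::rmultinom(1, sample(4:30, 1), rep(1 / 4, 4)), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(fisher_exact(tab)$p_value, fisher_enum_p(tab),
                 tolerance = 1e-9)
  }
})
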