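test_that("support bounds follow the margin formulas", {
  expect_equal(nhd_support(pair_counts(8, 42, 8)), c(0L, 8L))
  expect_equal(nhd_support(pair_counts(2, 48, 2)), c(0L, 2L))
  expect_equal(nhd_support(pair_counts(48, 2, 47)), c(45L, 47L))
  expect_error(pair_counts(-1, 5, 2), "non-negative")
  expect_error(pair_counts(3, 2, 9), "exceeds the total")
})

test_that("log normalizer matches Vandermonde at theta 0 and brute force", {
  expect_equal(nhd_log_normalizer(pair_counts(8, 42, 8), 0), lchoose(50, 8))
  expect_equal(nhd_log_normalizer(pair_counts(5, 7, 6), 0), lchoose(12, 6))
  set.seed(42)
  for (tb in random_tables(30)) {
    th <- runif(1, -5, 5)
    expect_equal(nhd_log_normalizer(pair_counts(tb$n_A, tb$n_notA, tb$n_B),
                                    th),
                 brute_nhd(tb$n_A, tb$n_notA, tb$n_B, th)$log_normalizer,
                 tolerance = 1e-10)
  }
  # one-point support: the normalizer is the single term
  expect_equal(nhd_log_normalizer(pair_counts(10, 0, 4), 3),
               lchoose(10, 4) + 4 * 3)
  expect_error(nhd_log_normalizer(pair_counts(5, 5, 5), Inf), "finite")
})

test_that("log pmf: central closed form, hypergeometric reduction,
           label symmetry, out-of-support contract", {
  expect_equal(nhd_logpmf(0, pair_counts(2, 48, 2), 0), log(1128 / 1225))
  set.seed(7)
  for (tb in random_tables(20)) {
    pc <- pair_counts(tb$n_A, tb$n_notA, tb$n_B)
    s <- nhd_support(pc)
    n <- s[1]:s[2]
    # theta = 0 is the centred (standard) hypergeometric distribution
    expect_equal(nhd_logpmf(n, pc, 0),
                 dhyper(n, tb$n_A, tb$n_notA, tb$n_B, log = TRUE),
                 tolerance = 1e-12)
    # swapping which species is A leaves the pmf unchanged
    th <- runif(1, -4, 4)
    pc_swap <- pair_counts(tb$n_B, tb$n_A + tb$n_notA - tb$n_B, tb$n_A)
    expect_equal(nhd_logpmf(n, pc, th), nhd_logpmf(n, pc_swap, th),
                 tolerance = 1e-10)
    # probabilities over the support sum to one
    expect_equal(sum(exp(nhd_logpmf(n, pc, th))), 1, tolerance = 1e-12)
  }
  expect_identical(nhd_logpmf(9, pair_counts(8, 42, 8), 1), -Inf)
  expect_identical(nhd_logpmf(-1, pair_counts(8, 42, 8), 1), -Inf)
})

test_that("normalization holds at extreme theta and large totals", {
  for (th in c(-20, -7, 7, 20)) {
    pc <- pair_counts(300, 9700, 250)
    s <- nhd_support(pc)
    expect_equal(sum(exp(nhd_logpmf(s[1]:s[2], pc, th))), 1,
                 tolerance = 1e-12)
  }
})

test_that("mode reproduces the occupancy-dependent shift and breaks ties
           toward the smaller count", {
  # two species on 8 of 50 sites: theta -2 -> +2 shifts the mode 0 -> 4
  expect_identical(nhd_mode(pair_counts(8, 42, 8), 2), 4L)
  expect_identical(nhd_mode(pair_counts(8, 42, 8), -2), 0L)
  # at occupancy 2 of 50 the same shift leaves the mode at zero
  expect_identical(nhd_mode(pair_counts(2, 48, 2), 2), 0L)
  expect_identical(nhd_mode(pair_counts(2, 48, 2), -2), 0L)
  set.seed(11)
  for (tb in random_tables(20)) {
    th <- runif(1, -4, 4)
    expect_identical(nhd_mode(pair_counts(tb$n_A, tb$n_notA, tb$n_B), th),
                     as.integer(brute_nhd(tb$n_A, tb$n_notA,
                                          tb$n_B, th)$mode))
  }
  # construct an exact two-point tie: f(1)/f(0) = 1 at theta_tie
  pc <- pair_counts(4, 6, 3)
  theta_tie <- -log(choose(4, 1) * choose(6, 2) / choose(6, 3))
  r <- nhd_logpmf(1, pc, theta_tie) - nhd_logpmf(0, pc, theta_tie)
  expect_equal(r, 0, tolerance = 1e-12)
  expect_identical(nhd_mode(pc, theta_tie), 0L)
})

test_that("mean: central closed form, brute-force match, monotone in theta,
           saturates at the support bounds", {
  expect_equal(nhd_mean(pair_counts(8, 42, 8), 0), 8 * 8 / 50)
  expect_equal(nhd_mean(pair_counts(8, 42, 8), 2),
               brute_nhd(8, 42, 8, 2)$mean, tolerance = 1e-10)
  set.seed(13)
  for (tb in random_tables(10)) {
    pc <- pair_counts(tb$n_A, tb$n_notA, tb$n_B)
    ths <- seq(-6, 6, by = 0.5)
    mns <- vapply(ths, function(t) nhd_mean(pc, t), numeric(1))
    s <- nhd_support(pc)
    if (s[2] > s[1]) expect_true(all(diff(mns) > 0))
    expect_lt(abs(nhd_mean(pc, 40) - s[2]), 1e-6)
    expect_lt(abs(nhd_mean(pc, -40) - s[1]), 1e-6)
  }
})

test_that("sampler draws match the pmf", {
  # one-point support is deterministic
  expect_identical(unique(nhd_sample(pair_counts(10, 0, 4), 1.7, 100)), 4L)
  set.seed(99)
  x <- nhd_sample(pair_counts(8, 42, 8), 0, 1e5)
  mu <- 8 * 8 / 50
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
  # chi-squared goodness of fit against the exact pmf at theta = 2
  x2 <- nhd_sample(pair_counts(8, 42, 8), 2, 1e5)
  p <- exp(nhd_logpmf(0:8, pair_counts(8, 42, 8), 2))
  obs <- tabulate(x2 + 1L, nbins = 9)
  keep <- p * 1e5 >= 5
  chi <- sum((obs[keep] - 1e5 * p[keep])^2 / (1e5 * p[keep]))
  expect_lt(chi, qchisq(0.999, df = sum(keep) - 1))
})

test_that("conditional MLE solves the mean equation and flags boundaries", {
  expect_equal(theta_mle(pair_counts(10, 10, 10, n_AB = 5))$theta, 0,
               tolerance = 1e-7)
  est <- theta_mle(pair_counts(8, 42, 8, n_AB = 4))
  expect_equal(est$theta, grid_theta_mle(8, 42, 8, 4), tolerance = 1e-6)
  # a non-overlapping pair is by itself uninformative: the MLE diverges
  expect_identical(theta_mle(pair_counts(8, 42, 8, n_AB = 0))$boundary,
                   "neg_infinite")
  expect_identical(theta_mle(pair_counts(8, 42, 8, n_AB = 8))$boundary,
                   "pos_infinite")
  expect_identical(theta_mle(pair_counts(50, 0, 8, n_AB = 8))$boundary,
                   "undefined")
  set.seed(5)
  for (tb in random_tables(30, interior_only = TRUE)) {
    a <- theta_mle(pair_counts(tb$n_A, tb$n_notA, tb$n_B, tb$n_AB))
    expect_identical(a$boundary, "finite")
    # label symmetry of the estimate
    b <- theta_mle(pair_counts(tb$n_B, tb$n_A + tb$n_notA - tb$n_B,
                               tb$n_A, tb$n_AB))
    expect_equal(a$theta, b$theta, tolerance = 1e-6)
  }
})

test_that("finite MLEs concentrate on the truth as margins grow", {
  set.seed(21)
  truths <- c(-1, -0.5, 0, 0.5, 1)
  est_means <- vapply(truths, function(th) {
    pc <- pair_counts(250, 750, 250)
    draws <- nhd_sample(pc, th, 40)
    ests <- vapply(draws, function(d)
      theta_mle(pair_counts(250, 750, 250, n_AB = d))$theta, numeric(1))
    mean(ests, na.rm = TRUE)
  }, numeric(1))
  slope <- coef(lm(est_means ~ truths))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("theta from conditional probabilities is the log odds ratio", {
  expect_equal(theta_from_conditional_probs(0.5, 0.5), 0)
  expect_equal(theta_from_conditional_probs(0.8, 0.5), log(4))
  expect_equal(theta_from_conditional_probs(0.5, 0.8), -log(4))
  expect_equal(theta_from_conditional_probs(0.3, 0.9),
               -theta_from_conditional_probs(0.9, 0.3))
  expect_error(theta_from_conditional_probs(0, 0.5), "infinite odds")
  expect_error(theta_from_conditional_probs(0.5, 1), "infinite odds")
})
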