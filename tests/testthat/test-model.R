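small_sim <- function(n = 250, seed = 1, ...)
  simulate_pair_level(n_pairs = n, seed = seed, ...)

sim_spec <- function(...)
  mcm_spec(fixed_terms = c("std_phylo_distance", "guild_overlap"),
           set_defining_vars = c("phylo_bin", "guild_overlap", "habitat",
                                 "occupancy_pairing"),
           sigma_grouping = "by_guild_overlap", ...)

test_that("model spec validates its structure", {
  expect_error(mcm_spec(fixed_terms = "elevation"), "unknown fixed term")
  expect_error(mcm_spec(set_defining_vars = c("phylo_bin", "habitat")),
               "occupancy_pairing")
  # sigma grouping must be resolvable per set
  expect_error(mcm_spec(set_defining_vars = c("phylo_bin",
                                              "occupancy_pairing"),
                        sigma_grouping = "by_habitat"),
               "resolved|resolvable|cannot be resolved")
  # diet pairing is finer than guild overlap, so it resolves the grouping
  expect_s3_class(mcm_spec(set_defining_vars = c("diet_pairing",
                                                 "occupancy_pairing"),
                           sigma_grouping = "by_guild_overlap"),
                  "mcm_spec")
})

test_that("linear predictor uses treatment coding with low/intact
           reference and adds the set intercepts", {
  rec <- data.frame(
    n_A = 8L, n_notA = 42L, n_B = 8L, n_AB = 2L,
    std_phylo_distance = 0,
    guild_overlap = c("low", "medium"),
    habitat = "intact",
    phylo_bin = 1L, diet_pairing = c("x|x", "y|y"),
    occupancy_pairing = "8-8")
  des <- coocmix:::mcm_design(rec, sim_spec())
  beta <- c("(Intercept)" = 0.41, "std_phylo_distance" = -0.10,
            "guild_overlapmedium" = 0.34, "guild_overlaphigh" = 0)
  th <- linear_predictor(des, beta[colnames(des$X)])
  # at standardized distance 0: 0.41 for low overlap, 0.75 for medium
  expect_equal(th[rec$guild_overlap == "low"], 0.41)
  expect_equal(th[rec$guild_overlap == "medium"], 0.75)
  expect_equal(linear_predictor(des, rep(0, ncol(des$X))), c(0, 0))
  u <- seq_len(des$n_set) / 10
  expect_equal(linear_predictor(des, rep(0, ncol(des$X)), u = u),
               u[des$set_idx])
  expect_error(linear_predictor(des, beta[1:2]), "expected")
})

test_that("pointwise log-likelihood matches a per-pair loop oracle", {
  sim <- small_sim(100, seed = 9)
  des <- coocmix:::mcm_design(sim, sim_spec())
  set.seed(2)
  beta <- rnorm(ncol(des$X), 0, 0.3)
  u <- rnorm(des$n_set, 0, 0.5)
  pw <- model_loglik(des, beta, u)
  th <- linear_predictor(des, beta, u)
  ref <- vapply(seq_len(nrow(sim)), function(i)
    nhd_logpmf(sim$n_AB[i],
               pair_counts(sim$n_A[i], sim$n_notA[i], sim$n_B[i]),
               th[i]), numeric(1))
  expect_equal(pw, ref, tolerance = 1e-10)
  # theta = 0 everywhere reduces to the central hypergeometric sum
  pw0 <- model_loglik(des, theta = rep(0, nrow(sim)))
  ref0 <- dhyper(sim$n_AB, sim$n_A, sim$n_notA, sim$n_B, log = TRUE)
  expect_equal(sum(pw0), sum(ref0), tolerance = 1e-8)
  # one-point supports contribute exactly zero
  if (any(des$one_point_support))
    expect_true(all(pw[des$one_point_support] == 0))
  expect_error(model_loglik(des, theta = rep(NA_real_, nrow(sim))),
               "non-finite")
})

test_that("log posterior responds to sigma by the closed-form Normal
           difference", {
  sim <- small_sim(60, seed = 3)
  des <- coocmix:::mcm_design(sim, sim_spec())
  pr <- mcm_priors()
  beta <- rep(0, ncol(des$X))
  u <- rnorm(des$n_set, 0, 0.4)
  s1 <- c(high = 0.5, low = 0.5, medium = 0.5)[des$group_levels]
  s2 <- s1; s2["low"] <- 1.0
  lp1 <- log_posterior(des, beta, u, s1, priors = pr)
  lp2 <- log_posterior(des, beta, u, s2, priors = pr)
  g_low <- which(des$group_levels == "low")
  ulow <- u[des$set_group == g_low]
  expected <- sum(dnorm(ulow, 0, 1.0, log = TRUE)) -
    sum(dnorm(ulow, 0, 0.5, log = TRUE)) +
    coocmix:::log_half_t(1.0, pr$sigma_df, pr$sigma_scale) -
    coocmix:::log_half_t(0.5, pr$sigma_df, pr$sigma_scale)
  expect_equal(lp2 - lp1, expected, tolerance = 1e-10)
  expect_identical(log_posterior(des, beta, u, s1 * 0, priors = pr), -Inf)
})

test_that("split Gelman-Rubin statistic: identical chains give 1, disjoint
           chains blow up, toy value matches hand arithmetic", {
  x <- rnorm(100)
  expect_equal(gelman_rubin(list(x, x, x)), 1)
  expect_gt(gelman_rubin(list(rnorm(100), rnorm(100) + 50)), 10)
  # hand computation on 2 chains x 10 draws (4 half-chains of 5)
  c1 <- c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6)
  c2 <- c(2, 3, 4, 5, 6, 1, 2, 3, 4, 5)
  halves <- list(c1[1:5], c1[6:10], c2[1:5], c2[6:10])
  W <- mean(sapply(halves, var))
  B_over_n <- var(sapply(halves, mean))
  by_hand <- sqrt((4 / 5 * W + B_over_n) / W)
  expect_equal(gelman_rubin(list(c1, c2)), by_hand)
  expect_error(gelman_rubin(list(c1)), "two chains")
  expect_error(gelman_rubin(list(c1, c2[1:5])), "equal length")
})

test_that("posterior summaries report means and central 95% intervals", {
  sim <- small_sim(80, seed = 5)
  fit <- fit_mcm(sim, sim_spec(), chains = 2, steps = 120, warmup = 40,
                 thin = 2, seed = 1, quiet = TRUE)
  # chain geometry: (120 - 40) / 2 = 40 draws per chain
  expect_equal(nrow(fit$beta), 2 * 40)
  expect_equal(fit$n_keep_per_chain, 40)
  s <- posterior_summary(fit)
  expect_true(all(c("mean", "q2.5", "q97.5", "rhat") %in% names(s)))
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  expect_true(all(is.finite(fit$rhat)))
  # large-sample sanity of the interval machinery on known draws
  fake <- fit
  fake$beta <- matrix(rnorm(4000), dimnames = list(NULL, "(Intercept)"))
  fake$u <- matrix(0, 4000, fit$design$n_set)
  fake$sigma <- matrix(1, 4000, fit$design$n_group,
                       dimnames = list(NULL, colnames(fit$sigma)))
  fake$chain <- rep(1:2, each = 2000)
  fake$rhat <- coocmix:::fit_rhat(fake)
  s2 <- posterior_summary(fake)
  b <- s2[s2$parameter == "(Intercept)", ]
  expect_lt(abs(b$mean), 0.05)
  expect_lt(abs(b$q2.5 - qnorm(0.025)), 0.15)
  expect_lt(abs(b$q97.5 - qnorm(0.975)), 0.15)
  # constant draws give a zero-width interval at the value
  fake$beta[] <- 0.7
  s3 <- posterior_summary(fake)
  b3 <- s3[s3$parameter == "(Intercept)", ]
  expect_equal(unname(unlist(b3[c("mean", "q2.5", "q97.5")])),
               c(0.7, 0.7, 0.7))
})

test_that("fits are deterministic under a fixed seed", {
  sim <- small_sim(80, seed = 6)
  f1 <- fit_mcm(sim, sim_spec(), chains = 2, steps = 150, warmup = 50,
                thin = 1, seed = 42, quiet = TRUE)
  f2 <- fit_mcm(sim, sim_spec(), chains = 2, steps = 150, warmup = 50,
                thin = 1, seed = 42, quiet = TRUE)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(f1$pointwise_loglik, f2$pointwise_loglik)
  f3 <- fit_mcm(sim, sim_spec(), chains = 2, steps = 150, warmup = 50,
                thin = 1, seed = 43, quiet = TRUE)
  expect_false(identical(f1$beta, f3$beta))
})

test_that("with a single set and one intercept the posterior concentrates
           on the pooled conditional MLE", {
  set.seed(31)
  n <- 60
  rec <- data.frame(
    n_A = 8L, n_notA = 42L, n_B = 8L,
    n_AB = nhd_sample(pair_counts(8, 42, 8), 0.6, n),
    std_phylo_distance = 0, guild_overlap = "low", habitat = "intact",
    phylo_bin = 1L, diet_pairing = "x|x", occupancy_pairing = "8-8")
  spec1 <- mcm_spec(fixed_terms = character(),
                    set_defining_vars = c("phylo_bin", "occupancy_pairing"),
                    sigma_grouping = "constant")
  fit <- fit_mcm(rec, spec1, chains = 2, steps = 700, warmup = 300,
                 thin = 1, seed = 4, quiet = TRUE)
  # pooled conditional MLE by grid search on the summed log pmf
  grid <- seq(-1, 2, by = 0.001)
  ll <- vapply(grid, function(t)
    sum(nhd_logpmf(rec$n_AB, pair_counts(8, 42, 8), t)), numeric(1))
  pooled_mle <- grid[which.max(ll)]
  theta_draws <- fit$beta[, "(Intercept)"] + fit$u[, 1]
  expect_lt(abs(mean(theta_draws) - pooled_mle), 0.12)
})

test_that("set intercepts shrink from the within-set MLE toward the grand
           mean", {
  sim <- simulate_pair_level(n_pairs = 600, seed = 12)
  spec <- sim_spec()
  fit <- fit_mcm(sim, spec, chains = 2, steps = 500, warmup = 200,
                 thin = 1, seed = 8, quiet = TRUE)
  des <- fit$design
  xb <- colMeans(fit$beta) |> (\(b) drop(des$X %*% b))()
  u_hat <- colMeans(fit$u)
  # pick interior sets: several pairs, non-boundary pooled MLE
  resid_mle <- rep(NA_real_, des$n_set)
  for (s in seq_len(des$n_set)) {
    idx <- which(des$set_idx == s)
    if (length(idx) < 4) next
    grid <- seq(-4, 4, by = 0.01)
    ll <- vapply(grid, function(t) {
      sum(vapply(idx, function(i)
        nhd_logpmf(sim$n_AB[i],
                   pair_counts(sim$n_A[i], sim$n_notA[i], sim$n_B[i]),
                   xb[i] + t), numeric(1)))
    }, numeric(1))
    j <- which.max(ll)
    if (j > 1 && j < length(grid)) resid_mle[s] <- grid[j]
  }
  cand <- which(!is.na(resid_mle) & abs(resid_mle) > 0.15)
  expect_gt(length(cand), 3)
  # shrinkage: posterior mean intercept lies between 0 (the random-effect
  # mean) and the within-set residual MLE for most interior sets
  between <- vapply(cand, function(s) {
    lo <- min(0, resid_mle[s]) - 0.05
    hi <- max(0, resid_mle[s]) + 0.05
    u_hat[s] >= lo && u_hat[s] <= hi &&
      abs(u_hat[s]) <= abs(resid_mle[s]) + 0.05
  }, logical(1))
  expect_gt(mean(between), 0.7)
})
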