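# Independent brute-force oracle for the non-central hypergeometric
# distribution: naive direct summation on the probability scale with
# choose()/exp(), no log-sum-exp, no shared code with the package
# internals. Valid for totals <= 60 and |theta| <= 5.
brute_nhd <- function(n_A, n_notA, n_B, theta) {
  lo <- max(0, n_B - n_notA)
  hi <- min(n_A, n_B)
  n <- lo:hi
  w <- choose(n_A, n) * choose(n_notA, n_B - n) * exp(n * theta)
  list(support = n,
       pmf = w / sum(w),
       log_normalizer = log(sum(w)),
       mean = sum(n * w) / sum(w),
       mode = n[which.max(w)])
}

# Grid-refinement maximizer of the brute-force log-likelihood in theta:
# an independent oracle for the conditional MLE. Repeatedly zooms a
# 41-point grid around the current maximizer until the spacing is tiny.
grid_theta_mle <- function(n_A, n_notA, n_B, n_AB,
                           lo = -20, hi = 20, levels = 9) {
  supp_lo <- max(0, n_B - n_notA)
  supp_hi <- min(n_A, n_B)
  supp <- supp_lo:supp_hi
  lw0 <- log(choose(n_A, supp)) + log(choose(n_notA, n_B - supp))
  ll <- function(th) {
    # log f(n_AB | theta) with the largest exponent factored out so the
    # grid stays finite at extreme theta
    lw <- lw0 + supp * th
    m <- max(lw)
    log(choose(n_A, n_AB) * choose(n_notA, n_B - n_AB)) + n_AB * th -
      (m + log(sum(exp(lw - m))))
  }
  for (l in seq_len(levels)) {
    grid <- seq(lo, hi, length.out = 41)
    vals <- vapply(grid, ll, numeric(1))
    j <- which.max(vals)
    step <- grid[2] - grid[1]
    lo <- grid[j] - step
    hi <- grid[j] + step
  }
  (lo + hi) / 2
}

# random valid pair-count tables with interior (or any) observed counts
random_tables <- function(n, max_total = 60, interior_only = FALSE) {
  out <- vector("list", n)
  i <- 1
  while (i <= n) {
    N <- sample(4:max_total, 1)
    n_A <- sample(1:(N - 1), 1)
    n_B <- sample(1:(N - 1), 1)
    lo <- max(0, n_B - (N - n_A)); hi <- min(n_A, n_B)
    if (interior_only && hi - lo < 2) next
    cand <- if (interior_only) (lo + 1):(hi - 1) else lo:hi
    n_AB <- cand[sample.int(length(cand), 1)]
    out[[i]] <- list(n_A = n_A, n_notA = N - n_A, n_B = n_B, n_AB = n_AB)
    i <- i + 1
  }
  out
}
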