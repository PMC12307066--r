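## Vectorized non-central hypergeometric log-likelihood over many pairs.
##
## The support of each pair is finite and short (at most min(n_A, n_B) + 1
## points), so the per-pair normalizer is an exact log-sum-exp over a
## padded matrix: row i holds the log binomial-coefficient terms of pair i
## over its support, padded with -Inf. Pairs are grouped into support-width
## classes so that the many rare pairs (support of a few points) are not
## padded out to the width of the few common-common pairs; one pointwise
## log-likelihood evaluation is then a handful of vectorized matrix
## operations per class, which is what the MCMC sampler needs.

nhd_batch_context <- function(n_A, n_notA, n_B, n_AB) {
  n_A <- as.integer(n_A); n_notA <- as.integer(n_notA)
  n_B <- as.integer(n_B); n_AB <- as.integer(n_AB)
  stopifnot(length(n_notA) == length(n_A), length(n_B) == length(n_A),
            length(n_AB) == length(n_A))
  if (any(n_A < 0 | n_notA < 0 | n_B < 0 | n_B > n_A + n_notA))
    stop("invalid pair counts in batch", call. = FALSE)
  lo <- pmax(0L, n_B - n_notA)
  hi <- pmin(n_A, n_B)
  if (any(n_AB < lo | n_AB > hi))
    stop("observed n_AB outside support in batch", call. = FALSE)
  width <- hi - lo + 1L
  m <- length(n_A)
  obs_lbc <- lchoose(n_A, n_AB) + lchoose(n_notA, n_B - n_AB)

  # width classes: narrow supports dominate sparse assemblages
  cls <- findInterval(width, c(0L, 3L, 9L, 27L))
  blocks <- lapply(sort(unique(cls)), function(cl) {
    idx <- which(cls == cl)
    wi <- width[idx]
    S <- max(wi)
    nb <- length(idx)
    J <- matrix(rep(seq_len(S) - 1L, each = nb), nb, S)
    Nmat <- lo[idx] + J
    pad <- J >= wi
    LBC <- lchoose(n_A[idx], Nmat) + lchoose(n_notA[idx], n_B[idx] - Nmat)
    LBC[pad] <- -Inf  # padded columns vanish in the normalizer
    Nmat[pad] <- 0L
    list(idx = idx, LBC = LBC, Nmat = Nmat, nb = nb)
  })
  structure(list(blocks = blocks, obs_lbc = obs_lbc, n_AB = n_AB,
                 lo = lo, hi = hi, width = width, m = m),
            class = "nhd_batch_context")
}

## pointwise log pmf of the observed counts at per-pair theta
nhd_batch_loglik <- function(ctx, theta) {
  stopifnot(length(theta) == ctx$m)
  lp0 <- numeric(ctx$m)
  for (b in ctx$blocks) {
    X <- b$LBC + b$Nmat * theta[b$idx]  # theta recycles along rows
    M <- X[cbind(seq_len(b$nb), max.col(X, ties.method = "first"))]
    lp0[b$idx] <- M + log(rowSums(exp(X - M)))
  }
  ctx$obs_lbc + ctx$n_AB * theta - lp0
}
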