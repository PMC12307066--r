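#' Curveball randomization of a binary occurrence matrix
#'
#' Randomizes which sites each species occupies while preserving every
#' row total (site richness) and every column total (species occupancy)
#' exactly. Each trade picks two random rows, takes the symmetric
#' difference of their occupied columns, and reallocates those columns
#' between the two rows at random, keeping each row's count; rows whose
#' occupied columns are nested trade nothing. Reproducible under
#' [set.seed()] or the `seed` argument.
#'
#' The number of trades needed for adequate mixing scales with matrix
#' fill; the default of 50 trades per occupied cell suits desk-scale
#' matrices, while full assemblage-scale analyses warrant on the order
#' of 1e8 trades. See [curveball_mixing_profile()] to justify a choice
#' on your own matrix.
#'
#' @param matrix binary site-by-species matrix.
#' @param n_swaps number of trades; default `50 * sum(matrix)`.
#' @param seed optional integer seed.
#' @return A matrix of the same dimensions, dimnames and margins.
#' @export
curveball_randomize <- function(matrix, n_swaps = NULL, seed = NULL) {
  m <- as.matrix(matrix)
  if (!all(m %in% c(0, 1)))
    stop("curveball requires a binary matrix", call. = FALSE)
  storage.mode(m) <- "integer"
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(m)
  if (nr < 2) return(m)
  if (is.null(n_swaps)) n_swaps <- 50L * sum(m)
  if (n_swaps < 1) stop("n_swaps must be >= 1", call. = FALSE)
  # row-wise occupied-column lists; trades reshuffle symmetric differences
  occ <- apply(m, 1, function(r) which(r == 1L), simplify = FALSE)
  pick <- matrix(sample.int(nr, 2L * n_swaps, replace = TRUE), ncol = 2L)
  same <- pick[, 1] == pick[, 2]
  if (any(same)) pick[same, 2] <- 1L + (pick[same, 2] %% nr)
  for (s in seq_len(n_swaps)) {
    i <- pick[s, 1]; j <- pick[s, 2]
    a <- occ[[i]]; b <- occ[[j]]
    shared <- intersect(a, b)
    only_a <- setdiff(a, shared); only_b <- setdiff(b, shared)
    diffpool <- c(only_a, only_b)
    if (length(only_a) == 0L || length(only_b) == 0L) next
    take <- sample(diffpool, length(only_a))
    occ[[i]] <- c(shared, take)
    occ[[j]] <- c(shared, setdiff(diffpool, take))
  }
  out <- m
  out[] <- 0L
  for (i in seq_len(nr)) out[i, occ[[i]]] <- 1L
  out
}

#' Mixing profile of the curveball randomization
#'
#' Reports, for a grid of trade counts, the mean fraction of occupied
#' cells that moved relative to the original matrix across replicate
#' randomizations. The perturbation rises with the number of trades and
#' plateaus once the chain has mixed; the plateau point justifies using
#' far fewer trades than the full-scale default on small matrices.
#'
#' @param matrix binary site-by-species matrix.
#' @param swap_grid integer vector of trade counts to profile.
#' @param n_reps replicates per grid point.
#' @param seed integer seed.
#' @return Data frame with `n_swaps` and `mean_perturbation` (mean
#'   fraction of presences relocated).
#' @export
curveball_mixing_profile <- function(matrix,
                                     swap_grid = round(sum(matrix) *
                                                         c(1, 2, 5, 10, 20,
                                                           50, 100)),
                                     n_reps = 5, seed = 1) {
  m <- as.matrix(matrix)
  fill <- sum(m)
  pert <- vapply(seq_along(swap_grid), function(g) {
    mean(vapply(seq_len(n_reps), function(r) {
      rm <- curveball_randomize(m, n_swaps = swap_grid[g],
                                seed = seed + g * 1000L + r)
      sum(m == 1L & rm == 0L) / fill
    }, numeric(1)))
  }, numeric(1))
  data.frame(n_swaps = swap_grid, mean_perturbation = pert)
}

#' Null distributions of posterior means under fixed-margin randomization
#'
#' Refits a model to repeatedly randomized occurrence matrices. Each
#' replicate randomizes the matrix with the curveball algorithm (which
#' ignores phylogeny and guilds -- the covariate tables are reused
#' unchanged), rebuilds the pair records, refits the model spec, and
#' stores the posterior means of the fixed effects and random-effect
#' SDs. Disparity between observed estimates and the null distribution
#' indicates that biological structure, not the margins alone, drives
#' the estimate. Replicate seeds are derived from the master seed by a
#' counter; failed replicate fits are recorded and excluded.
#'
#' @param matrix the observed binary site-by-species matrix.
#' @param data_builder function(matrix) returning a pair-record data
#'   frame (typically a closure over [build_pair_records()] with the
#'   observed site, guild and tree tables).
#' @param spec the final [mcm_spec()] to refit.
#' @param n_reps number of randomized datasets (100 is the convention
#'   for assemblage-scale analyses).
#' @param n_swaps trades per randomization (default as in
#'   [curveball_randomize()]).
#' @param seed master seed.
#' @param observed_fit optional `mcm_fit` on the observed data; when
#'   given, the summary table compares observed posterior means with
#'   null quantiles.
#' @param randomize_within optional factor/named vector splitting sites
#'   into blocks (e.g. habitat) randomized separately; default
#'   randomizes the full matrix.
#' @param ... chain geometry passed to [fit_mcm()].
#' @return List of class `mcm_null`: `samples` (replicates x parameters
#'   data frame of posterior means), `n_failed`, and `summary`
#'   (parameter, observed, null mean and 2.5/97.5% quantiles, replicate
#'   count; observed is `NA` without `observed_fit`).
#' @export
null_distribution <- function(matrix, data_builder, spec, n_reps = 100,
                              n_swaps = NULL, seed = 1,
                              observed_fit = NULL,
                              randomize_within = NULL, ...) {
  stopifnot(n_reps >= 1)
  m <- as.matrix(matrix)
  rows <- list(); failed <- 0L
  for (r in seq_len(n_reps)) {
    rm <- if (is.null(randomize_within)) {
      curveball_randomize(m, n_swaps = n_swaps, seed = seed + r)
    } else {
      blocks <- split(rownames(m), randomize_within[rownames(m)])
      out <- m
      for (bi in seq_along(blocks)) {
        sel <- blocks[[bi]]
        out[sel, ] <- curveball_randomize(m[sel, , drop = FALSE],
                                          n_swaps = n_swaps,
                                          seed = seed + r + bi * 100000L)
      }
      out
    }
    res <- tryCatch({
      rec <- data_builder(rm)
      fit <- fit_mcm(rec, spec, seed = seed + 10000L + r, quiet = TRUE, ...)
      s <- posterior_summary(fit)
      stats::setNames(s$mean, s$parameter)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (failed > 0)
    warning(failed, " null replicate fit(s) failed and were excluded")
  if (!length(rows))
    stop("all null replicate fits failed", call. = FALSE)
  params <- names(rows[[1]])
  samples <- as.data.frame(do.call(rbind, lapply(rows, function(z)
    z[params])))
  obs <- if (!is.null(observed_fit)) {
    s <- posterior_summary(observed_fit)
    stats::setNames(s$mean, s$parameter)[params]
  } else rep(NA_real_, length(params))
  summ <- data.frame(
    parameter = params,
    observed = as.numeric(obs),
    null_mean = colMeans(samples),
    null_q2.5 = apply(samples, 2, stats::quantile, 0.025, names = FALSE),
    null_q97.5 = apply(samples, 2, stats::quantile, 0.975, names = FALSE),
    n_reps = nrow(samples), row.names = NULL)
  out <- list(samples = samples, n_failed = failed, summary = summ)
  class(out) <- "mcm_null"
  out
}

#' @export
print.mcm_null <- function(x, ...) {
  cat(sprintf("curveball null distribution: %d replicates (%d failed)\n",
              nrow(x$samples), x$n_failed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
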