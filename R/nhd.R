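#' Occupancy contingency counts for one species pair
#'
#' Bundles the 2x2 occupancy summary of a species pair across the sites of
#' one habitat subset: the number of sites where species A is present
#' (`n_A`), where A is absent (`n_notA`), where species B is present
#' (`n_B`), and optionally the observed number of co-occurrences (`n_AB`,
#' sites where both occur). The total number of sites is `n_A + n_notA`.
#'
#' @param n_A integer, sites occupied by species A.
#' @param n_notA integer, sites not occupied by species A.
#' @param n_B integer, sites occupied by species B.
#' @param n_AB integer or `NA`, observed co-occurrence count. When supplied
#'   it must lie in the support returned by [nhd_support()].
#'
#' @return An object of class `pair_counts`.
#' @examples
#' pair_counts(8, 42, 8, n_AB = 3)
#' @export
pair_counts <- function(n_A, n_notA, n_B, n_AB = NA_integer_) {
  x <- list(n_A = as.integer(n_A), n_notA = as.integer(n_notA),
            n_B = as.integer(n_B), n_AB = as.integer(n_AB))
  class(x) <- "pair_counts"
  validate_pair_counts(x)
  x
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("pair_counts: n_A=%d n_notA=%d n_B=%d n_AB=%s (N=%d sites)\n",
              x$n_A, x$n_notA, x$n_B,
              ifelse(is.na(x$n_AB), "?", as.character(x$n_AB)),
              x$n_A + x$n_notA))
  invisible(x)
}

validate_pair_counts <- function(x, require_n_AB = FALSE) {
  if (!inherits(x, "pair_counts"))
    stop("expected a 'pair_counts' object", call. = FALSE)
  with(x, {
    if (anyNA(c(n_A, n_notA, n_B)))
      stop("n_A, n_notA and n_B must be non-missing integers", call. = FALSE)
    if (n_A < 0 || n_notA < 0 || n_B < 0)
      stop("occupancy counts must be non-negative", call. = FALSE)
    if (n_B > n_A + n_notA)
      stop("n_B exceeds the total number of sites (n_A + n_notA)",
           call. = FALSE)
  })
  if (require_n_AB && is.na(x$n_AB))
    stop("observed co-occurrence count n_AB is required here", call. = FALSE)
  if (!is.na(x$n_AB)) {
    lo <- max(0L, x$n_B - x$n_notA); hi <- min(x$n_A, x$n_B)
    if (x$n_AB < lo || x$n_AB > hi)
      stop(sprintf("n_AB=%d outside support [%d, %d]", x$n_AB, lo, hi),
           call. = FALSE)
  }
  invisible(x)
}

#' Support of the co-occurrence count
#'
#' The number of co-occurrences of a pair is bounded below by
#' `max(0, n_B - n_notA)` (if B occupies more sites than A leaves empty,
#' some overlap is forced) and above by `min(n_A, n_B)`.
#'
#' @param counts a [pair_counts()] object (`n_AB` is ignored).
#' @return Integer vector `c(lo, hi)`.
#' @examples
#' nhd_support(pair_counts(48, 2, 47))  # c(45, 47)
#' @export
nhd_support <- function(counts) {
  validate_pair_counts(counts)
  c(max(0L, counts$n_B - counts$n_notA), min(counts$n_A, counts$n_B))
}

## log binomial-coefficient terms over the full support:
## log C(n_A, n) + log C(n_notA, n_B - n) for n = lo..hi
nhd_log_terms <- function(counts) {
  s <- nhd_support(counts)
  n <- s[1]:s[2]
  lchoose(counts$n_A, n) + lchoose(counts$n_notA, counts$n_B - n)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log normalizing constant of the non-central hypergeometric distribution
#'
#' Computes `log P0(theta)`, the log of the sum of
#' `C(n_A, n) C(n_notA, n_B - n) exp(n * theta)` over the finite support of
#' the co-occurrence count. All arithmetic is in log space (log-gamma
#' binomial coefficients, log-sum-exp), so the result is finite and
#' overflow-free for any finite `theta` and assemblage-scale margins.
#'
#' @inheritParams nhd_support
#' @param theta finite real, the log odds ratio.
#' @return `log P0(theta)`, a scalar.
#' @examples
#' # at theta = 0 the sum collapses to C(N, n_B) (Vandermonde)
#' nhd_log_normalizer(pair_counts(8, 42, 8), 0) == lchoose(50, 8)
#' @export
nhd_log_normalizer <- function(counts, theta) {
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  s <- nhd_support(counts)
  log_sum_exp(nhd_log_terms(counts) + (s[1]:s[2]) * theta)
}

#' Log probability mass of a co-occurrence count
#'
#' Log density of Fisher's non-central hypergeometric distribution: the
#' probability that two species with fixed occupancies `n_A` and `n_B`
#' among `n_A + n_notA` sites co-occur at exactly `n` sites, when the log
#' odds ratio of their association is `theta`. At `theta = 0` this is the
#' central hypergeometric pmf (independent placement); `theta > 0` tilts
#' mass toward aggregation, `theta < 0` toward segregation. The value is
#' unchanged by exchanging the two species' labels.
#'
#' @param n integer co-occurrence count (vectorized). Values outside the
#'   support return `-Inf` rather than an error.
#' @inheritParams nhd_log_normalizer
#' @return Log pmf value(s).
#' @examples
#' exp(nhd_logpmf(0, pair_counts(2, 48, 2), 0))  # 1128/1225
#' @export
nhd_logpmf <- function(n, counts, theta) {
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  s <- nhd_support(counts)
  lp0 <- nhd_log_normalizer(counts, theta)
  out <- rep(-Inf, length(n))
  ok <- n >= s[1] & n <= s[2] & n == round(n)
  if (any(ok)) {
    nn <- n[ok]
    out[ok] <- lchoose(counts$n_A, nn) +
      lchoose(counts$n_notA, counts$n_B - nn) + nn * theta - lp0
  }
  out
}

#' Most likely co-occurrence count
#'
#' Argmax of the non-central hypergeometric pmf over its support. Ties
#' (which occur at `theta` values where the ratio of adjacent pmf values
#' passes through 1) are broken toward the smaller count, so the result is
#' deterministic.
#'
#' For two species each occupying 8 of 50 sites, moving `theta` from -2 to
#' +2 shifts the mode from 0 to 4 co-occurrences; for species occupying
#' only 2 of 50 sites the mode stays at 0 over the same range -- rare
#' species are unlikely to co-occur regardless of association strength.
#'
#' @inheritParams nhd_log_normalizer
#' @return Integer, the modal co-occurrence count.
#' @examples
#' nhd_mode(pair_counts(8, 42, 8), 2)   # 4
#' nhd_mode(pair_counts(8, 42, 8), -2)  # 0
#' @export
nhd_mode <- function(counts, theta) {
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  s <- nhd_support(counts)
  supp <- s[1]:s[2]
  lp <- nhd_log_terms(counts) + supp * theta
  supp[which.max(lp)]  # which.max returns the first (smallest n) on ties
}

#' Mean co-occurrence count under the non-central hypergeometric model
#'
#' Expected value `sum(n * pmf(n))` over the finite support. The mean is
#' strictly increasing in `theta` whenever the support has more than one
#' point, which is what makes the conditional maximum-likelihood equation
#' `E[N | theta] = n_AB` solvable by bracketed root-finding.
#'
#' @inheritParams nhd_log_normalizer
#' @return The expected co-occurrence count.
#' @examples
#' nhd_mean(pair_counts(8, 42, 8), 0)  # 8 * 8 / 50
#' @export
nhd_mean <- function(counts, theta) {
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  s <- nhd_support(counts)
  supp <- s[1]:s[2]
  lp <- nhd_log_terms(counts) + supp * theta
  w <- exp(lp - max(lp))
  sum(supp * w) / sum(w)
}

#' Draw co-occurrence counts from the non-central hypergeometric pmf
#'
#' Exact sampling by inverse-CDF over the finite support, using R's global
#' random number stream (seed with [set.seed()] for reproducibility).
#'
#' @inheritParams nhd_log_normalizer
#' @param n number of draws.
#' @return Integer vector of length `n`.
#' @export
nhd_sample <- function(counts, theta, n = 1) {
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  s <- nhd_support(counts)
  supp <- s[1]:s[2]
  if (length(supp) == 1L) return(rep(supp, n))
  lp <- nhd_log_terms(counts) + supp * theta
  p <- exp(lp - max(lp))
  cdf <- cumsum(p) / sum(p)
  supp[findInterval(stats::runif(n), cdf) + 1L]
}

#' Conditional maximum-likelihood estimate of the association parameter
#'
#' Maximizes the non-central hypergeometric likelihood of the observed
#' co-occurrence count `n_AB` over `theta`, which is equivalent to solving
#' the mean equation `E[N | theta] = n_AB`. The solution is found by
#' bisection on `theta` in `[-50, 50]` to an absolute tolerance of 1e-8
#' after boundary screening: when `n_AB` sits on the lower (upper) edge of
#' a support with more than one point the likelihood increases without
#' bound as `theta` decreases (increases), so the estimate is flagged as
#' `neg_infinite` (`pos_infinite`) rather than carrying a floating
#' infinity into downstream arithmetic. A single observation of a
#' non-overlapping pair is therefore, by itself, uninformative about how
#' negative the association is. When the support has a single point the
#' count is forced by the margins, `theta` carries no information, and the
#' estimate is flagged `undefined`.
#'
#' @param counts a [pair_counts()] object with `n_AB` observed.
#' @return A list of class `theta_estimate` with fields `theta` (finite
#'   real or `NA` on a boundary), `boundary` (one of `"finite"`,
#'   `"neg_infinite"`, `"pos_infinite"`, `"undefined"`) and
#'   `loglik_at_max` (log-likelihood at the estimate; the supremum value 0
#'   on a boundary, and 0 for a one-point support).
#' @examples
#' theta_mle(pair_counts(10, 10, 10, n_AB = 5))$theta  # 0
#' theta_mle(pair_counts(8, 42, 8, n_AB = 0))$boundary  # "neg_infinite"
#' @export
theta_mle <- function(counts) {
  validate_pair_counts(counts, require_n_AB = TRUE)
  s <- nhd_support(counts)
  out <- list(theta = NA_real_, boundary = "finite", loglik_at_max = NA_real_)
  class(out) <- "theta_estimate"
  if (s[1] == s[2]) {
    out$boundary <- "undefined"
    out$loglik_at_max <- 0
    return(out)
  }
  if (counts$n_AB == s[1]) {
    out$boundary <- "neg_infinite"
    out$loglik_at_max <- 0  # sup of the likelihood as theta -> -Inf
    return(out)
  }
  if (counts$n_AB == s[2]) {
    out$boundary <- "pos_infinite"
    out$loglik_at_max <- 0
    return(out)
  }
  f <- function(th) nhd_mean(counts, th) - counts$n_AB
  lo <- -50; hi <- 50
  # E[N|theta] is strictly increasing, so the root is bracketed
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  out$theta <- (lo + hi) / 2
  out$loglik_at_max <- nhd_logpmf(counts$n_AB, counts, out$theta)
  out
}

#' @export
print.theta_estimate <- function(x, ...) {
  if (x$boundary == "finite")
    cat(sprintf("theta_estimate: theta = %.6f (loglik %.4f)\n",
                x$theta, x$loglik_at_max))
  else
    cat(sprintf("theta_estimate: boundary case '%s'\n", x$boundary))
  invisible(x)
}

#' Association parameter from conditional occupancy probabilities
#'
#' The log odds ratio `theta = log(odds(B | A present) / odds(B | A
#' absent))`: how the presence of species A changes the odds that species
#' B occupies a site. Antisymmetric under exchanging the two arguments.
#'
#' @param p_B_given_A,p_B_given_notA probabilities strictly in (0, 1) that
#'   species B occupies a site given that species A is present / absent.
#' @return The log odds ratio, a finite real.
#' @examples
#' theta_from_conditional_probs(0.8, 0.5)  # log 4
#' @export
theta_from_conditional_probs <- function(p_B_given_A, p_B_given_notA) {
  if (any(c(p_B_given_A, p_B_given_notA) <= 0) ||
      any(c(p_B_given_A, p_B_given_notA) >= 1))
    stop("probabilities at 0 or 1 imply infinite odds; must be in (0, 1)",
         call. = FALSE)
  log(p_B_given_A * (1 - p_B_given_notA)) -
    log((1 - p_B_given_A) * p_B_given_notA)
}
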