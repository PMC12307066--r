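#' PSIS-LOO expected log predictive density
#'
#' Estimates the expected log pointwise predictive density (ELPD), an
#' out-of-sample prediction accuracy measure, from a draws-by-pairs
#' pointwise log-likelihood matrix by Pareto-smoothed importance
#' sampling. For each pair the leave-one-out importance ratios are the
#' reciprocal likelihoods; the largest 20% of log ratios are replaced by
#' expected order statistics of a generalized Pareto distribution fitted
#' to the tail (Zhang-Stephens profile estimator), truncated at the raw
#' maximum. The tail shape estimate `k` is reported per pair; values
#' above 0.7 indicate an unreliable importance-sampling estimate and are
#' flagged. `elpd` is the sum of the pointwise values and its standard
#' error is `sqrt(n * var(pointwise))`.
#'
#' @param x a draws-by-pairs pointwise log-likelihood matrix, or an
#'   `mcm_fit` (its `pointwise_loglik` is used). At least 100 draws.
#' @param tail_frac fraction of draws treated as the Pareto tail.
#' @return A list of class `elpd_loo`: `elpd`, `se`, `pointwise`
#'   (per-pair vector), `pareto_k`, `n_flagged`.
#' @export
elpd_psis_loo <- function(x, tail_frac = 0.2) {
  ll <- if (inherits(x, "mcm_fit")) x$pointwise_loglik else as.matrix(x)
  if (!all(is.finite(ll)))
    stop("pointwise log-likelihood matrix has non-finite entries",
         call. = FALSE)
  S <- nrow(ll); n <- ncol(ll)
  if (S < 100)
    stop("need at least 100 draws for PSIS-LOO", call. = FALSE)
  col_rng <- apply(ll, 2, function(z) diff(range(z)))
  if (all(col_rng == 0)) {
    warning("degenerate posterior (identical draws): returning plain ",
            "pointwise log-likelihood")
    pw <- ll[1, ]
    out <- list(elpd = sum(pw), se = sqrt(n * stats::var(pw)),
                pointwise = pw, pareto_k = rep(NA_real_, n), n_flagged = 0L)
    class(out) <- "elpd_loo"
    return(out)
  }
  M <- ceiling(tail_frac * S)
  pw <- numeric(n); pk <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    if (diff(range(lw)) == 0) {
      # flat ratios: plain Monte-Carlo average
      pw[i] <- log_sum_exp(ll[, i]) - log(S)
      next
    }
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1):S]
    cut <- lw[ord[S - M]]
    exc <- exp(lw[tail_ids]) - exp(cut)
    pos <- exc > 0  # ties with the cutoff carry no tail information
    if (sum(pos) >= 5) {
      gp <- gpd_fit(sort(exc[pos]))
      pk[i] <- gp$k
      np <- sum(pos)
      p <- (seq_len(np) - 0.5) / np
      q <- exp(cut) + gpd_quantile(p, gp$k, gp$sigma)
      sm <- pmin(log(q), max(lw))  # never exceed the raw maximum ratio
      pos_ids <- tail_ids[pos]
      lw[pos_ids[order(lw[pos_ids])]] <- sm
    }
    # normalized self-importance estimate of the loo predictive density
    pw[i] <- log_sum_exp(ll[, i] + lw) - log_sum_exp(lw)
  }
  out <- list(elpd = sum(pw), se = sqrt(n * stats::var(pw)), pointwise = pw,
              pareto_k = pk, n_flagged = sum(pk > 0.7, na.rm = TRUE))
  class(out) <- "elpd_loo"
  out
}

#' @export
print.elpd_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO elpd = %.2f (se %.2f) over %d pairs; %d pair(s) ",
              x$elpd, x$se, length(x$pointwise), x$n_flagged))
  cat("with Pareto k > 0.7\n")
  invisible(x)
}

## Zhang & Stephens (2009) profile-likelihood fit of the generalized
## Pareto distribution to sorted exceedances, with the weak prior
## regularization of the shape used by standard PSIS implementations.
gpd_fit <- function(x) {
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  q25 <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * q25)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  Lp <- n * (log(bs / ks) + ks - 1)
  w <- exp(Lp - log_sum_exp(Lp))
  b <- sum(bs * w)
  k <- -mean(log1p(-b * x))
  sigma <- k / b
  k <- (n * k + 10 * 0.5) / (n + 10)  # shrink shape toward 0.5
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma * expm1(-k * log1p(-p)) / k
}

#' Compare two fitted models by ELPD difference
#'
#' Computes `delta_e = elpd_a - elpd_b` from the pointwise PSIS-LOO
#' values, its standard error `s_delta` from the pointwise differences
#' (`sqrt(n * var(diff))`), and the evidence score
#' `z_delta = delta_e / s_delta`. Both fits must be evaluated on the
#' same pairs in the same order. These z-scores are informal evidence
#' summaries, not formal tests: each species enters many pairs, so the
#' pointwise contributions are not independent.
#'
#' @param fit_a,fit_b `mcm_fit` objects or `elpd_loo` results.
#' @return A list of class `elpd_comparison`: `elpd_a`, `elpd_b`,
#'   `se_a`, `se_b`, `delta_e`, `se_delta`, `z_delta`, `degenerate`
#'   (TRUE when the pointwise vectors are identical and 0/0 was reported
#'   as 0) and the per-pair `pareto_k` diagnostics of both fits.
#' @export
compare_models <- function(fit_a, fit_b) {
  la <- if (inherits(fit_a, "elpd_loo")) fit_a else elpd_psis_loo(fit_a)
  lb <- if (inherits(fit_b, "elpd_loo")) fit_b else elpd_psis_loo(fit_b)
  if (length(la$pointwise) != length(lb$pointwise))
    stop("models were evaluated on different numbers of pairs",
         call. = FALSE)
  d <- la$pointwise - lb$pointwise
  delta <- sum(d)
  se_d <- sqrt(length(d) * stats::var(d))
  degen <- se_d == 0
  out <- list(elpd_a = la$elpd, elpd_b = lb$elpd, se_a = la$se, se_b = lb$se,
              delta_e = delta, se_delta = se_d,
              z_delta = if (degen) 0 else delta / se_d,
              degenerate = degen,
              pareto_k_a = la$pareto_k, pareto_k_b = lb$pareto_k)
  class(out) <- "elpd_comparison"
  out
}

#' @export
print.elpd_comparison <- function(x, ...) {
  cat(sprintf("delta ELPD = %.2f (se %.2f), z = %.2f%s\n", x$delta_e,
              x$se_delta, x$z_delta,
              if (x$degenerate) " [identical pointwise values]" else ""))
  invisible(x)
}

#' Default random-effects structure candidates
#'
#' The default random-structure search space: co-occurrence sets
#' defined by phylogenetic-distance bin,
#' diet pairing, habitat and occupancy pairing; the random-intercept SD
#' constant, varying by dietary-guild overlap, or varying by habitat;
#' and diet pairing included or not as an additional random effect. All
#' candidates keep occupancy pairing among the set-defining variables.
#' Override by passing your own list of [mcm_spec()]s to
#' [select_structure()].
#'
#' @param fixed_terms fixed part used while the random structures are
#'   compared (the full structure by default).
#' @param include_diet_re also include variants with the diet-pairing
#'   random effect (doubles the catalogue).
#' @return List of `mcm_spec` objects.
#' @export
default_random_specs <- function(fixed_terms = full_fixed_terms(),
                                 include_diet_re = FALSE) {
  sets <- c("phylo_bin", "diet_pairing", "habitat", "occupancy_pairing")
  base <- lapply(c("constant", "by_guild_overlap", "by_habitat"),
                 function(sg) mcm_spec(fixed_terms = fixed_terms,
                                       set_defining_vars = sets,
                                       sigma_grouping = sg))
  if (include_diet_re)
    base <- c(base, lapply(c("constant", "by_guild_overlap", "by_habitat"),
                           function(sg)
                             mcm_spec(fixed_terms = fixed_terms,
                                      set_defining_vars = sets,
                                      sigma_grouping = sg,
                                      include_diet_pairing_re = TRUE)))
  base
}

#' All-subsets fixed-structure candidates
#'
#' Every subset of the three main effects (standardized phylogenetic
#' distance, guild overlap, habitat), plus the full model with all
#' two-way interactions.
#'
#' @return List of character vectors of fixed terms.
#' @export
default_fixed_terms <- function() {
  mains <- c("std_phylo_distance", "guild_overlap", "habitat")
  subsets <- unlist(lapply(0:3, function(k)
    utils::combn(mains, k, simplify = FALSE)), recursive = FALSE)
  c(subsets, list(full_fixed_terms()))
}

#' @rdname default_fixed_terms
#' @export
full_fixed_terms <- function() {
  c("std_phylo_distance", "guild_overlap", "habitat",
    "std_phylo_distance:guild_overlap", "std_phylo_distance:habitat",
    "guild_overlap:habitat")
}

#' Two-step selection of random then fixed structure
#'
#' Step 1 fits every candidate random structure with the full fixed
#' structure (all main effects and two-way interactions) and keeps the
#' one with the highest PSIS-LOO ELPD. Step 2 holds that random
#' structure fixed and fits every candidate fixed structure, again
#' keeping the highest ELPD. Candidates whose fit fails convergence
#' (any split-Rhat above `rhat_max`) are recorded in the trace, warned
#' about, and excluded from the choice. The trace records every fit's
#' label, ELPD, standard error and seed.
#'
#' @param records pair-record data frame.
#' @param random_specs list of [mcm_spec()] candidates for step 1.
#' @param fixed_terms_list list of character vectors for step 2.
#' @param seed master seed. All candidates within a step share one seed
#'   (step 2 uses `seed + 1`): with common data and seed the
#'   Monte-Carlo error of the ELPD estimates is partially shared across
#'   candidates, stabilizing the differences that drive the choice.
#' @param rhat_max convergence threshold for candidate exclusion.
#' @param fixed_stage_args optional named list of [fit_mcm()] arguments
#'   used for the step-2 (fixed-structure) fits only, overriding `...`.
#'   Nested fixed structures differ by fractions of an ELPD unit per
#'   removed term, so step 2 often warrants more retained draws than the
#'   coarser random-structure comparison of step 1.
#' @param refit_best refit the winning spec (from its recorded seed, so
#'   the refit is exact) and return it as `best_fit`; set `FALSE` to
#'   save one fit when only the chosen structure is needed.
#' @param ... chain geometry and priors passed to [fit_mcm()].
#' @return List of class `mcm_selection`: `best_spec`, `best_fit`,
#'   `trace` (data frame: step, label, elpd, se, max_rhat, converged,
#'   seed, selected).
#' @export
select_structure <- function(records,
                             random_specs = default_random_specs(),
                             fixed_terms_list = default_fixed_terms(),
                             seed = 1, rhat_max = 1.1,
                             fixed_stage_args = NULL, refit_best = TRUE,
                             ...) {
  if (!length(random_specs) || !length(fixed_terms_list))
    stop("candidate lists must be non-empty", call. = FALSE)
  for (sp in random_specs)
    if (!("occupancy_pairing" %in% sp$set_defining_vars))
      stop("all random candidates must keep occupancy_pairing", call. = FALSE)

  base_args <- list(...)
  fit_one <- function(spec, step, sd) {
    fa <- base_args
    if (step == "fixed" && !is.null(fixed_stage_args))
      fa[names(fixed_stage_args)] <- fixed_stage_args
    do.call(fit_mcm, c(list(records = records, spec = spec,
                            seed = sd, quiet = TRUE), fa))
  }
  # candidate fits are summarized and discarded (their pointwise
  # log-likelihood matrices dominate memory); the winner is refit at the
  # end from its recorded seed, which reproduces it exactly
  run_one <- function(spec, step, sd) {
    fit <- fit_one(spec, step, sd)
    loo <- elpd_psis_loo(fit)
    mx <- max(fit$rhat, na.rm = TRUE)
    list(spec = spec,
         row = data.frame(step = step, label = spec$label, elpd = loo$elpd,
                          se = loo$se, max_rhat = mx,
                          converged = mx <= rhat_max, seed = sd,
                          selected = FALSE))
  }

  # all candidates within a step share one seed: with common random
  # numbers the Monte-Carlo noise of the ELPD estimates is strongly
  # correlated across candidates, so their differences -- which drive
  # the choice -- are far less noisy than with independent seeds
  trace <- list(); fits <- list(); sd0 <- seed
  for (j in seq_along(random_specs)) {
    r <- run_one(random_specs[[j]], "random", sd0)
    trace[[length(trace) + 1L]] <- r$row
    fits[[length(fits) + 1L]] <- r
  }
  ok <- vapply(fits, function(f) f$row$converged, logical(1))
  if (!all(ok))
    warning(sum(!ok), " random-structure candidate(s) excluded for ",
            "non-convergence")
  if (!any(ok))
    stop("no random-structure candidate converged", call. = FALSE)
  elpds <- vapply(fits, function(f) ifelse(f$row$converged, f$row$elpd, -Inf),
                  numeric(1))
  jbest <- which.max(elpds)
  trace[[jbest]]$selected <- TRUE
  best_random <- random_specs[[jbest]]
  fits <- NULL

  sd1 <- sd0 + 1L
  fits2 <- list()
  for (j in seq_along(fixed_terms_list)) {
    sp <- mcm_spec(fixed_terms = fixed_terms_list[[j]],
                   set_defining_vars = best_random$set_defining_vars,
                   sigma_grouping = best_random$sigma_grouping,
                   include_diet_pairing_re =
                     best_random$include_diet_pairing_re)
    r <- run_one(sp, "fixed", sd1)
    trace[[length(trace) + 1L]] <- r$row
    fits2[[length(fits2) + 1L]] <- r
  }
  ok2 <- vapply(fits2, function(f) f$row$converged, logical(1))
  if (!all(ok2))
    warning(sum(!ok2), " fixed-structure candidate(s) excluded for ",
            "non-convergence")
  if (!any(ok2))
    stop("no fixed-structure candidate converged", call. = FALSE)
  elpds2 <- vapply(fits2, function(f)
    ifelse(f$row$converged, f$row$elpd, -Inf), numeric(1))
  kbest <- which.max(elpds2)
  trace[[length(random_specs) + kbest]]$selected <- TRUE
  best_spec <- fits2[[kbest]]$spec
  fits2 <- NULL

  out <- list(best_spec = best_spec,
              best_fit = if (refit_best) fit_one(best_spec, "fixed", sd1)
                         else NULL,
              trace = do.call(rbind, trace))
  class(out) <- "mcm_selection"
  out
}

#' @export
print.mcm_selection <- function(x, ...) {
  cat("two-step structure selection; best:", x$best_spec$label, "\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

## terms removable from a fixed structure while respecting hierarchy:
## an interaction is always removable; a main effect only when it does
## not appear in any retained interaction
removable_terms <- function(fixed_terms) {
  is_int <- grepl(":", fixed_terms, fixed = TRUE)
  ints <- fixed_terms[is_int]
  mains <- fixed_terms[!is_int]
  in_int <- vapply(mains, function(m)
    any(vapply(strsplit(ints, ":", fixed = TRUE),
               function(ps) m %in% ps, logical(1))), logical(1))
  c(ints, mains[!in_int])
}

#' Evidence z-scores for each term of a final model
#'
#' Refits the final model with one fixed term removed at a time
#' (interactions before their main effects, so the hierarchy is
#' respected) and, when the random-intercept SD varies by group, with
#' the SD held constant, and reports `z_delta = delta_e / s_delta` of
#' full minus nested for every comparison. Positive z favours keeping
#' the term.
#'
#' @param fit the final `mcm_fit`.
#' @param records the pair records the model was fitted to.
#' @param seed seed reused for every refit.
#' @param ... chain geometry passed to [fit_mcm()].
#' @return Data frame: `term`, `delta_e`, `se_delta`, `z_delta`.
#' @export
nested_term_zscores <- function(fit, records, seed = 1, ...) {
  spec <- fit$spec
  loo_full <- elpd_psis_loo(fit)
  rows <- list()
  for (tm in removable_terms(spec$fixed_terms)) {
    sp <- mcm_spec(fixed_terms = setdiff(spec$fixed_terms, tm),
                   set_defining_vars = spec$set_defining_vars,
                   sigma_grouping = spec$sigma_grouping,
                   include_diet_pairing_re = spec$include_diet_pairing_re)
    f2 <- fit_mcm(records, sp, seed = seed, quiet = TRUE, ...)
    cmp <- compare_models(loo_full, elpd_psis_loo(f2))
    rows[[length(rows) + 1L]] <-
      data.frame(term = tm, delta_e = cmp$delta_e,
                 se_delta = cmp$se_delta, z_delta = cmp$z_delta)
  }
  if (spec$sigma_grouping != "constant") {
    sp <- mcm_spec(fixed_terms = spec$fixed_terms,
                   set_defining_vars = spec$set_defining_vars,
                   sigma_grouping = "constant",
                   include_diet_pairing_re = spec$include_diet_pairing_re)
    f2 <- fit_mcm(records, sp, seed = seed, quiet = TRUE, ...)
    cmp <- compare_models(loo_full, elpd_psis_loo(f2))
    rows[[length(rows) + 1L]] <-
      data.frame(term = paste0("sigma_", spec$sigma_grouping,
                               " -> constant"),
                 delta_e = cmp$delta_e, se_delta = cmp$se_delta,
                 z_delta = cmp$z_delta)
  }
  do.call(rbind, rows)
}
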