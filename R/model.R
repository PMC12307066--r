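#' Declare a mixed-effects co-occurrence model structure
#'
#' A model spec says which pair covariates enter the fixed part of the
#' linear predictor for theta, which variables define the co-occurrence
#' sets that receive random intercepts, whether the random-intercept
#' standard deviation is constant or varies by dietary-guild overlap or
#' habitat, and whether diet pairing contributes an additional random
#' intercept. Occupancy pairing must always be among the set-defining
#' variables. When the standard deviation varies by a grouping variable,
#' that variable must resolve to a single level within every set, which
#' is guaranteed when it is itself set-defining.
#'
#' @param fixed_terms character vector of fixed-effect terms drawn from
#'   `"std_phylo_distance"`, `"guild_overlap"`, `"habitat"` and their
#'   `":"` interactions. An intercept is always included; `character(0)`
#'   gives an intercept-only fixed part.
#' @param set_defining_vars passed to [assign_cooc_sets()]; must contain
#'   `"occupancy_pairing"`.
#' @param sigma_grouping `"constant"`, `"by_guild_overlap"` or
#'   `"by_habitat"`.
#' @param include_diet_pairing_re logical; add a second random intercept
#'   indexed by the diet-pairing label.
#' @param label optional short name used in selection traces.
#' @return An object of class `mcm_spec`.
#' @export
mcm_spec <- function(fixed_terms = c("std_phylo_distance", "guild_overlap",
                                     "habitat"),
                     set_defining_vars = c("phylo_bin", "diet_pairing",
                                           "habitat", "occupancy_pairing"),
                     sigma_grouping = c("constant", "by_guild_overlap",
                                        "by_habitat"),
                     include_diet_pairing_re = FALSE,
                     label = NULL) {
  sigma_grouping <- match.arg(sigma_grouping)
  mains <- c("std_phylo_distance", "guild_overlap", "habitat")
  for (tm in fixed_terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% mains))
      stop("unknown fixed term: ", tm, call. = FALSE)
  }
  if (!("occupancy_pairing" %in% set_defining_vars))
    stop("set_defining_vars must contain occupancy_pairing", call. = FALSE)
  grp_var <- switch(sigma_grouping, constant = NULL,
                    by_guild_overlap = "guild_overlap",
                    by_habitat = "habitat")
  if (!is.null(grp_var) && !(grp_var %in% set_defining_vars) &&
      !(grp_var == "guild_overlap" && "diet_pairing" %in% set_defining_vars))
    stop("sigma grouping variable '", grp_var,
         "' cannot be resolved per set: include it (or a finer variable) ",
         "among set_defining_vars", call. = FALSE)
  structure(list(fixed_terms = fixed_terms,
                 set_defining_vars = sort(set_defining_vars),
                 sigma_grouping = sigma_grouping,
                 include_diet_pairing_re = include_diet_pairing_re,
                 label = label %||% spec_auto_label(fixed_terms,
                                                    sigma_grouping,
                                                    include_diet_pairing_re)),
            class = "mcm_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spec_auto_label <- function(fixed_terms, sigma_grouping, diet_re) {
  ft <- if (length(fixed_terms)) paste(fixed_terms, collapse = "+") else "1"
  paste0("fix(", ft, ")|sigma_", sigma_grouping,
         if (diet_re) "|dietRE" else "")
}

#' @export
print.mcm_spec <- function(x, ...) {
  cat("mcm_spec:", x$label, "\n")
  cat("  sets defined by:", paste(x$set_defining_vars, collapse = ", "), "\n")
  invisible(x)
}

#' Default weakly informative priors
#'
#' Normal(0, 5^2) on each fixed-effect coefficient and half-Student-t
#' with 3 degrees of freedom and scale 2.5 on every random-effect
#' standard deviation. On the log-odds scale of theta these are broad:
#' a coefficient of 5 corresponds to an odds ratio of ~148.
#'
#' @param beta_sd fixed-effect prior SD.
#' @param sigma_df,sigma_scale half-t parameters for random-effect SDs.
#' @return A list of prior settings.
#' @export
mcm_priors <- function(beta_sd = 5, sigma_df = 3, sigma_scale = 2.5) {
  list(beta_sd = beta_sd, sigma_df = sigma_df, sigma_scale = sigma_scale)
}

log_half_t <- function(sigma, df, scale) {
  log(2) + stats::dt(sigma / scale, df = df, log = TRUE) - log(scale)
}

## Prepare the model matrices and index vectors for a record table.
## Reference levels: low guild overlap, intact habitat (treatment coding),
## so the intercept is the expected theta for a low-overlap pair in
## intact habitat at standardized distance 0 and average random effect.
mcm_design <- function(records, spec) {
  stopifnot(inherits(spec, "mcm_spec"))
  need <- c("n_A", "n_notA", "n_B", "n_AB")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack count columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0) stop("no pair records", call. = FALSE)
  df <- records
  if ("guild_overlap" %in% names(df))
    df$guild_overlap <- factor(df$guild_overlap,
                               levels = c("low", "medium", "high"))
  if ("habitat" %in% names(df))
    df$habitat <- factor(df$habitat, levels = c("intact", "altered"))
  fml <- if (length(spec$fixed_terms))
    stats::as.formula(paste("~", paste(spec$fixed_terms, collapse = "+")))
  else ~1
  X <- stats::model.matrix(fml, data = df)
  X <- X[, !duplicated(colnames(X)), drop = FALSE]

  if (all(spec$set_defining_vars %in% names(df))) {
    # always re-derive set_id from the spec's own defining variables so
    # candidate specs with different set definitions partition correctly
    df <- assign_cooc_sets(df, defining_vars = spec$set_defining_vars)
  } else if (!("set_id" %in% names(df))) {
    stop("records lack both set_id and the set-defining columns ",
         paste(setdiff(spec$set_defining_vars, names(df)), collapse = ", "),
         call. = FALSE)
  }
  set_fac <- factor(df$set_id)
  set_idx <- as.integer(set_fac)
  n_set <- nlevels(set_fac)

  grp_var <- switch(spec$sigma_grouping, constant = NULL,
                    by_guild_overlap = "guild_overlap",
                    by_habitat = "habitat")
  if (is.null(grp_var)) {
    set_group <- rep(1L, n_set)
    group_levels <- "all"
  } else {
    lv_by_set <- tapply(as.character(df[[grp_var]]), set_idx,
                        function(z) unique(z))
    bad <- vapply(lv_by_set, length, 1L) > 1L
    if (any(bad))
      stop("sigma grouping variable '", grp_var,
           "' is not constant within every co-occurrence set", call. = FALSE)
    lv <- vapply(lv_by_set, `[[`, "", 1L)
    gf <- factor(lv)
    set_group <- as.integer(gf)
    group_levels <- levels(gf)
  }

  diet_idx <- NULL; n_diet <- 0L; diet_levels <- character()
  if (spec$include_diet_pairing_re) {
    if (!("diet_pairing" %in% names(df)))
      stop("records lack diet_pairing, required by the model spec",
           call. = FALSE)
    dfac <- factor(df$diet_pairing)
    diet_idx <- as.integer(dfac)
    n_diet <- nlevels(dfac)
    diet_levels <- levels(dfac)
  }

  # set-level covariate values for columns constant within every set:
  # those columns admit an exact Gibbs recentering move between beta and
  # the set intercepts (the likelihood is invariant under the shift)
  Xset <- matrix(NA_real_, n_set, ncol(X),
                 dimnames = list(NULL, colnames(X)))
  recenter <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    rng_j <- tapply(X[, j], set_idx, function(z) diff(range(z)))
    if (all(rng_j == 0)) {
      recenter[j] <- TRUE
      Xset[, j] <- tapply(X[, j], set_idx, function(z) z[1])
    }
  }

  ctx <- nhd_batch_context(df$n_A, df$n_notA, df$n_B, df$n_AB)
  list(X = X, Xset = Xset, recenter_cols = which(recenter),
       ctx = ctx, records = df,
       set_idx = set_idx, n_set = n_set, set_levels = levels(set_fac),
       set_group = set_group, n_group = length(group_levels),
       group_levels = group_levels,
       diet_idx = diet_idx, n_diet = n_diet, diet_levels = diet_levels,
       one_point_support = ctx$width == 1L,
       spec = spec)
}

#' Linear predictor for theta
#'
#' `theta_i = x_i' beta + u_set(i) + v_dietpair(i)`: the fixed part plus
#' the pair's co-occurrence-set random intercept and, when enabled, its
#' diet-pairing random intercept.
#'
#' @param design the prepared design from `mcm_design()` (internal; any
#'   fit's `$design` works).
#' @param beta numeric coefficient vector matching `colnames(design$X)`.
#' @param u per-set random intercepts (default all zero).
#' @param v per-diet-pairing intercepts (default all zero).
#' @return Numeric vector of per-pair theta values.
#' @export
linear_predictor <- function(design, beta, u = NULL, v = NULL) {
  if (length(beta) != ncol(design$X))
    stop("beta has length ", length(beta), ", expected ", ncol(design$X),
         call. = FALSE)
  th <- unname(drop(design$X %*% beta))
  if (!is.null(u)) {
    if (length(u) != design$n_set)
      stop("u has length ", length(u), ", expected ", design$n_set,
           call. = FALSE)
    th <- th + u[design$set_idx]
  }
  if (!is.null(v)) {
    if (design$n_diet == 0L)
      stop("model has no diet-pairing random effect", call. = FALSE)
    th <- th + v[design$diet_idx]
  }
  th
}

#' Pointwise model log-likelihood
#'
#' Element `i` is the non-central hypergeometric log pmf of the observed
#' co-occurrence count of pair `i` at its linear-predictor theta. Pairs
#' whose support has a single point contribute exactly 0 (their count is
#' forced by the margins); they are flagged in the design and retained.
#'
#' @inheritParams linear_predictor
#' @param theta optional explicit per-pair theta vector; otherwise built
#'   from `beta`, `u`, `v`.
#' @return Numeric vector, one log-likelihood per pair.
#' @export
model_loglik <- function(design, beta = NULL, u = NULL, v = NULL,
                         theta = NULL) {
  if (is.null(theta)) theta <- linear_predictor(design, beta, u, v)
  if (any(!is.finite(theta))) {
    i <- which(!is.finite(theta))[1]
    stop("non-finite theta for pair ", i, " (set '",
         design$set_levels[design$set_idx[i]], "')", call. = FALSE)
  }
  nhd_batch_loglik(design$ctx, theta)
}

#' Log posterior density (unnormalized)
#'
#' Sum of the pointwise model log-likelihood, Normal(0, sigma_group) log
#' densities of the set intercepts (and Normal(0, sigma_diet) of the
#' diet-pairing intercepts when present), and the log priors on the
#' fixed effects and standard deviations.
#'
#' @inheritParams linear_predictor
#' @param sigma per-group random-effect SDs (length `design$n_group`).
#' @param sigma_diet SD of the diet-pairing intercepts, if enabled.
#' @param priors from [mcm_priors()].
#' @return Scalar log posterior density up to a constant.
#' @export
log_posterior <- function(design, beta, u, sigma, v = NULL,
                          sigma_diet = NULL, priors = mcm_priors()) {
  if (any(sigma <= 0)) return(-Inf)
  ll <- sum(model_loglik(design, beta, u, v))
  lp <- ll +
    sum(stats::dnorm(beta, 0, priors$beta_sd, log = TRUE)) +
    sum(stats::dnorm(u, 0, sigma[design$set_group], log = TRUE)) +
    sum(log_half_t(sigma, priors$sigma_df, priors$sigma_scale))
  if (!is.null(v)) {
    if (is.null(sigma_diet) || sigma_diet <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(v, 0, sigma_diet, log = TRUE)) +
      log_half_t(sigma_diet, priors$sigma_df, priors$sigma_scale)
  }
  lp
}

## ---------------------------------------------------------------------
## Sampler: adaptive Metropolis-within-Gibbs.
## Blocks: (1) joint random-walk update of beta with a Haario-style
## adaptive covariance; (2) simultaneous independent random-walk updates
## of all set intercepts u (each set touches only its own pairs, so the
## per-set acceptance decisions are exact and vectorized); (3) same for
## the diet-pairing intercepts v; (4) per-group random-walk updates of
## log sigma (these touch only the Normal terms of u). Proposal scales
## adapt toward standard target acceptance rates during warmup only.
## ---------------------------------------------------------------------

run_mcm_chain <- function(design, priors, steps, warmup, thin, seed) {
  set.seed(seed)
  X <- design$X; ctx <- design$ctx
  p <- ncol(X); n_set <- design$n_set; n_grp <- design$n_group
  n_diet <- design$n_diet
  set_idx <- design$set_idx
  diet_on <- n_diet > 0L

  beta <- rep(0, p); u <- rep(0, n_set); v <- rep(0, max(n_diet, 1L))
  lsig <- rep(0, n_grp); lsig_v <- 0

  theta <- linear_predictor(design, beta, u, if (diet_on) v else NULL)
  ll <- nhd_batch_loglik(ctx, theta)

  lp_beta_prior <- function(b) sum(stats::dnorm(b, 0, priors$beta_sd,
                                                log = TRUE))
  # log prior of sigma under the log-sigma parameterization (jacobian
  # term exp(t) included)
  lp_lsig <- function(t) log_half_t(exp(t), priors$sigma_df,
                                    priors$sigma_scale) + t

  s_beta <- 0.1; s_u <- rep(0.5, n_set); s_v <- rep(0.3, max(n_diet, 1L))
  s_s <- rep(0.3, n_grp); s_sv <- 0.3; s_sc <- rep(0.2, n_grp)
  bmean <- rep(0, p); bM2 <- matrix(0, p, p); L <- diag(p)

  n_keep <- floor((steps - warmup) / thin)
  B <- matrix(NA_real_, n_keep, p,
              dimnames = list(NULL, colnames(X)))
  U <- matrix(NA_real_, n_keep, n_set)
  V <- if (diet_on) matrix(NA_real_, n_keep, n_diet) else NULL
  SIG <- matrix(NA_real_, n_keep, n_grp,
                dimnames = list(NULL, paste0("sigma_", design$group_levels)))
  SIGV <- if (diet_on) numeric(n_keep) else NULL
  LL <- matrix(NA_real_, n_keep, ctx$m)
  kept <- 0L

  for (it in seq_len(steps)) {
    adapting <- it <= warmup
    ## (1) beta block
    prop <- beta + s_beta * drop(L %*% stats::rnorm(p))
    theta_p <- theta + drop(X %*% (prop - beta))
    ll_p <- nhd_batch_loglik(ctx, theta_p)
    la <- sum(ll_p) - sum(ll) + lp_beta_prior(prop) - lp_beta_prior(beta)
    acc_b <- is.finite(la) && log(stats::runif(1)) < la
    if (acc_b) { beta <- prop; theta <- theta_p; ll <- ll_p }
    if (adapting)
      s_beta <- exp(log(s_beta) +
                      ((acc_b) - 0.234) / max(20, it)^0.6)

    ## (2) u block: simultaneous per-set proposals
    du <- s_u * stats::rnorm(n_set)
    sig_set <- exp(lsig)[design$set_group]
    theta_p <- theta + du[set_idx]
    ll_p <- nhd_batch_loglik(ctx, theta_p)
    dll <- drop(rowsum(ll_p - ll, set_idx))  # ordered 1..n_set
    dpr <- stats::dnorm(u + du, 0, sig_set, log = TRUE) -
      stats::dnorm(u, 0, sig_set, log = TRUE)
    acc_u <- log(stats::runif(n_set)) < dll + dpr
    if (any(acc_u)) {
      u[acc_u] <- u[acc_u] + du[acc_u]
      sel <- acc_u[set_idx]
      theta[sel] <- theta_p[sel]
      ll[sel] <- ll_p[sel]
    }
    if (adapting)
      s_u <- exp(log(s_u) + (acc_u - 0.44) / max(20, it)^0.6)

    ## (3) v block
    if (diet_on) {
      dv <- s_v * stats::rnorm(n_diet)
      theta_p <- theta + dv[design$diet_idx]
      ll_p <- nhd_batch_loglik(ctx, theta_p)
      dll_v <- drop(rowsum(ll_p - ll, design$diet_idx))
      sv <- exp(lsig_v)
      dpr_v <- stats::dnorm(v + dv, 0, sv, log = TRUE) -
        stats::dnorm(v, 0, sv, log = TRUE)
      acc_v <- log(stats::runif(n_diet)) < dll_v + dpr_v
      if (any(acc_v)) {
        v[acc_v] <- v[acc_v] + dv[acc_v]
        sel <- acc_v[design$diet_idx]
        theta[sel] <- theta_p[sel]
        ll[sel] <- ll_p[sel]
      }
      if (adapting)
        s_v <- exp(log(s_v) + (acc_v - 0.44) / max(20, it)^0.6)
    }

    ## (4) sigma blocks (only Normal terms of u involved)
    dls <- s_s * stats::rnorm(n_grp)
    lsig_p <- lsig + dls
    cur <- drop(rowsum(stats::dnorm(u, 0, exp(lsig)[design$set_group],
                                    log = TRUE), design$set_group))
    prp <- drop(rowsum(stats::dnorm(u, 0, exp(lsig_p)[design$set_group],
                                    log = TRUE), design$set_group))
    la_s <- prp - cur + lp_lsig(lsig_p) - lp_lsig(lsig)
    acc_s <- log(stats::runif(n_grp)) < la_s
    lsig[acc_s] <- lsig_p[acc_s]
    if (adapting)
      s_s <- exp(log(s_s) + (acc_s - 0.44) / max(20, it)^0.6)

    ## (4b) joint scale move: rescale a group's intercepts and SD
    ## together (u' = c u, sigma' = c sigma). The Normal prior term of u
    ## cancels against the Jacobian, leaving the likelihood change plus
    ## the SD prior; this breaks the strong u-sigma coupling that makes
    ## separate updates mix slowly.
    eps <- s_sc * stats::rnorm(n_grp)
    u_new <- u * exp(eps)[design$set_group]
    theta_p <- theta + (u_new - u)[set_idx]
    ll_p <- nhd_batch_loglik(ctx, theta_p)
    dll_g <- drop(rowsum(ll_p - ll, design$set_group[set_idx]))
    la_sc <- dll_g + lp_lsig(lsig + eps) - lp_lsig(lsig)
    acc_sc <- log(stats::runif(n_grp)) < la_sc
    if (any(acc_sc)) {
      gsel <- acc_sc[design$set_group]
      u[gsel] <- u_new[gsel]
      lsig[acc_sc] <- lsig[acc_sc] + eps[acc_sc]
      psel <- acc_sc[design$set_group[set_idx]]
      theta[psel] <- theta_p[psel]
      ll[psel] <- ll_p[psel]
    }
    if (adapting)
      s_sc <- exp(log(s_sc) + (acc_sc - 0.44) / max(20, it)^0.6)

    ## (4c) exact recentering between beta and the set intercepts for
    ## set-constant covariate columns: shift beta_j by delta and every
    ## u_s by -delta * x_s. theta (hence the likelihood) is unchanged
    ## and the conditional of delta is Gaussian, so this is a Gibbs step.
    if (length(design$recenter_cols)) {
      sig2_set <- exp(lsig)[design$set_group]^2
      for (j in design$recenter_cols) {
        xs <- design$Xset[, j]
        tau <- sum(xs^2 / sig2_set) + 1 / priors$beta_sd^2
        mu <- (sum(xs * u / sig2_set) - beta[j] / priors$beta_sd^2) / tau
        delta <- stats::rnorm(1, mu, 1 / sqrt(tau))
        u <- u - delta * xs
        beta[j] <- beta[j] + delta
      }
    }

    if (diet_on) {
      t_p <- lsig_v + s_sv * stats::rnorm(1)
      la_sv <- sum(stats::dnorm(v, 0, exp(t_p), log = TRUE)) -
        sum(stats::dnorm(v, 0, exp(lsig_v), log = TRUE)) +
        lp_lsig(t_p) - lp_lsig(lsig_v)
      acc_sv <- log(stats::runif(1)) < la_sv
      if (acc_sv) lsig_v <- t_p
      if (adapting)
        s_sv <- exp(log(s_sv) + (acc_sv - 0.44) / max(20, it)^0.6)
    }

    ## adapt the beta proposal covariance from post-recentering values,
    ## where the retained draws live (warmup only)
    if (adapting) {
      d <- beta - bmean
      bmean <- bmean + d / it
      bM2 <- bM2 + tcrossprod(d, beta - bmean)
      if (it > max(50, 2 * p) && it %% 25 == 0) {
        cv <- bM2 / (it - 1) + diag(1e-8, p)
        ch <- tryCatch(chol(cv), error = function(e) NULL)
        if (!is.null(ch)) L <- t(ch)
      }
    }

    ## record
    if (it > warmup && (it - warmup) %% thin == 0) {
      kept <- kept + 1L
      B[kept, ] <- beta
      U[kept, ] <- u
      if (diet_on) { V[kept, ] <- v; SIGV[kept] <- exp(lsig_v) }
      SIG[kept, ] <- exp(lsig)
      LL[kept, ] <- ll
    }
  }
  list(beta = B, u = U, v = V, sigma = SIG, sigma_diet = SIGV,
       pointwise_loglik = LL)
}

#' Fit a mixed-effects co-occurrence model by MCMC
#'
#' Samples the posterior of the hierarchical model: observed
#' co-occurrence counts follow the non-central hypergeometric
#' distribution with a log link on the odds ratio, `theta = X beta +
#' u_set (+ v_dietpair)`, set intercepts `u ~ Normal(0, sigma_group)`
#' with the SD possibly varying by guild overlap or habitat, and weakly
#' informative priors ([mcm_priors()]). The sampler is an adaptive
#' Metropolis-within-Gibbs scheme (joint adaptive random walk on beta;
#' simultaneous exact per-set updates of the intercepts; log-scale
#' random walks on the SDs); adaptation runs during warmup only. The
#' default chain geometry (4 chains of 3000 steps, 1000 warmup, thinning
#' 2) retains 4000 draws. Runs are deterministic given `seed`.
#'
#' @param records pair-record data frame (from [build_pair_records()] or
#'   [simulate_pair_level()]).
#' @param spec an [mcm_spec()].
#' @param chains,steps,warmup,thin chain geometry.
#' @param seed integer master seed; chain `c` uses `seed + c - 1`.
#' @param priors from [mcm_priors()].
#' @param rhat_warn warn when any split-Rhat exceeds this (default 1.05).
#' @param quiet suppress the convergence warning.
#' @return An object of class `mcm_fit`: matrices of retained draws
#'   (`beta`, `u`, `sigma`, optionally `v`, `sigma_diet`, all chains
#'   stacked), the `chain` index of every draw, the draws-by-pairs
#'   `pointwise_loglik` matrix, per-parameter `rhat`, and the design.
#' @export
fit_mcm <- function(records, spec = mcm_spec(), chains = 4, steps = 3000,
                    warmup = 1000, thin = 2, seed = 1,
                    priors = mcm_priors(), rhat_warn = 1.05,
                    quiet = FALSE) {
  stopifnot(steps > warmup, chains >= 1, thin >= 1)
  design <- mcm_design(records, spec)
  res <- lapply(seq_len(chains), function(ch)
    run_mcm_chain(design, priors, steps, warmup, thin,
                  seed = seed + ch - 1L))
  n_keep <- nrow(res[[1]]$beta)
  stack <- function(name) do.call(rbind, lapply(res, `[[`, name))
  fit <- list(
    beta = stack("beta"),
    u = stack("u"),
    sigma = stack("sigma"),
    v = if (design$n_diet > 0) stack("v") else NULL,
    sigma_diet = if (design$n_diet > 0)
      do.call(c, lapply(res, `[[`, "sigma_diet")) else NULL,
    pointwise_loglik = stack("pointwise_loglik"),
    chain = rep(seq_len(chains), each = n_keep),
    n_keep_per_chain = n_keep,
    design = design, spec = spec, priors = priors,
    config = list(chains = chains, steps = steps, warmup = warmup,
                  thin = thin, seed = seed))
  class(fit) <- "mcm_fit"
  fit$rhat <- fit_rhat(fit)
  if (!quiet && chains >= 2 && any(fit$rhat > rhat_warn, na.rm = TRUE))
    warning(sprintf("%d parameter(s) with split-Rhat > %.2f (max %.3f)",
                    sum(fit$rhat > rhat_warn, na.rm = TRUE), rhat_warn,
                    max(fit$rhat, na.rm = TRUE)))
  fit
}

## parameter matrix (draws x all scalar parameters) of a fit
fit_param_matrix <- function(fit, include_re = TRUE) {
  out <- cbind(fit$beta, fit$sigma)
  if (!is.null(fit$sigma_diet))
    out <- cbind(out, sigma_diet = fit$sigma_diet)
  if (include_re) {
    um <- fit$u
    colnames(um) <- paste0("u[", fit$design$set_levels, "]")
    out <- cbind(out, um)
    if (!is.null(fit$v)) {
      vm <- fit$v
      colnames(vm) <- paste0("v[", fit$design$diet_levels, "]")
      out <- cbind(out, vm)
    }
  }
  out
}

fit_rhat <- function(fit, include_re = TRUE) {
  pm <- fit_param_matrix(fit, include_re = include_re)
  chains <- split.data.frame(pm, fit$chain)
  apply_rhat <- vapply(seq_len(ncol(pm)), function(j)
    gelman_rubin(lapply(chains, function(m) m[, j])), numeric(1))
  names(apply_rhat) <- colnames(pm)
  apply_rhat
}

#' @export
print.mcm_fit <- function(x, ...) {
  cat(sprintf("mcm_fit: %s\n", x$spec$label))
  cat(sprintf("  %d pairs, %d sets, %d sigma group(s); %d draws (%d chains)\n",
              x$design$ctx$m, x$design$n_set, x$design$n_group,
              nrow(x$beta), x$config$chains))
  cat(sprintf("  max split-Rhat %.3f\n", max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior means and 95% credible intervals
#'
#' @param fit an `mcm_fit`.
#' @param include_re include the per-set and per-diet-pairing random
#'   intercepts (default FALSE: fixed effects and SDs only).
#' @return Data frame with `parameter`, `mean`, `q2.5`, `q97.5`, `rhat`.
#' @export
posterior_summary <- function(fit, include_re = FALSE) {
  pm <- fit_param_matrix(fit, include_re = include_re)
  qs <- t(apply(pm, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  data.frame(parameter = colnames(pm),
             mean = colMeans(pm),
             q2.5 = qs[, 1], q97.5 = qs[, 2],
             rhat = fit$rhat[colnames(pm)],
             row.names = NULL)
}

#' Split Gelman-Rubin convergence statistic
#'
#' Classical split-Rhat: each chain is halved, and Rhat is
#' `sqrt(((n-1)/n * W + B/n) / W)` over the resulting 2m half-chains,
#' where `W` is the mean within-half variance and `B/n` the between-half
#' variance of the means. (The rank-normalized refinement is not
#' applied; for the unimodal posteriors of this model the classical form
#' is the standard diagnostic.) Identical chains give exactly 1.
#'
#' @param chains list (length >= 2) of equal-length numeric draw vectors,
#'   one per chain.
#' @return The Rhat scalar.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("need at least two chains", call. = FALSE)
  len <- lengths(chains)
  if (length(unique(len)) != 1)
    stop("chains must have equal length", call. = FALSE)
  if (all(vapply(chains[-1], identical, logical(1), chains[[1]])))
    return(1)  # identical chains carry no convergence signal
  half <- floor(len[1] / 2)
  halves <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[(half + 1):(2 * half)])), recursive = FALSE)
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, stats::var, numeric(1))
  W <- mean(vrs)
  B_over_n <- stats::var(mns)
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B_over_n) / W)
}
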