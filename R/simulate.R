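#' Log-series-like occupancy sampler
#'
#' Returns a sampler of species occupancies (sites occupied out of
#' `n_sites`) with many rare species and few common ones, the occupancy
#' structure typical of tropical assemblages where rare taxa compose the
#' vast majority of species. Probabilities are proportional to
#' `p^k / k` on `1..k_max`.
#'
#' @param n_sites total number of sites.
#' @param p log-series tilt in (0, 1); larger means fatter tail.
#' @param k_max maximum occupancy (default 60% of sites).
#' @return `function(n)` drawing `n` occupancies.
#' @export
logseries_occupancy_sampler <- function(n_sites = 50, p = 0.92,
                                        k_max = max(2L, floor(0.6 * n_sites))) {
  k <- seq_len(k_max)
  w <- p^k / k
  function(n) sample(k, n, replace = TRUE, prob = w)
}

default_true_beta <- function() {
  c("(Intercept)" = 0.41, "std_phylo_distance" = -0.10,
    "guild_overlapmedium" = 0.34, "guild_overlaphigh" = 0.03)
}

default_true_sigma <- function() {
  c(low = 0.60, medium = 0.53, high = 0.87)
}

#' Simulate pair-level co-occurrence records from the model itself
#'
#' Generates pair records whose co-occurrence counts are exact draws
#' from the non-central hypergeometric distribution at a known theta, so
#' every downstream stage (likelihood, sampler, selection) can be tested
#' against ground truth. Covariates are sampled (occupancies from a
#' log-series-like sampler; guild-overlap levels with medium most
#' common; node distances log-normal-ish and then standardized and
#' binned exactly as for real data), pairs are pooled into co-occurrence
#' sets, each set draws `u ~ Normal(0, sigma_group)`, and each pair
#' draws its count at `theta = x' beta + u`.
#'
#' Defaults mirror the assemblage-scale conditions this model was built
#' for: 50 sites, intercept 0.41 (low overlap), distance slope -0.10,
#' medium-overlap contrast +0.34, and set-intercept SDs of 0.60 / 0.53 /
#' 0.87 for the low / medium / high overlap groups.
#'
#' @param n_pairs number of pair records.
#' @param true_beta named coefficient vector; names must match the
#'   design-matrix columns implied by `fixed_terms`.
#' @param true_sigma named per-group SD vector (names = group levels).
#' @param fixed_terms fixed structure generating theta.
#' @param sigma_grouping `"by_guild_overlap"` (default), `"by_habitat"`
#'   or `"constant"` (then `true_sigma` must be a single value named
#'   `"all"`).
#' @param set_defining_vars set definition used for the random
#'   intercepts.
#' @param n_sites sites per habitat subset.
#' @param occupancy_sampler `function(n)` of occupancies (>= 1; zero or
#'   out-of-range draws are redrawn and counted).
#' @param seed integer seed; records are byte-identical across runs at a
#'   fixed seed.
#' @return A pair-record data frame with the same columns as
#'   [build_pair_records()] plus `true_theta`, and attributes `true`
#'   (beta, sigma, u, fixed_terms, sigma_grouping, set_defining_vars),
#'   `n_sites` and `n_redraws`.
#' @export
simulate_pair_level <- function(n_pairs = 5000,
                                true_beta = default_true_beta(),
                                true_sigma = default_true_sigma(),
                                fixed_terms = c("std_phylo_distance",
                                                "guild_overlap"),
                                sigma_grouping = "by_guild_overlap",
                                set_defining_vars = c("phylo_bin",
                                                      "guild_overlap",
                                                      "habitat",
                                                      "occupancy_pairing"),
                                n_sites = 50,
                                occupancy_sampler =
                                  logseries_occupancy_sampler(n_sites),
                                seed = 1) {
  stopifnot(all(true_sigma > 0), n_pairs >= 1)
  set.seed(seed)
  draw_occ <- function(n) {
    out <- occupancy_sampler(n)
    redraws <- 0L
    bad <- out < 1 | out > n_sites
    while (any(bad)) {
      redraws <- redraws + sum(bad)
      out[bad] <- occupancy_sampler(sum(bad))
      bad <- out < 1 | out > n_sites
    }
    attr(out, "redraws") <- redraws
    out
  }
  nA <- draw_occ(n_pairs); nB <- draw_occ(n_pairs)
  n_redraws <- attr(nA, "redraws") + attr(nB, "redraws")
  df <- data.frame(
    species_a = sprintf("simA%05d", seq_len(n_pairs)),
    species_b = sprintf("simB%05d", seq_len(n_pairs)),
    n_A = as.integer(nA), n_notA = as.integer(n_sites - nA),
    n_B = as.integer(nB), n_AB = NA_integer_,
    habitat = sample(c("intact", "altered"), n_pairs, replace = TRUE),
    guild_overlap = sample(c("low", "medium", "high"), n_pairs,
                           replace = TRUE, prob = c(0.40, 0.45, 0.15)),
    stringsAsFactors = FALSE)
  df$diet_pairing <- paste0(df$guild_overlap, "_diet",
                            sample(1:3, n_pairs, replace = TRUE))
  raw_d <- pmax(1L, as.integer(round(exp(stats::rnorm(n_pairs,
                                                      log(15), 0.6)))))
  ph <- standardize_and_bin(raw_d)
  df$raw_node_distance <- ph$raw_node_distance
  df$std_phylo_distance <- ph$std_phylo_distance
  df$phylo_bin <- ph$bin_index
  df$occupancy_pairing <- paste(pmin(df$n_A, df$n_B),
                                pmax(df$n_A, df$n_B), sep = "-")
  df <- assign_cooc_sets(df, defining_vars = set_defining_vars)

  # fixed part with the same encoding the model uses
  df$guild_overlap_f <- factor(df$guild_overlap,
                               levels = c("low", "medium", "high"))
  df$habitat_f <- factor(df$habitat, levels = c("intact", "altered"))
  fml <- if (length(fixed_terms))
    stats::as.formula(paste("~", paste(gsub("guild_overlap",
                                            "guild_overlap_f",
                                            gsub("habitat", "habitat_f",
                                                 fixed_terms)),
                                       collapse = "+")))
  else ~1
  X <- stats::model.matrix(fml, data = df)
  colnames(X) <- gsub("_f", "", colnames(X), fixed = TRUE)
  df$guild_overlap_f <- NULL; df$habitat_f <- NULL
  miss <- setdiff(colnames(X), names(true_beta))
  if (length(miss))
    stop("true_beta lacks coefficients: ", paste(miss, collapse = ", "),
         call. = FALSE)
  xb <- drop(X %*% true_beta[colnames(X)])

  set_fac <- factor(df$set_id)
  grp_var <- switch(sigma_grouping, constant = NULL,
                    by_guild_overlap = "guild_overlap",
                    by_habitat = "habitat")
  set_level_grp <- if (is.null(grp_var)) {
    rep("all", nlevels(set_fac))
  } else {
    vapply(split(as.character(df[[grp_var]]), set_fac),
           function(z) z[1], "")
  }
  missg <- setdiff(unique(set_level_grp), names(true_sigma))
  if (length(missg))
    stop("true_sigma lacks groups: ", paste(missg, collapse = ", "),
         call. = FALSE)
  u <- stats::rnorm(nlevels(set_fac), 0, true_sigma[set_level_grp])
  names(u) <- levels(set_fac)
  df$true_theta <- xb + u[as.integer(set_fac)]

  df$n_AB <- vapply(seq_len(n_pairs), function(i)
    nhd_sample(pair_counts(df$n_A[i], df$n_notA[i], df$n_B[i]),
               df$true_theta[i], 1L),
    integer(1))
  attr(df, "true") <- list(beta = true_beta, sigma = true_sigma, u = u,
                           fixed_terms = fixed_terms,
                           sigma_grouping = sigma_grouping,
                           set_defining_vars = sort(set_defining_vars))
  attr(df, "n_sites") <- n_sites
  attr(df, "n_redraws") <- n_redraws
  attr(df, "seed") <- seed
  df
}

#' Simulate a full assemblage: matrix, metadata, guilds and tree
#'
#' End-to-end generator for pipeline testing. A Yule tree is simulated;
#' latent niche traits evolve along it by Brownian motion and are mixed
#' with independent noise in proportion `phylo_signal`; sites get random
#' niche positions and a habitat label; each species occupies the sites
#' where its niche match (plus optional guild-site affinity scaled by
#' `guild_effect`, plus Gumbel noise) is highest, with its occupancy
#' drawn from `occupancy_sampler`. Column sums therefore follow the
#' requested occupancy distribution exactly. With `phylo_signal > 0`
#' closely related species prefer similar sites and co-occur more, so a
#' fitted distance slope should be negative; with `phylo_signal = 0` and
#' `guild_effect = 0` the matrix carries no pair-level structure beyond
#' its margins. No exact pairwise theta truth is claimed at this level
#' -- that lives in [simulate_pair_level()].
#'
#' @param n_species,n_sites dimensions (>= 3 species, >= 4 sites).
#' @param occupancy_sampler `function(n)` of target occupancies.
#' @param latent_niche_dim number of latent niche axes.
#' @param phylo_signal fraction in \[0, 1\] of trait variance that is
#'   phylogenetic.
#' @param guild_effect strength of guild-site affinity.
#' @param guild_phylo_clustered assign primary guilds by discretizing a
#'   Brownian trait (TRUE) or at random.
#' @param habitat_split fraction of sites labelled altered.
#' @param noise_sd SD of the site-suitability noise.
#' @param seed integer seed.
#' @return A list of class `assemblage_bundle`: `matrix` (sites x
#'   species, 0/1), `sites` (site_id, habitat_category), `site_habitat`
#'   (named altered/intact vector), `guilds`, `tree`.
#' @export
simulate_matrix_level <- function(n_species = 40, n_sites = 40,
                                  occupancy_sampler =
                                    logseries_occupancy_sampler(n_sites),
                                  latent_niche_dim = 2,
                                  phylo_signal = 0.8,
                                  guild_effect = 0,
                                  guild_phylo_clustered = TRUE,
                                  habitat_split = 0.5,
                                  noise_sd = 0.5,
                                  seed = 1) {
  if (n_species < 3 || n_sites < 4)
    stop("need at least 3 species and 4 sites", call. = FALSE)
  stopifnot(phylo_signal >= 0, phylo_signal <= 1)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  zscale <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
    else x * 0
  traits <- vapply(seq_len(latent_niche_dim), function(d) {
    bm <- zscale(ape::rTraitCont(tree, model = "BM"))
    eps <- zscale(stats::rnorm(n_species))
    sqrt(phylo_signal) * bm + sqrt(1 - phylo_signal) * eps
  }, numeric(n_species))
  rownames(traits) <- tree$tip.label

  guild_pool <- c("frugivore", "invertivore", "nectarivore", "granivore")
  if (guild_phylo_clustered) {
    g_trait <- zscale(ape::rTraitCont(tree, model = "BM"))
    primary <- guild_pool[cut(rank(g_trait, ties.method = "first"),
                              breaks = length(guild_pool),
                              labels = FALSE)]
  } else {
    primary <- sample(guild_pool, n_species, replace = TRUE)
  }
  secondary <- ifelse(stats::runif(n_species) < 0.3,
                      vapply(primary, function(g)
                        sample(setdiff(guild_pool, g), 1), ""),
                      NA_character_)
  # a few omnivores so the medium-overlap rule is exercised
  omn <- stats::runif(n_species) < 0.1
  primary[omn] <- "omnivore"; secondary[omn] <- NA_character_
  guilds <- data.frame(species_id = tree$tip.label,
                       primary_guild = primary,
                       secondary_guild = secondary,
                       stringsAsFactors = FALSE)

  site_id <- sprintf("site%03d", seq_len(n_sites))
  n_alt <- max(1L, min(n_sites - 1L, round(habitat_split * n_sites)))
  habitat <- sample(c(rep("altered", n_alt), rep("intact", n_sites - n_alt)))
  altered_cats <- c("cropland", "pasture", "plantation", "secondary forest",
                    "fragment", "disturbed forest", "inhabited area")
  sites <- data.frame(
    site_id = site_id,
    habitat_category = ifelse(habitat == "intact", "none",
                              sample(altered_cats, n_sites, replace = TRUE)),
    stringsAsFactors = FALSE)

  site_pos <- matrix(stats::rnorm(n_sites * latent_niche_dim), n_sites)
  aff <- matrix(stats::rnorm(n_sites * (length(guild_pool) + 1)), n_sites,
                dimnames = list(NULL, c(guild_pool, "omnivore")))
  occ_target <- occupancy_sampler(n_species)
  occ_target <- pmin(pmax(occ_target, 1L), n_sites)
  m <- matrix(0L, n_sites, n_species, dimnames = list(site_id,
                                                      tree$tip.label))
  for (i in seq_len(n_species)) {
    d2 <- rowSums((site_pos - matrix(traits[i, ], n_sites,
                                     latent_niche_dim, byrow = TRUE))^2)
    suit <- -d2 / 2 + guild_effect * aff[, primary[i]] +
      noise_sd * (-log(-log(stats::runif(n_sites))))
    m[order(suit, decreasing = TRUE)[seq_len(occ_target[i])], i] <- 1L
  }
  if (sum(m) == 0) stop("degenerate parameters: empty matrix", call. = FALSE)
  out <- list(matrix = m, sites = sites,
              site_habitat = stats::setNames(habitat, site_id),
              guilds = guilds, tree = tree)
  class(out) <- "assemblage_bundle"
  out
}

#' @export
print.assemblage_bundle <- function(x, ...) {
  cat(sprintf("assemblage_bundle: %d sites x %d species (fill %.2f); ",
              nrow(x$matrix), ncol(x$matrix), mean(x$matrix)))
  cat(sprintf("%d altered / %d intact sites\n",
              sum(x$site_habitat == "altered"),
              sum(x$site_habitat == "intact")))
  invisible(x)
}

#' Parameter-recovery report over replicate simulations
#'
#' Runs the pair-level generator and the model fit across replicates and
#' tabulates, per parameter, the truth, mean posterior mean, bias, RMSE
#' and 95% credible-interval coverage. Optionally also runs the
#' two-step structure selection each replicate and reports how often the
#' generative sigma grouping was chosen.
#'
#' @param n_reps number of replicates.
#' @param sim_args list of arguments to [simulate_pair_level()] (the
#'   per-replicate seed is added automatically).
#' @param spec the [mcm_spec()] to fit; defaults to the generative
#'   structure.
#' @param fit_args list of arguments to [fit_mcm()] (chains, steps, ...).
#' @param selection optional list with `random_specs`,
#'   `fixed_terms_list` and `fit_args`; when given, selection accuracy
#'   is reported.
#' @param seed master seed; replicate r simulates with `seed + r` and
#'   fits with `seed + 5000 + r`.
#' @return A list of class `recovery_report`: `table` (per-parameter
#'   data frame), `n_reps`, and `selection` (chosen sigma grouping per
#'   replicate plus accuracy) when requested.
#' @export
recovery_report <- function(n_reps = 20, sim_args = list(), spec = NULL,
                            fit_args = list(), selection = NULL, seed = 1) {
  if (n_reps < 1) stop("need at least one replicate", call. = FALSE)
  acc <- list(); sel_choices <- character()
  for (r in seq_len(n_reps)) {
    sim <- do.call(simulate_pair_level, c(sim_args, list(seed = seed + r)))
    tr <- attr(sim, "true")
    sp <- spec %||% mcm_spec(fixed_terms = tr$fixed_terms,
                             set_defining_vars = tr$set_defining_vars,
                             sigma_grouping = tr$sigma_grouping)
    fit <- do.call(fit_mcm, c(list(records = sim, spec = sp,
                                   seed = seed + 5000L + r, quiet = TRUE),
                              fit_args))
    s <- posterior_summary(fit)
    truth <- c(tr$beta, stats::setNames(tr$sigma,
                                        paste0("sigma_", names(tr$sigma))))
    s$true <- truth[s$parameter]
    s$covered <- !is.na(s$true) & s$true >= s$q2.5 & s$true <= s$q97.5
    s$rep <- r
    acc[[r]] <- s
    if (!is.null(selection)) {
      selres <- do.call(select_structure,
                        c(list(records = sim,
                               seed = seed + 9000L + r),
                          selection))
      sel_choices <- c(sel_choices, selres$best_spec$sigma_grouping)
    }
  }
  all_s <- do.call(rbind, acc)
  all_s <- all_s[!is.na(all_s$true), ]
  tab <- do.call(rbind, lapply(split(all_s, all_s$parameter), function(g)
    data.frame(parameter = g$parameter[1], true = g$true[1],
               mean_estimate = mean(g$mean),
               bias = mean(g$mean - g$true),
               rmse = sqrt(mean((g$mean - g$true)^2)),
               coverage = mean(g$covered))))
  rownames(tab) <- NULL
  out <- list(table = tab, n_reps = n_reps)
  if (!is.null(selection)) {
    truth_sg <- (sim_args$sigma_grouping) %||% "by_guild_overlap"
    out$selection <- list(chosen = sel_choices,
                          accuracy = mean(sel_choices == truth_sg))
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("parameter recovery over %d replicates\n", x$n_reps))
  print(x$table, row.names = FALSE, digits = 3)
  if (!is.null(x$selection))
    cat(sprintf("sigma-grouping selection accuracy: %.2f\n",
                x$selection$accuracy))
  invisible(x)
}
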