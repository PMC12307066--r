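# coocmix — mixed-effects co-occurrence modelling

`coocmix` analyses spatial associations between species at the
assemblage level: every pairwise combination of species in a
site-by-species presence–absence matrix, jointly, in one hierarchical
model. It is aimed at community ecologists asking whether phylogenetic
relatedness, dietary-niche overlap, or habitat alteration shape which
species share sites — questions that classical pair-at-a-time
co-occurrence tests cannot answer for speciose assemblages dominated by
rare taxa.

## The model

For a species pair with occupancies $N_A$ and $N_B$ among
$N = N_A + N_{(A)}$ sites, the co-occurrence count $N_{AB}$ follows
Fisher's non-central hypergeometric distribution,

$$ f(N_{AB}\mid\theta) \;=\;
 \frac{\binom{N_A}{N_{AB}}\binom{N_{(A)}}{N_B-N_{AB}}\,e^{N_{AB}\theta}}
      {P_0(\theta)},
 \qquad
 \theta = \log\frac{\pi_{B\mid A}}{\pi_{B\mid (A)}}, $$

where $\theta$ is the log odds ratio of one species' occurrence given
the other's presence versus absence: $\theta>0$ means aggregation,
$\theta<0$ segregation, $\theta=0$ independence (the central
hypergeometric null). A single pair — especially a rare one — says
little about $\theta$, so pairs are pooled into *co-occurrence sets*
(pairs sharing occupancy pairing, phylogenetic-distance bin, diet
pairing, habitat, …) that receive Normal random intercepts inside a
Bayesian mixed model:

$$ \theta_i = x_i^\top\beta + u_{s(i)},\qquad
   u_s \sim \mathcal N(0,\sigma_{g(s)}), $$

with fixed effects for standardized phylogenetic distance, guild
overlap and habitat, and a random-intercept SD that may vary by overlap
group or habitat. Structures are compared by PSIS-LOO expected log
predictive density (ELPD) in a two-step random-then-fixed search, and
final estimates are benchmarked against curveball (fixed row and column
margins) randomization nulls.

The package implements the full stack: a numerically exact NHD kernel
(`nhd_logpmf`, `nhd_mode`, `theta_mle`, …), data preparation from the
four standard input files (`read_assemblage`, `build_pair_records`),
the MCMC sampler (`fit_mcm`), model comparison (`elpd_psis_loo`,
`select_structure`, `nested_term_zscores`), nulls
(`curveball_randomize`, `null_distribution`) and synthetic-data
generators with a recovery harness (`simulate_pair_level`,
`simulate_matrix_level`, `recovery_report`). A thin command-line
wrapper lives in `inst/scripts/coocmix-cli.R`. See the vignette
(`vignettes/mixed-effects-cooccurrence.Rmd`) for the methods account.

## A worked example

Simulate pair records from the model itself (5 000 pairs over 50 sites,
distance slope −0.10, intercept 0.41 for low-overlap pairs, +0.34 for
medium, and set-intercept SDs 0.60/0.53/0.87 for low/medium/high
overlap), then fit:

```r
library(coocmix)

sim <- simulate_pair_level(n_pairs = 5000, seed = 101)
spec <- mcm_spec(
  fixed_terms = c("std_phylo_distance", "guild_overlap"),
  set_defining_vars = c("phylo_bin", "guild_overlap", "habitat",
                        "occupancy_pairing"),
  sigma_grouping = "by_guild_overlap")
fit <- fit_mcm(sim, spec, chains = 2, steps = 900, warmup = 400,
               thin = 1, seed = 11)
posterior_summary(fit)
```

```
            parameter        mean       q2.5       q97.5     rhat
1         (Intercept)  0.47759094  0.3607217  0.58643373 1.057013
2  std_phylo_distance -0.07998257 -0.1428077 -0.01554265 1.020196
3 guild_overlapmedium  0.27644337  0.1252737  0.42886610 1.058504
4   guild_overlaphigh -0.04791963 -0.2550301  0.15318329 1.021674
5          sigma_high  0.88559409  0.6627415  1.13519385 1.011256
6           sigma_low  0.47127403  0.3484473  0.60027533 1.019254
7        sigma_medium  0.41731448  0.2514427  0.55382919 1.077258
```

Read it as: at average phylogenetic distance a low-overlap pair in
intact habitat has posterior mean `theta` of about 0.48 (odds ratio
`exp(0.48)` ≈ 1.6, mild aggregation); co-occurrence declines with
phylogenetic distance (slope −0.08, CI excluding 0 — close relatives
co-occur more); medium-overlap pairs sit about 0.28 higher; and the
spread of set-level associations is largest in the high-overlap group
(`sigma_high` ≈ 0.88), the signature of pair-specific outcomes of food
competition. The 95% credible intervals cover the generating values for
every parameter in this run.

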