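---
title: "Mixed-effects co-occurrence modelling with coocmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-effects co-occurrence modelling with coocmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical co-occurrence analysis asks, pair by pair, whether two species
share sites more or less often than a null model predicts. That framing
has two well-known weaknesses at the assemblage scale. First, most
species are rare, so a single pair's $2\times2$ occupancy table carries
very little information: a pair that never co-occurs is compatible with
anything from mild to total segregation, and its maximum-likelihood
association is $-\infty$. Second, a p-value against a null model is not
a measure of association strength, so estimates cannot be compared or
modelled across pairs.

`coocmix` takes a different route. The co-occurrence count of a pair is
given a likelihood with an interpretable association parameter, and all
pairs of an assemblage are analysed *jointly* in a hierarchical model, so
information is shared ("partially pooled") across pairs that are alike.
The questions the package is built to answer are ecological: does
co-occurrence increase with phylogenetic relatedness (niche
conservatism feeding environmental filtering)? Do pairs with similar
diets co-occur less (competitive exclusion) or more (shared
environmental filtering), or simply show more *variable* associations
(pair-specific outcomes of food competition)? Does habitat alteration
change any of this?

## The model

### Likelihood

For a pair (A, B) observed over $N = N_A + N_{(A)}$ sites, with $N_A$
sites occupied by A, $N_{(A)}$ not occupied by A, and $N_B$ occupied by
B, the number of co-occurrences $N_{AB}$ is modelled by Fisher's
non-central hypergeometric distribution (NHD):

$$ f(N_{AB} \mid \theta) =
   \frac{\binom{N_A}{N_{AB}} \binom{N_{(A)}}{N_B - N_{AB}}
         e^{N_{AB}\theta}}{P_0(\theta)}, $$

where $P_0(\theta)$ sums the numerator over the finite support
$\max(0, N_B - N_{(A)}) \le n \le \min(N_A, N_B)$. The parameter

$$ \theta = \log\psi =
   \log\frac{\pi_{B\mid A}}{\pi_{B\mid (A)}} $$

is the log of the ratio of the odds that B occupies a site given that A
is present versus absent: $\theta > 0$ is aggregation, $\theta < 0$
segregation, $\theta = 0$ independence (where the NHD reduces to the
central hypergeometric distribution, the classical null). $\theta$ is
symmetric in the two species and is a direct effect size, not a test
statistic.

Occupancy controls how much a count can say about $\theta$. With two
species each on 8 of 50 sites, moving $\theta$ from $-2$ to $+2$ moves
the most likely co-occurrence count from 0 to 4; with occupancies of 2,
the most likely count is 0 across that whole range (`nhd_mode()`
reproduces both). This is why single rare pairs are uninformative and
why pooling is the heart of the method.

### Hierarchy

Each pair is assigned to a *co-occurrence set*: the group of pairs
sharing levels of chosen defining variables, always including the
unordered occupancy pairing $\{\min(N_A,N_B), \max(N_A,N_B)\}$, and
typically also the phylogenetic-distance bin, the diet pairing and the
habitat. The model is

$$ \theta_i = x_i^\top\beta + u_{s(i)} \;(+\, v_{d(i)}), \qquad
   u_s \sim \mathcal N(0, \sigma_{g(s)}), $$

with fixed effects for standardized phylogenetic distance, dietary-guild
overlap (reference level: low) and habitat (reference: intact), a random
intercept per set, optionally a second random intercept per diet
pairing, and a random-intercept SD that is constant or varies by guild
overlap or habitat. The varying-SD option is the model's device for the
"more variable associations under shared diet" hypothesis.

### Data preparation

* Habitat categories collapse to intact (`"none"`) versus altered
  (everything else).
* Guild overlap: *high* if the two species carry the same multiset of
  primary/secondary guilds (order ignored), *medium* if they share some
  but not all guilds or either is an omnivore, *low* if none are shared.
  Low-overlap pairs are the control group.
* Phylogenetic distance is the number of branch nodes separating two
  tips. The count of *internal nodes strictly between* the tips is the
  default (sister tips: 1); an edge-count convention is available. The
  choice only shifts and rescales the standardized covariate, so it
  cannot change the sign or interpretation of fitted slopes, which is
  why both conventions are offered rather than agonized over.
* Distances are logged, centred, scaled to unit variance over all
  analysed records (habitats pooled, so both habitats share one
  covariate scale and one slope meaning), cut into five equal-width
  bins, and every pair carries its bin's mean standardized distance.
  Binning makes the continuous covariate set-constant, which is what
  lets pairs pool into sets.

## Fitting

Priors are weakly informative and configurable: $\mathcal N(0, 5^2)$ on
fixed effects and half-Student-t(3, 0, 2.5) on random-effect SDs. On
the log-odds scale a coefficient of 5 is an odds ratio of about 148, so
these priors are broad for any realistic assemblage.

The sampler is an adaptive Metropolis-within-Gibbs scheme written for
this likelihood:

1. a joint random-walk update of $\beta$ with a Haario-style adaptive
   covariance;
2. simultaneous independent random-walk updates of all set intercepts
   (each set touches only its own pairs, so thousands of accept/reject
   decisions are made exactly, in a single vectorized likelihood pass);
3. log-scale random-walk updates of each $\sigma_g$;
4. a joint scale move that rescales a group's intercepts and SD
   together (the Normal prior term cancels against the Jacobian), which
   breaks the $u$--$\sigma$ coupling that otherwise mixes slowly;
5. an exact Gibbs *recentering* move between each set-constant fixed
   effect and the set intercepts (the likelihood is invariant under the
   shift and the conditional is Gaussian), which decorrelates the
   intercept and contrasts from the random-effect means.

Proposal scales adapt toward standard acceptance targets during warmup
only. All pmf arithmetic is in log space with log-gamma binomial
coefficients and exact log-sum-exp over the finite support, so the
likelihood is overflow-free at any assemblage scale. Pairs whose
support is a single point (their count is forced by the margins)
contribute exactly zero log-likelihood; they are retained and flagged.
Boundary conditional MLEs ($\hat\theta = \pm\infty$ when the observed
count sits on the edge of a support with more than one point) are
reported as explicit flags by `theta_mle()`, never as floating
infinities.

The default chain geometry (4 chains of 3000 steps, warmup 1000,
thinning 2, so 4000 retained draws) suits assemblage-scale final fits.
Convergence is monitored with the classical split Gelman–Rubin
statistic on every scalar parameter (the rank-normalized refinement is
not applied; the posteriors here are unimodal in all tested regimes).
Runs are deterministic given a seed.

## Model selection

Out-of-sample fit is measured by the expected log pointwise predictive
density (ELPD), estimated by PSIS-LOO from the stored draws-by-pairs
log-likelihood matrix: per pair, leave-one-out importance ratios are
smoothed by a generalized Pareto fit (Zhang–Stephens profile estimator
with the standard weak-prior shrinkage of the shape) to the largest 20%
of ratios, truncated at the raw maximum; tail-shape values $k > 0.7$
are flagged. Ratios tied at the tail cutoff carry no tail information
and are left unsmoothed. The standard error is
$\sqrt{n \,\mathrm{var}(\text{pointwise})}$.

Structure search is two-step: first the random structure (set-defining
variables, SD grouping, optional diet-pairing effect) is chosen with
the full fixed structure held fixed; then the fixed structure is chosen
with the winning random structure held fixed. Comparisons are reported
as $z_{\Delta E} = \Delta E / s_{\Delta E}$, an *informal* evidence
score: each species enters many pairs, so pointwise contributions are
not independent and these are not formal tests. Identical models give
$0/0$, which is reported as 0 with a degeneracy flag. The built-in
candidate catalogue (`default_random_specs()`, `default_fixed_terms()`)
covers the canonical search space -- sets from phylo bin x diet
pairing x habitat x occupancy pairing; SD constant or varying by
overlap or habitat; all-subsets fixed effects plus the full
two-way-interaction model -- and is fully user-overridable. The "full
fixed structure" held fixed in step 1 is all three main effects plus
all two-way interactions.

## Randomization nulls

`curveball_randomize()` trades occupied columns between random row
pairs, preserving every row and column margin exactly; refitting the
final model to randomized matrices (covariate tables untouched) yields
null distributions of the posterior means. Estimates well outside the
null envelope indicate structure beyond the margins. Assemblage-scale
analyses warrant on the order of $10^8$ trades per matrix; the package
default is
50 trades per occupied cell, chosen from mixing profiles
(`curveball_mixing_profile()`) that plateau well below that on
desk-scale matrices -- users should check the profile on their own
matrix. Fixed-margin nulls are conservative: they preserve nestedness
and other biogeographic structure, so null intercepts tend to resemble
observed intercepts even when contrasts and slopes do not.

## Synthetic data: what it does and does not emulate

Generation is two-tier, on purpose.

* `simulate_pair_level()` is the *oracle* tier: covariates and sets are
  sampled, $u_s$ and then $N_{AB}$ are drawn exactly from the model, and
  every record carries its true $\theta$. Defaults are the assemblage
  conditions the model targets: 50 sites; occupancies from a log-series
  sampler (mean occupancy about 4.5 sites, most species rare); overlap
  frequencies 40/45/15% for low/medium/high; intercept 0.41 at low
  overlap, distance slope $-0.10$, medium contrast $+0.34$, high
  contrast $+0.03$; SDs 0.60/0.53/0.87 for low/medium/high. Parameter
  recovery and selection consistency are tested against this tier.
* `simulate_matrix_level()` is the *realism* tier: a Yule tree,
  Brownian niche traits mixed with noise in proportion `phylo_signal`,
  random site niches, and top-$k$ site choice per species so column
  sums follow the requested occupancy distribution exactly. A
  site-by-species matrix cannot carry arbitrary prescribed pairwise
  $\theta$ for all pairs simultaneously -- the problem is
  over-constrained -- so this tier claims only directional truth
  (positive `phylo_signal` makes related pairs co-occur, so fitted
  distance slopes should be negative) and serves end-to-end pipeline
  tests and negative controls.

Passing tests on these generators shows the machinery is correct and
calibrated *under the model's own assumptions*. Real assemblages add
spatial autocorrelation, heterogeneous sampling effort and
non-independence of pairs sharing species, none of which the generators
emulate; inferences on real data inherit those caveats.

## Numerical choices and edge cases

* Conditional MLE: bisection on $\theta \in [-50, 50]$ of the monotone
  mean equation $E[N\mid\theta] = N_{AB}$, to tolerance $10^{-8}$,
  after boundary screening.
* Mode ties are broken toward the smaller count, deterministically.
* Binary coercion: any positive abundance is presence.
* Degenerate inputs fail loudly: constant distances cannot be
  standardized; empty habitat subsets, all-boundary single-pair sets
  and non-binary matrices are errors, not warnings.
* Null-replicate fits that fail are recorded, excluded and counted.
* Chain seeds derive from the master seed by consecutive offsets;
  null-replicate seeds by a counter.

## Problem sizes used in the shipped tests

The test suite exercises the full stack at desk scale, chosen so the
whole suite runs in minutes on one core while remaining statistically
meaningful: parameter recovery uses 20 replicates of 5000 pairs with 2
chains of 900 steps (the coverage tolerance at 20 replicates is wide --
a 95% interval should cover in at least 18 of 20); selection
consistency uses 10 replicates of 4000 pairs over a reduced candidate
list, with extra draws in the fixed-structure step because a single
nested term moves the ELPD by well under one unit; null envelopes use
100 scaled-down refits of a 24-species, 28-site structure-free
assemblage; PSIS-LOO is validated against exact leave-one-out
refitting on 15-pair datasets. Full-scale analyses
(hundreds of thousands of pairs, $10^8$ trades, 4x3000-step chains) use
the same code paths with larger settings.

## Known limitations

* The sampler is random-walk based; posteriors with hundreds of
  thousands of sets will mix slowly compared to gradient-based
  samplers, though the vectorized set updates keep per-iteration cost
  linear in the number of pairs.
* $z_{\Delta E}$ scores are informal by construction; treat them as
  effect-ordering devices, not tests.
* Fixed-margin nulls are conservative, and the package deliberately
  offers no equiprobable or proportional alternatives.
* Occupancy-pairing sets grow with assemblage size; extremely sparse
  matrices can produce many singleton sets, which is statistically
  harmless (they shrink to the group mean) but computationally wasteful.

## A worked session

```{r, eval = FALSE}
library(coocmix)

# exact pair-level truth
sim <- simulate_pair_level(n_pairs = 2000, seed = 1)
spec <- mcm_spec(
  fixed_terms = c("std_phylo_distance", "guild_overlap"),
  set_defining_vars = c("phylo_bin", "guild_overlap", "habitat",
                        "occupancy_pairing"),
  sigma_grouping = "by_guild_overlap")
fit <- fit_mcm(sim, spec, chains = 2, steps = 1000, warmup = 400,
               thin = 1, seed = 2)
posterior_summary(fit)

# structure search and term evidence
sel <- select_structure(sim, seed = 3, chains = 2, steps = 600,
                        warmup = 250, thin = 1)
nested_term_zscores(sel$best_fit, sim, seed = 3, chains = 2,
                    steps = 600, warmup = 250, thin = 1)

# end-to-end with files and a curveball null
b <- simulate_matrix_level(n_species = 30, n_sites = 36, seed = 4)
paths <- write_assemblage(b, tempfile())
b2 <- read_assemblage(paths["matrix"], paths["sites"], paths["guilds"],
                      paths["tree"])
rec <- build_pair_records(b2$matrix, b2$site_habitat, b2$guilds, b2$tree)
obs <- fit_mcm(rec, spec, chains = 2, steps = 800, warmup = 300,
               thin = 1, seed = 5)
nd <- null_distribution(b2$matrix,
                        function(m) build_pair_records(m, b2$site_habitat,
                                                       b2$guilds, b2$tree),
                        spec, n_reps = 100, seed = 6,
                        observed_fit = obs, chains = 2, steps = 400,
                        warmup = 150, thin = 1)
nd$summary
```
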