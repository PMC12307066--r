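sp_info <- function(p, s = NA_character_)
  list(primary_guild = p, secondary_guild = s)

test_that("habitat categories collapse to altered/intact", {
  expect_identical(collapse_habitat("none"), "intact")
  expect_identical(collapse_habitat("secondary forest"), "altered")
  expect_identical(collapse_habitat(c("cropland", "pasture", "plantation",
                                      "fragment", "disturbed forest",
                                      "inhabited area", "combined")),
                   rep("altered", 7))
  expect_identical(collapse_habitat("NONE "), "intact")
  expect_error(collapse_habitat("swamp"), "allowed")
})

test_that("pair counts are within-subset occupancies and joint counts", {
  m <- rbind(s1 = c(A = 1, B = 0), s2 = c(A = 1, B = 1),
             s3 = c(A = 0, B = 1), s4 = c(A = 0, B = 0))
  pc <- build_pair_counts(m)
  expect_equal(nrow(pc), 1)
  expect_equal(pc$n_A, 2); expect_equal(pc$n_notA, 2)
  expect_equal(pc$n_B, 2); expect_equal(pc$n_AB, 1)
  # species with zero occupancy in the subset appear in no pair
  m2 <- cbind(m, C = c(0, 0, 0, 0), D = c(1, 0, 1, 1))
  pc2 <- build_pair_counts(m2)
  expect_equal(nrow(pc2), choose(3, 2))
  expect_false("C" %in% c(pc2$species_a, pc2$species_b))
  # subset restriction changes the occupancies
  pc3 <- build_pair_counts(m, sites = c("s1", "s2"))
  expect_equal(pc3$n_A, 2); expect_equal(pc3$n_B, 1); expect_equal(pc3$n_AB, 1)
  expect_warning(build_pair_counts(m[, "A", drop = FALSE]), "fewer than two")
  # abundances are coerced to presence
  expect_equal(build_pair_counts(m * 7)$n_AB, 1)
})

test_that("pair enumeration yields exactly choose(k, 2) records", {
  for (k in c(5, 23, 170)) {
    m <- matrix(1L, nrow = 3, ncol = k,
                dimnames = list(NULL, sprintf("sp%04d", seq_len(k))))
    expect_equal(nrow(build_pair_counts(m)), choose(k, 2))
  }
})

test_that("guild overlap classification follows the shared-guild rules", {
  fr_ne <- sp_info("frugivore", "nectarivore")
  ne_fr <- sp_info("nectarivore", "frugivore")
  fr <- sp_info("frugivore")
  in_fr <- sp_info("invertivore", "frugivore")
  ne <- sp_info("nectarivore")
  iv <- sp_info("invertivore")
  om <- sp_info("omnivore")
  # same guilds in either order are high overlap
  expect_identical(classify_guild_overlap(fr_ne, ne_fr), "high")
  expect_identical(classify_guild_overlap(fr, fr), "high")
  # partial sharing is medium
  expect_identical(classify_guild_overlap(fr, in_fr), "medium")
  # no sharing is low
  expect_identical(classify_guild_overlap(ne, iv), "low")
  # any omnivore pair is medium, even omnivore-omnivore
  expect_identical(classify_guild_overlap(om, iv), "medium")
  expect_identical(classify_guild_overlap(om, om), "medium")
  # symmetry over random pairs
  pool <- list(fr_ne, ne_fr, fr, in_fr, ne, iv, om)
  for (i in seq_along(pool)) for (j in seq_along(pool))
    expect_identical(classify_guild_overlap(pool[[i]], pool[[j]]),
                     classify_guild_overlap(pool[[j]], pool[[i]]))
  expect_error(classify_guild_overlap(sp_info(NA_character_), fr), "missing")
})

test_that("diet-pairing labels are canonical and order-invariant", {
  expect_identical(diet_pairing_label(sp_info("frugivore"),
                                      sp_info("nectarivore")),
                   "frugivore|nectarivore")
  expect_identical(diet_pairing_label(sp_info("nectarivore"),
                                      sp_info("frugivore")),
                   "frugivore|nectarivore")
  expect_identical(diet_pairing_label(sp_info("granivore"),
                                      sp_info("granivore")),
                   "granivore|granivore")
  # within-species guild order is canonicalized too
  expect_identical(diet_pairing_label(sp_info("frugivore", "nectarivore"),
                                      sp_info("invertivore")),
                   diet_pairing_label(sp_info("nectarivore", "frugivore"),
                                      sp_info("invertivore")))
})

test_that("node distances count internal nodes on the tip-to-tip path", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(phylo_node_distance(tr, "a", "b"), 1L)
  expect_equal(phylo_node_distance(tr, "a", "c"), 3L)
  expect_equal(phylo_node_distance(tr, "a", "c", convention = "edge"), 4L)
  expect_error(phylo_node_distance(tr, "a", "zz"), "zz")
  # matrix route agrees with the per-pair route, and is symmetric
  set.seed(3)
  tr2 <- ape::rtree(12)
  d <- phylo_node_distance_matrix(tr2)
  expect_true(isSymmetric(unname(d)))
  tips <- tr2$tip.label
  for (k in 1:15) {
    ij <- sample(tips, 2)
    expect_equal(d[ij[1], ij[2]],
                 phylo_node_distance(tr2, ij[1], ij[2]))
  }
  # polytomies are followed as given
  tr3 <- ape::read.tree(text = "(a,b,c,(d,e));")
  expect_equal(phylo_node_distance(tr3, "a", "b"), 1L)
  expect_equal(phylo_node_distance(tr3, "a", "d"), 2L)
})

test_that("standardization gives mean 0 / sd 1, five equal bins, and a
           shared bin mean", {
  set.seed(8)
  d <- sample(1:40, 500, replace = TRUE)
  tab <- standardize_and_bin(d)
  expect_equal(mean(tab$standardized), 0, tolerance = 1e-9)
  expect_equal(sd(tab$standardized), 1, tolerance = 1e-9)
  br <- attr(tab, "breaks")
  expect_length(br, 6)
  expect_equal(diff(br), rep(diff(br)[1], 5), tolerance = 1e-12)
  expect_true(all(tab$bin_index %in% 1:5))
  for (b in unique(tab$bin_index))
    expect_length(unique(tab$std_phylo_distance[tab$bin_index == b]), 1)
  # binned value is the mean of the bin's standardized values
  for (b in unique(tab$bin_index))
    expect_equal(unique(tab$std_phylo_distance[tab$bin_index == b]),
                 mean(tab$standardized[tab$bin_index == b]))
  # re-binning the binned values leaves bin membership intact (idempotence)
  tab2 <- standardize_and_bin(d)
  expect_identical(tab$bin_index, tab2$bin_index)
  expect_error(standardize_and_bin(rep(4, 10)), "identical")
  expect_error(standardize_and_bin(c(0, 3)), ">= 1")
})

test_that("co-occurrence sets partition pairs by the defining levels", {
  rec <- data.frame(
    phylo_bin = c(1, 1, 1, 2),
    guild_overlap = "low",
    diet_pairing = "a|b",
    habitat = c("altered", "altered", "intact", "altered"),
    occupancy_pairing = c("3-7", "3-7", "3-7", "3-7"))
  out <- assign_cooc_sets(rec, c("phylo_bin", "habitat",
                                 "occupancy_pairing"))
  expect_equal(out$set_id[1], out$set_id[2])
  expect_false(out$set_id[1] == out$set_id[3])  # habitat differs
  expect_false(out$set_id[1] == out$set_id[4])  # bin differs
  expect_equal(length(unique(out$set_id)), 3)
  # occupancy pairing is unordered: {3,7} built from either order matches
  expect_equal(paste(pmin(3, 7), pmax(3, 7), sep = "-"),
               paste(pmin(7, 3), pmax(7, 3), sep = "-"))
  expect_error(assign_cooc_sets(rec, c("phylo_bin", "habitat")),
               "occupancy_pairing")
  expect_warning(assign_cooc_sets(rec, c("phylo_bin", "habitat"),
                                  allow_missing_occupancy = TRUE),
                 "without occupancy_pairing")
  expect_error(assign_cooc_sets(rec, c("occupancy_pairing")), "two")
})

test_that("restricted pool keeps species present in both habitats", {
  set.seed(4)
  m <- matrix(0L, 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("sp", 1:10)))
  hab <- setNames(rep(c("altered", "intact"), each = 4), rownames(m))
  m[1:4, 1:8] <- rbinom(32, 1, 0.9)   # most species in altered
  m[5:8, 1:6] <- rbinom(24, 1, 0.9)   # first six also in intact
  m[1:4, 1:8][colSums(m[1:4, 1:8]) == 0] <- 1
  # force exactly: sp1..sp6 in both, sp7..sp8 only altered, sp9..sp10 absent
  m[, 7:8] <- 0; m[1, 7:8] <- 1
  m[, 9:10] <- 0; m[5, 9] <- 1
  for (j in 1:6) { m[1, j] <- 1; m[5, j] <- 1 }
  rp <- restrict_species_pool(m, hab)
  expect_setequal(colnames(rp), paste0("sp", 1:6))
  expect_equal(attr(rp, "retained_fraction"), 6 / 10)
  # pairing after restriction gives choose(k, 2) per habitat subset
  pc <- build_pair_counts(rp, sites = names(hab)[hab == "intact"])
  expect_equal(nrow(pc), choose(sum(colSums(rp[5:8, ]) > 0), 2))
})

test_that("pair records carry order-invariant covariates and shared
           standardization across habitats", {
  b <- simulate_matrix_level(n_species = 15, n_sites = 20, seed = 2)
  rec <- build_pair_records(b$matrix, b$site_habitat, b$guilds, b$tree)
  expect_true(all(rec$species_a < rec$species_b))
  expect_true(all(rec$habitat %in% c("altered", "intact")))
  # each habitat contributes choose(k_present, 2) records
  for (h in c("altered", "intact")) {
    sel <- rownames(b$matrix)[b$site_habitat == h]
    k <- sum(colSums(b$matrix[sel, , drop = FALSE]) > 0)
    expect_equal(sum(rec$habitat == h), choose(k, 2))
  }
  # occupancy pairing is invariant to species order by construction
  expect_true(all(mapply(function(o, a, b2) {
    parts <- as.integer(strsplit(o, "-", fixed = TRUE)[[1]])
    parts[1] <= parts[2]
  }, rec$occupancy_pairing)))
  # covariates identical for the same unordered pair across habitats
  key <- paste(rec$species_a, rec$species_b)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    one <- rec[key == dup[1], ]
    expect_length(unique(one$guild_overlap), 1)
    expect_length(unique(one$diet_pairing), 1)
    expect_length(unique(one$raw_node_distance), 1)
  }
  # standardization is over all analysed records pooled
  z <- (log(rec$raw_node_distance) - mean(log(rec$raw_node_distance))) /
    sd(log(rec$raw_node_distance))
  expect_equal(mean(z), 0, tolerance = 1e-9)
})
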