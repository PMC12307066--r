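#' Collapse a habitat-disturbance category to altered/intact
#'
#' Site registries record nine disturbance categories; the analysis uses
#' two: `"none"` maps to `intact`, every other recognized category
#' (cropland, pasture, plantation, secondary forest, fragment, disturbed
#' forest, inhabited area, combined) to `altered`. Matching is
#' case-insensitive and ignores surrounding whitespace.
#'
#' @param category character vector of disturbance categories.
#' @param extra_intact,extra_altered optional character vectors of
#'   additional category synonyms to accept.
#' @return Character vector with values `"altered"` or `"intact"`.
#' @examples
#' collapse_habitat(c("none", "secondary forest"))
#' @export
collapse_habitat <- function(category, extra_intact = character(),
                             extra_altered = character()) {
  norm <- tolower(trimws(category))
  intact_set <- c("none", tolower(trimws(extra_intact)))
  altered_set <- c("cropland", "pasture", "plantation", "secondary forest",
                   "fragment", "disturbed forest", "inhabited area",
                   "combined", tolower(trimws(extra_altered)))
  bad <- !(norm %in% c(intact_set, altered_set))
  if (any(bad))
    stop("unrecognized habitat categories: ",
         paste(unique(category[bad]), collapse = ", "),
         "; allowed: ", paste(c(intact_set, altered_set), collapse = ", "),
         call. = FALSE)
  ifelse(norm %in% intact_set, "intact", "altered")
}

coerce_binary_matrix <- function(mat) {
  m <- as.matrix(mat)
  if (!is.numeric(m)) stop("occurrence matrix must be numeric", call. = FALSE)
  if (any(m < 0)) stop("occurrence matrix has negative entries", call. = FALSE)
  storage.mode(m) <- "integer"
  m[m > 0L] <- 1L  # any positive abundance counts as presence
  if (is.null(colnames(m)))
    stop("occurrence matrix needs species column names", call. = FALSE)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("site", seq_len(nrow(m)))
  m
}

#' Build co-occurrence counts for every species pair
#'
#' Enumerates all unordered pairs of species present (occupancy >= 1)
#' within a subset of sites and tallies, for each pair, the within-subset
#' occupancies and the number of subset sites where both species occur.
#' Species absent from the subset appear in no pair, so the result has
#' exactly `choose(k, 2)` rows for `k` species present.
#'
#' @param matrix site-by-species occurrence matrix (rows = sites, columns
#'   = species, named); positive abundances are coerced to presence.
#' @param sites optional character vector of site IDs (row names) to
#'   restrict to; default all sites.
#' @return A data frame with columns `species_a`, `species_b` (ordered so
#'   `species_a < species_b`), `n_A`, `n_notA`, `n_B`, `n_AB`, carrying
#'   the subset size as attribute `n_sites`.
#' @examples
#' m <- rbind(s1 = c(A = 1, B = 0), s2 = c(A = 1, B = 1),
#'            s3 = c(A = 0, B = 1), s4 = c(A = 0, B = 0))
#' build_pair_counts(m)
#' @export
build_pair_counts <- function(matrix, sites = NULL) {
  m <- coerce_binary_matrix(matrix)
  if (!is.null(sites)) {
    missing_sites <- setdiff(sites, rownames(m))
    if (length(missing_sites))
      stop("sites not in matrix: ", paste(missing_sites, collapse = ", "),
           call. = FALSE)
    m <- m[sites, , drop = FALSE]
  }
  occ <- colSums(m)
  m <- m[, occ >= 1L, drop = FALSE]
  k <- ncol(m)
  if (k < 2L) {
    warning("fewer than two species present in the site subset")
    out <- data.frame(species_a = character(), species_b = character(),
                      n_A = integer(), n_notA = integer(),
                      n_B = integer(), n_AB = integer())
    attr(out, "n_sites") <- nrow(m)
    return(out)
  }
  m <- m[, order(colnames(m)), drop = FALSE]
  occ <- colSums(m)
  co <- crossprod(m)  # co[i, j] = joint occupancy of species i and j
  iu <- which(upper.tri(co), arr.ind = TRUE)
  nsite <- nrow(m)
  out <- data.frame(
    species_a = colnames(m)[iu[, 1]],
    species_b = colnames(m)[iu[, 2]],
    n_A = as.integer(occ[iu[, 1]]),
    n_notA = nsite - as.integer(occ[iu[, 1]]),
    n_B = as.integer(occ[iu[, 2]]),
    n_AB = as.integer(co[iu]),
    stringsAsFactors = FALSE)
  attr(out, "n_sites") <- nsite
  out
}

species_guild_set <- function(primary, secondary) {
  g <- c(primary, secondary)
  g <- g[!is.na(g) & nzchar(g)]
  unique(tolower(trimws(g)))
}

#' Classify dietary-guild overlap of a species pair
#'
#' A pair is `high` overlap when the two species carry the same set of
#' primary and secondary guilds, regardless of which is primary and which
#' secondary (a frugivore-nectarivore equals a nectarivore-frugivore);
#' `medium` when the species share some but not all guild assignments, or
#' when either species is an omnivore; `low` when they share none.
#' Guild overlap proxies the potential for food competition, with the
#' low-overlap group serving as the control.
#'
#' @param a,b lists (or one-row data frames) with fields `primary_guild`
#'   and `secondary_guild` (`NA` or `""` when absent).
#' @return `"low"`, `"medium"` or `"high"`.
#' @examples
#' classify_guild_overlap(
#'   list(primary_guild = "frugivore", secondary_guild = "nectarivore"),
#'   list(primary_guild = "nectarivore", secondary_guild = "frugivore"))
#' @export
classify_guild_overlap <- function(a, b) {
  ga <- species_guild_set(a$primary_guild, a$secondary_guild)
  gb <- species_guild_set(b$primary_guild, b$secondary_guild)
  if (length(ga) == 0 || length(gb) == 0)
    stop("species with missing guild information cannot be classified",
         call. = FALSE)
  if ("omnivore" %in% c(ga, gb)) return("medium")
  if (setequal(ga, gb)) return("high")
  if (length(intersect(ga, gb)) > 0) return("medium")
  "low"
}

species_guild_label <- function(primary, secondary) {
  paste(sort(species_guild_set(primary, secondary)), collapse = "-")
}

#' Canonical diet-pairing label for a species pair
#'
#' The unordered combination of the two species' full guild labels, e.g.
#' `"frugivore|nectarivore"` or `"granivore|granivore"`. Each species'
#' own guild string is first canonicalized by sorting its guilds, and the
#' two species labels are then sorted, so the result is invariant both to
#' the order of a species' primary/secondary guilds and to the order of
#' the two species.
#'
#' @inheritParams classify_guild_overlap
#' @return A single string.
#' @export
diet_pairing_label <- function(a, b) {
  la <- species_guild_label(a$primary_guild, a$secondary_guild)
  lb <- species_guild_label(b$primary_guild, b$secondary_guild)
  paste(sort(c(la, lb)), collapse = "|")
}

#' Phylogenetic distance between two tips in branch nodes
#'
#' Counts nodes along the unique path between two tips. Under the default
#' `"internal"` convention the count is the number of internal nodes
#' strictly between the tips (sister tips are at distance 1); under the
#' `"edge"` convention it is the number of edges on the path (sister tips
#' at distance 2). Both are symmetric; the choice only shifts and
#' stretches the standardized scale downstream.
#'
#' @param tree an [ape::phylo] tree (polytomies allowed).
#' @param a,b tip labels.
#' @param convention `"internal"` (default) or `"edge"`.
#' @return A positive integer.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' phylo_node_distance(tr, "a", "c")  # 3
#' @export
phylo_node_distance <- function(tree, a, b,
                                convention = c("internal", "edge")) {
  convention <- match.arg(convention)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("tip not in tree: ", a, call. = FALSE)
  if (is.na(ib)) stop("tip not in tree: ", b, call. = FALSE)
  if (ia == ib) return(0L)
  path <- ape::nodepath(tree, ia, ib)  # includes both tips
  n_edges <- length(path) - 1L
  if (convention == "edge") n_edges else n_edges - 1L
}

#' All pairwise tip distances in branch nodes
#'
#' Same conventions as [phylo_node_distance()], computed for every tip
#' pair at once by measuring path lengths on the tree with unit branch
#' lengths (a path through k internal nodes has k + 1 edges).
#'
#' @inheritParams phylo_node_distance
#' @param tips optional subset of tip labels.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
phylo_node_distance_matrix <- function(tree, tips = NULL,
                                       convention = c("internal", "edge")) {
  convention <- match.arg(convention)
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  d <- stats::cophenetic(tr)  # edge counts between tips
  if (!is.null(tips)) {
    missing_tips <- setdiff(tips, rownames(d))
    if (length(missing_tips))
      stop("tips not in tree: ", paste(missing_tips, collapse = ", "),
           call. = FALSE)
    d <- d[tips, tips, drop = FALSE]
  }
  if (convention == "internal") d <- d - 1
  diag(d) <- 0
  storage.mode(d) <- "integer"
  d
}

#' Standardize and bin phylogenetic distances
#'
#' Node-count distances are logged, centred and scaled to mean 0 and
#' variance 1 over all analysed pairs, then cut into five equal-width
#' bins spanning the standardized range (left-closed; the last bin is
#' right-closed). Every pair in a bin is assigned that bin's mean
#' standardized distance, so the continuous covariate takes at most five
#' values; this pooling is what lets pairs share co-occurrence sets.
#'
#' @param distances integer vector of node-count distances (all >= 1).
#' @param n_bins number of equal-width bins (default 5).
#' @return A data frame with columns `raw_node_distance`, `standardized`,
#'   `bin_index`, `std_phylo_distance` (the bin mean), with the bin
#'   breaks and per-bin means as attributes `breaks` and `bin_means`.
#' @export
standardize_and_bin <- function(distances, n_bins = 5L) {
  d <- as.numeric(distances)
  if (any(d < 1)) stop("node-count distances must be >= 1", call. = FALSE)
  ld <- log(d)
  if (stats::sd(ld) == 0)
    stop("all distances identical: cannot standardize", call. = FALSE)
  z <- (ld - mean(ld)) / stats::sd(ld)
  breaks <- seq(min(z), max(z), length.out = n_bins + 1L)
  bin <- findInterval(z, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  bin_means <- tapply(z, factor(bin, levels = seq_len(n_bins)), mean)
  out <- data.frame(raw_node_distance = as.integer(distances),
                    standardized = z,
                    bin_index = as.integer(bin),
                    std_phylo_distance = as.numeric(bin_means[bin]))
  attr(out, "breaks") <- breaks
  attr(out, "bin_means") <- as.numeric(bin_means)
  out
}

#' Assign species pairs to co-occurrence sets
#'
#' A co-occurrence set pools all pairs sharing the same levels of the
#' chosen defining variables; each set later receives one random
#' intercept. Occupancy pairing (the unordered pair of the two species'
#' occupancies) must be among the defining variables, because occupancy
#' is the primary determinant of how much a co-occurrence count can say
#' about the association; overriding this requires
#' `allow_missing_occupancy = TRUE` and is logged with a warning.
#'
#' @param records a pair-record data frame (see [build_pair_records()])
#'   containing the columns named in `defining_vars`.
#' @param defining_vars character vector, two or more of `"phylo_bin"`,
#'   `"guild_overlap"`, `"diet_pairing"`, `"habitat"`,
#'   `"occupancy_pairing"`.
#' @param allow_missing_occupancy logical escape hatch.
#' @return `records` with a `set_id` column (canonical concatenation of
#'   the defining levels).
#' @export
assign_cooc_sets <- function(records,
                             defining_vars = c("phylo_bin", "diet_pairing",
                                               "habitat", "occupancy_pairing"),
                             allow_missing_occupancy = FALSE) {
  allowed <- c("phylo_bin", "guild_overlap", "diet_pairing", "habitat",
               "occupancy_pairing")
  bad <- setdiff(defining_vars, allowed)
  if (length(bad))
    stop("unknown set-defining variables: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(defining_vars) < 2L)
    stop("at least two set-defining variables are required", call. = FALSE)
  if (!("occupancy_pairing" %in% defining_vars)) {
    if (!allow_missing_occupancy)
      stop("occupancy_pairing must be among the set-defining variables ",
           "(override with allow_missing_occupancy = TRUE)", call. = FALSE)
    warning("defining co-occurrence sets without occupancy_pairing")
  }
  miss <- setdiff(defining_vars, names(records))
  if (length(miss))
    stop("records lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vars <- sort(defining_vars)  # canonical order, independent of input order
  records$set_id <- do.call(paste,
                            c(lapply(vars, function(v) paste0(v, "=", records[[v]])),
                              sep = ";"))
  attr(records, "set_defining_vars") <- vars
  records
}

#' Restrict the species pool to species present in both habitats
#'
#' Keeps only species with occupancy of at least one site in the altered
#' subset and at least one in the intact subset. Comparing fits on the
#' full and restricted pools separates changed spatial relationships from
#' compositional turnover between habitat types.
#'
#' @param matrix site-by-species occurrence matrix.
#' @param site_habitat named character vector (`"altered"`/`"intact"` per
#'   site ID) covering the matrix rows.
#' @return The column-subset matrix, with the retained fraction of
#'   species as attribute `retained_fraction`.
#' @export
restrict_species_pool <- function(matrix, site_habitat) {
  m <- coerce_binary_matrix(matrix)
  miss <- setdiff(rownames(m), names(site_habitat))
  if (length(miss))
    stop("sites without habitat assignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  hab <- site_habitat[rownames(m)]
  alt <- m[hab == "altered", , drop = FALSE]
  int <- m[hab == "intact", , drop = FALSE]
  if (nrow(alt) == 0 || nrow(int) == 0)
    stop("both habitat subsets must be non-empty", call. = FALSE)
  keep <- colSums(alt) >= 1L & colSums(int) >= 1L
  if (!any(keep))
    stop("no species occur in both habitat types", call. = FALSE)
  out <- m[, keep, drop = FALSE]
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Build the full pair-record table for an assemblage
#'
#' The end-to-end data-preparation step: for each habitat subset,
#' enumerate all pairs of species present and their co-occurrence counts;
#' attach dietary-guild overlap, the diet-pairing label, the occupancy
#' pairing and the standardized (binned) phylogenetic distance; and
#' assign co-occurrence sets. Phylogenetic standardization is computed
#' over all analysed pairs with both habitats pooled, so the covariate
#' scale (and hence a shared slope) means the same thing in both
#' habitats. Species absent from the guild table or the tree must be
#' excluded beforehand (see [read_assemblage()]).
#'
#' @param matrix site-by-species occurrence matrix.
#' @param site_habitat named character vector, `"altered"`/`"intact"` per
#'   site.
#' @param guilds data frame with `species_id`, `primary_guild`,
#'   `secondary_guild`.
#' @param tree an [ape::phylo] tree containing every matrix species as a
#'   tip.
#' @param set_defining_vars passed to [assign_cooc_sets()].
#' @param node_convention passed to [phylo_node_distance_matrix()].
#' @param n_bins number of phylogenetic-distance bins.
#' @return A data frame with one row per pair per habitat: `species_a`,
#'   `species_b`, the four counts, `habitat`, `guild_overlap`,
#'   `diet_pairing`, `raw_node_distance`, `std_phylo_distance`,
#'   `phylo_bin`, `occupancy_pairing` and `set_id`.
#' @export
build_pair_records <- function(matrix, site_habitat, guilds, tree,
                               set_defining_vars = c("phylo_bin",
                                                     "diet_pairing",
                                                     "habitat",
                                                     "occupancy_pairing"),
                               node_convention = "internal",
                               n_bins = 5L) {
  m <- coerce_binary_matrix(matrix)
  sp <- colnames(m)
  if (!all(sp %in% guilds$species_id))
    stop("species missing from guild table: ",
         paste(setdiff(sp, guilds$species_id), collapse = ", "),
         call. = FALSE)
  if (!all(sp %in% tree$tip.label))
    stop("species missing from tree: ",
         paste(setdiff(sp, tree$tip.label), collapse = ", "), call. = FALSE)
  gtab <- guilds[match(sp, guilds$species_id), , drop = FALSE]
  rownames(gtab) <- sp
  hab <- site_habitat[rownames(m)]
  if (anyNA(hab))
    stop("sites without habitat assignment", call. = FALSE)

  per_hab <- lapply(c("altered", "intact"), function(h) {
    sel <- rownames(m)[hab == h]
    if (length(sel) == 0) return(NULL)
    pc <- build_pair_counts(m, sites = sel)
    if (nrow(pc) == 0) return(NULL)
    pc$habitat <- h
    pc
  })
  rec <- do.call(rbind, per_hab)
  if (is.null(rec) || nrow(rec) == 0)
    stop("no species pairs found in any habitat subset", call. = FALSE)

  ginfo <- function(id) list(primary_guild = gtab[id, "primary_guild"],
                             secondary_guild = gtab[id, "secondary_guild"])
  # covariates are per unordered species pair; compute once, then join
  upairs <- unique(rec[, c("species_a", "species_b")])
  dmat <- phylo_node_distance_matrix(tree, tips = sp,
                                     convention = node_convention)
  upairs$raw_node_distance <- dmat[cbind(upairs$species_a, upairs$species_b)]
  upairs$guild_overlap <- mapply(function(a, b)
    classify_guild_overlap(ginfo(a), ginfo(b)),
    upairs$species_a, upairs$species_b)
  upairs$diet_pairing <- mapply(function(a, b)
    diet_pairing_label(ginfo(a), ginfo(b)),
    upairs$species_a, upairs$species_b)

  rec <- merge(rec, upairs, by = c("species_a", "species_b"), sort = FALSE)
  # standardize over every analysed record, habitats pooled, so the
  # covariate scale is shared by both habitats
  ph <- standardize_and_bin(rec$raw_node_distance, n_bins = n_bins)
  rec$std_phylo_distance <- ph$std_phylo_distance
  rec$phylo_bin <- ph$bin_index
  rec$occupancy_pairing <- paste(pmin(rec$n_A, rec$n_B),
                                 pmax(rec$n_A, rec$n_B), sep = "-")
  rec <- assign_cooc_sets(rec, defining_vars = set_defining_vars)
  rec <- rec[order(rec$habitat, rec$species_a, rec$species_b), ]
  rownames(rec) <- NULL
  rec
}
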