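#' Read and cross-validate the four assemblage input files
#'
#' Reads the site-by-species occurrence table (CSV/TSV; sites as rows,
#' first column site IDs, header row of species IDs, cells 0/1 or
#' abundances), the site metadata (columns `site_id`,
#' `habitat_category`), the dietary-guild table (columns `species_id`,
#' `primary_guild`, `secondary_guild`; secondary may be empty) and a
#' Newick tree. Species are retained only when they appear in the
#' matrix, carry a primary guild, and are a tree tip (after optional
#' normalization of spaces vs underscores in tip labels); everything
#' else is dropped and listed in the exclusion manifest. Habitat
#' categories are collapsed to altered/intact.
#'
#' @param matrix_path,sites_path,guilds_path,tree_path file paths.
#' @param normalize_tips replace spaces with underscores on both sides
#'   before matching tip labels to species IDs (default TRUE).
#' @param quiet suppress the exclusion message.
#' @return A list of class `assemblage_bundle`: `matrix` (binary,
#'   filtered), `sites`, `site_habitat`, `guilds`, `tree` (pruned to
#'   the retained species) and `manifest` (data frame of excluded
#'   species and reasons).
#' @export
read_assemblage <- function(matrix_path, sites_path, guilds_path, tree_path,
                            normalize_tips = TRUE, quiet = FALSE) {
  m <- read_occurrence_matrix(matrix_path)
  sites <- utils::read.csv(sites_path, stringsAsFactors = FALSE)
  need <- c("site_id", "habitat_category")
  if (!all(need %in% names(sites)))
    stop(sites_path, ": needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  guilds <- utils::read.csv(guilds_path, stringsAsFactors = FALSE)
  needg <- c("species_id", "primary_guild")
  if (!all(needg %in% names(guilds)))
    stop(guilds_path, ": needs columns ", paste(needg, collapse = ", "),
         call. = FALSE)
  if (!("secondary_guild" %in% names(guilds)))
    guilds$secondary_guild <- NA_character_
  guilds$secondary_guild[!nzchar(trimws(
    ifelse(is.na(guilds$secondary_guild), "", guilds$secondary_guild)))] <-
    NA_character_
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop("could not parse tree: ", tree_path, call. = FALSE)

  norm <- function(x) if (normalize_tips) gsub(" ", "_", x, fixed = TRUE)
    else x
  tree$tip.label <- norm(tree$tip.label)
  colnames(m) <- norm(colnames(m))
  guilds$species_id <- norm(guilds$species_id)

  missing_sites <- setdiff(rownames(m), sites$site_id)
  if (length(missing_sites))
    stop("matrix sites missing from site metadata: ",
         paste(missing_sites, collapse = ", "), call. = FALSE)
  site_habitat <- stats::setNames(collapse_habitat(sites$habitat_category),
                                  sites$site_id)[rownames(m)]

  sp <- colnames(m)
  has_guild <- sp %in% guilds$species_id[!is.na(guilds$primary_guild) &
                                           nzchar(guilds$primary_guild)]
  in_tree <- sp %in% tree$tip.label
  manifest <- data.frame(
    species_id = sp[!(has_guild & in_tree)],
    reason = paste0(ifelse(!has_guild[!(has_guild & in_tree)],
                           "no dietary guild; ", ""),
                    ifelse(!in_tree[!(has_guild & in_tree)],
                           "not a tree tip", "")),
    stringsAsFactors = FALSE)
  keep <- sp[has_guild & in_tree]
  if (length(keep) == 0)
    stop("no species remain after matching matrix, guilds and tree",
         call. = FALSE)
  if (!quiet && nrow(manifest))
    message(nrow(manifest), " species excluded for incomplete dietary or ",
            "phylogenetic information")
  m <- m[, keep, drop = FALSE]
  tree <- ape::keep.tip(tree, keep)
  out <- list(matrix = m,
              sites = sites[match(rownames(m), sites$site_id), ],
              site_habitat = site_habitat,
              guilds = guilds[guilds$species_id %in% keep, ],
              tree = tree, manifest = manifest)
  class(out) <- "assemblage_bundle"
  out
}

#' @rdname read_assemblage
#' @param path occurrence matrix path (`.tsv`/`.txt` read as
#'   tab-separated, otherwise comma-separated).
#' @export
read_occurrence_matrix <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop(path, ": expected a site-ID column plus species columns",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!is.numeric(m))
    stop(path, ": non-numeric occurrence entries", call. = FALSE)
  coerce_binary_matrix(m)
}

#' Write an assemblage bundle as the four standard input files
#'
#' Emits `matrix.csv`, `sites.csv`, `guilds.csv` and `tree.nwk` into a
#' directory, in the formats [read_assemblage()] consumes, so generator
#' output round-trips through the readers.
#'
#' @param bundle an `assemblage_bundle` (e.g. from
#'   [simulate_matrix_level()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_assemblage <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.csv"),
             sites = file.path(dir, "sites.csv"),
             guilds = file.path(dir, "guilds.csv"),
             tree = file.path(dir, "tree.nwk"))
  mdf <- data.frame(site_id = rownames(bundle$matrix),
                    bundle$matrix, check.names = FALSE)
  utils::write.csv(mdf, paths["matrix"], row.names = FALSE)
  utils::write.csv(bundle$sites, paths["sites"], row.names = FALSE)
  g <- bundle$guilds
  g$secondary_guild[is.na(g$secondary_guild)] <- ""
  utils::write.csv(g, paths["guilds"], row.names = FALSE)
  ape::write.tree(bundle$tree, paths["tree"])
  invisible(paths)
}

#' Export posterior draws, a selection trace or a null summary as CSV
#'
#' Thin convenience writers with documented column orders, mirroring the
#' selection-trace and null-summary tables users inspect.
#'
#' @param x an `mcm_fit`, `mcm_selection` or `mcm_null` object.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_mcm_csv <- function(x, path) {
  if (inherits(x, "mcm_fit")) {
    out <- cbind(chain = x$chain,
                 as.data.frame(fit_param_matrix(x, include_re = TRUE)))
  } else if (inherits(x, "mcm_selection")) {
    out <- x$trace
  } else if (inherits(x, "mcm_null")) {
    out <- x$summary
  } else stop("unsupported object for CSV export", call. = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Provenance block for a run
#'
#' A small named list recording the package version, R version, seed and
#' configuration of a run; written alongside artifacts so every output
#' is reproducible from its provenance alone.
#'
#' @param seed the master seed of the run.
#' @param config a named list of the run's settings.
#' @return A named list with `package_version`, `r_version`, `seed`,
#'   `timestamp` and `config`.
#' @export
provenance_block <- function(seed, config = list()) {
  list(package_version =
         as.character(utils::packageVersion("coocmix")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = config)
}
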