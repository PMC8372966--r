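#' Read and write occurrence tables
#'
#' Delimited text with header `species,longitude,latitude` (WGS84
#' decimal degrees).
#'
#' @param occurrences data frame with those three columns.
#' @param path file path.
#' @return `write_occurrences` returns `path` invisibly;
#'   `read_occurrences` returns the data frame.
#' @export
write_occurrences <- function(occurrences, path) {
  stopifnot(all(c("species", "longitude", "latitude") %in%
                  names(occurrences)))
  utils::write.csv(occurrences[, c("species", "longitude", "latitude")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write chronograms as Newick
#'
#' Thin wrappers over `ape`; multi-tree files hold one tree per line.
#'
#' @param tree a `phylo` or `multiPhylo` object.
#' @param path file path.
#' @return `write_chronogram` returns `path` invisibly;
#'   `read_chronogram` returns a `phylo` (or `multiPhylo`).
#' @export
write_chronogram <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_chronogram
#' @export
read_chronogram <- function(path) {
  ape::read.tree(path)
}

#' Write species climate summaries
#'
#' One row per species with the 60 statistic columns, `n_pixels`, and
#' (optionally) per-scheme microhabitat codes merged in.
#'
#' @param summaries output of [summarize_species()].
#' @param path file path.
#' @param classifications optional output of [classify_table()] to
#'   merge by species.
#' @return `path`, invisibly.
#' @export
write_species_summaries <- function(summaries, path,
                                    classifications = NULL) {
  out <- summaries
  if (!is.null(classifications))
    out <- merge(out, classifications, by = "species", all.x = TRUE,
                 sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pairwise overlap table
#'
#' Columns `species_a,species_b,pair_type,D,I,geo_km,phylo_dist`.
#'
#' @param pair_table output of [build_pair_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pair_table, path) {
  cols <- c("species_a", "species_b", "pair_type", "D", "I", "geo_km",
            "phylo_dist")
  utils::write.csv(as.data.frame(pair_table)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
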