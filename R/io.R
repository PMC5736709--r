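#' Write a hit/survey table to TSV
#'
#' Coordinates are 0-based half-open, as produced by [scan_sequence].
#'
#' @param hits Data.frame from [scan_sequence], [classify_hits] or
#'   [survey_proteomes].
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster set to TSV (representative, member)
#'
#' @param clusters A `cluster_set` from [reduce_redundancy].
#' @param path Output file.
#' @export
write_clusters_tsv <- function(clusters, path) {
  write.table(clusters$assignments[, c("representative", "sequence_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D Labelled symmetric matrix from [ml_distance_matrix].
#' @param path Output file.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.6f", D[i, ]), collapse = "  ")), con)
  invisible(path)
}

#' Write a tree (with any bootstrap supports) to Newick
#'
#' @param tree An `ape::phylo` or a `bootstrap_nj` result (full-data tree).
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "bootstrap_nj")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
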