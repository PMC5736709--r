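#' Protein multiple alignment container
#'
#' Holds an aligned set of amino-acid sequences as a character matrix
#' (one row per sequence, one column per alignment column) together with
#' sequence identifiers. Gap characters `-` and `.` are normalised to `-`.
#'
#' @param seqs A named character vector of equal-length aligned sequences,
#'   a `Biostrings::AAStringSet`, or a character matrix of single residues.
#' @param ids Optional identifiers; defaults to names of `seqs`.
#' @return An object of class `aa_alignment` with elements `ids`, `mat`
#'   (n x n_columns character matrix) and `n_columns`.
#' @examples
#' aln <- aa_alignment(c(a = "AC-D", b = "ACED"))
#' aln$n_columns
#' @export
aa_alignment <- function(seqs, ids = NULL) {
  if (inherits(seqs, "aa_alignment")) return(seqs)
  if (inherits(seqs, "AAStringSet")) {
    ids <- ids %||% names(seqs)
    seqs <- as.character(seqs)
  }
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    ids <- ids %||% rownames(mat) %||% paste0("seq", seq_len(nrow(mat)))
  } else {
    ids <- ids %||% names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- as.character(seqs)
    if (length(seqs) == 0L) stop("no sequences")
    w <- unique(nchar(seqs))
    if (length(w) != 1L)
      stop("aligned sequences must all have the same length")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (nrow(mat) == 0L) stop("no sequences")
  if (ncol(mat) < 1L) stop("alignment has no columns")
  mat[mat == "."] <- "-"
  bad <- !(mat %in% c(AA_ALPHABET, AA_AMBIGUOUS, "-"))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("unknown residue '%s' in alignment", mat[i]))
  }
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, n_columns = ncol(mat)),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an aligned (or plain) protein FASTA file
#'
#' @param path FASTA file; gaps `-`/`.` allowed.
#' @param aligned If `TRUE` (default) return an [aa_alignment], else a
#'   named character vector of sequences.
#' @export
read_fasta_aa <- function(path, aligned = TRUE) {
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e) stop(sprintf(
                  "FASTA parse failure for '%s': %s", path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(x))
  s <- setNames(as.character(x), ids)
  if (aligned) aa_alignment(s) else s
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (may contain gaps) or [aa_alignment].
#' @param path Output file.
#' @export
write_fasta_aa <- function(seqs, path) {
  if (inherits(seqs, "aa_alignment"))
    seqs <- setNames(apply(seqs$mat, 1L, paste, collapse = ""), seqs$ids)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(gsub("(.{70})", "\\1\n", seqs[[i]]), con)
  }
  invisible(path)
}

# per-column gap fraction and the match-column mask
match_mask <- function(alignment, match_fraction = 0.5) {
  aln <- aa_alignment(alignment)
  gapfrac <- colMeans(aln$mat == "-")
  gapfrac < match_fraction
}
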