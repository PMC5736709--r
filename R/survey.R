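#' Survey a proteome for CBM40 domains and sialidase co-occurrence
#'
#' Scans every protein with the CBM40 subtype models (plus any decoys),
#' classifies hits by cross-model score comparison, and screens the full
#' protein with a GH33 sialidase model. Proteins with at least one
#' classified CBM40 hit (label canonical or vibrio) produce one survey
#' record.
#'
#' @param proteins Named character vector of protein sequences, or a FASTA
#'   path.
#' @param cbm40_models Named list of `profile_hmm`s containing at least the
#'   models named by `canonical` and `vibrio`; extra entries act as decoys.
#' @param gh33_model A `profile_hmm` for the sialidase catalytic domain, or
#'   `NULL` to skip the co-occurrence screen.
#' @param taxonomy Optional data.frame with columns
#'   `sequence_id`, `phylum`, `class`, `genus` (or a TSV path).
#' @param canonical,vibrio Names of the two CBM40 subtype models.
#' @param report_threshold_bits Reporting threshold (default 10).
#' @param margin_bits Decoy margin for classification (default 0).
#' @return A data.frame ordered by `sequence_id` with one row per CBM40 hit:
#'   `sequence_id`, `start`, `end`, `model`, `bits`, `label`, `margin_bits`,
#'   `tie`, `has_sialidase`, `protein_length`, `phylum`, `class`, `genus`.
#' @export
survey_proteomes <- function(proteins, cbm40_models, gh33_model = NULL,
                             taxonomy = NULL, canonical = "canonical",
                             vibrio = "vibrio", report_threshold_bits = 10,
                             margin_bits = 0) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins))
    proteins <- read_fasta_aa(proteins, aligned = FALSE)
  if (anyDuplicated(names(proteins)))
    stop(sprintf("duplicate sequence ids (first: '%s')",
                 names(proteins)[duplicated(names(proteins))][1]))
  if (is.character(taxonomy) && length(taxonomy) == 1L)
    taxonomy <- read.delim(taxonomy, stringsAsFactors = FALSE)
  decoys <- setdiff(names(cbm40_models), c(canonical, vibrio))

  rows <- list()
  for (id in sort(names(proteins))) {
    seqi <- proteins[[id]]
    hits <- scan_sequence(cbm40_models, seqi, report_threshold_bits,
                          sequence_id = id)
    if (nrow(hits) == 0L) next
    hits <- classify_hits(hits, canonical, vibrio, decoys,
                          margin_bits, report_threshold_bits)
    hits <- hits[hits$label %in% c("canonical", "vibrio"), , drop = FALSE]
    if (nrow(hits) == 0L) next
    has_gh33 <- FALSE
    if (!is.null(gh33_model)) {
      g <- viterbi_align(gh33_model, seqi)
      has_gh33 <- is.finite(g$bit_score) &&
        g$bit_score >= report_threshold_bits
    }
    hits$has_sialidase <- has_gh33
    hits$protein_length <- nchar(seqi)
    rows[[id]] <- hits[, c("sequence_id", "start", "end", "model", "bits",
                           "label", "margin_bits", "tie", "has_sialidase",
                           "protein_length")]
  }
  out <- if (length(rows) == 0L) {
    data.frame(sequence_id = character(0), start = integer(0),
               end = integer(0), model = character(0), bits = numeric(0),
               label = character(0), margin_bits = numeric(0),
               tie = logical(0), has_sialidase = logical(0),
               protein_length = integer(0))
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  for (col in c("phylum", "class", "genus"))
    out[[col]] <- rep(NA_character_, nrow(out))
  if (!is.null(taxonomy) && nrow(out) > 0L) {
    m <- match(out$sequence_id, taxonomy$sequence_id)
    for (col in c("phylum", "class", "genus"))
      out[[col]] <- taxonomy[[col]][m]
  }
  out
}

#' Fraction of CBM40 records of a type that carry a sialidase
#'
#' @param records Survey table from [survey_proteomes] (one row per hit;
#'   proteins are counted once per distinct `sequence_id` within the label).
#' @param label `"canonical"` or `"vibrio"`.
#' @return Proportion in `[0, 1]`.
#' @export
cooccurrence_fraction <- function(records, label) {
  r <- records[records$label == label, , drop = FALSE]
  if (nrow(r) == 0L) stop(sprintf("empty class '%s'", label))
  r <- r[!duplicated(r$sequence_id), , drop = FALSE]
  mean(r$has_sialidase)
}

#' Percent identity between two protein sequences
#'
#' In `aligned_columns` mode the sequences must be pre-aligned (equal
#' lengths including gaps); columns gapped in both sequences are excluded
#' (pairwise deletion) and a gap against a residue counts as a mismatch.
#' In `global_align` mode a Needleman-Wunsch global alignment is computed
#' first (BLOSUM62, gap opening 10, gap extension 0.5) and identity is
#' taken over all alignment columns, gaps counting in the denominator.
#'
#' @param seq_a,seq_b Amino-acid strings (gapped in `aligned_columns` mode).
#' @param mode `"aligned_columns"` or `"global_align"`.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              mode = c("global_align", "aligned_columns")) {
  mode <- match.arg(mode)
  if (mode == "aligned_columns") {
    a <- strsplit(toupper(seq_a), "")[[1]]
    b <- strsplit(toupper(seq_b), "")[[1]]
    if (length(a) != length(b))
      stop("length mismatch in aligned_columns mode")
    a[a == "."] <- "-"; b[b == "."] <- "-"
    use <- !(a == "-" & b == "-")
    if (!any(use)) stop("no comparable columns")
    ident <- a[use] == b[use] & a[use] != "-"
    return(100 * sum(ident) / sum(use))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  100 * sum(a == b & a != "-") / length(a)
}

#' Greedy redundancy reduction at an identity threshold
#'
#' Sequences are considered in order of decreasing length (ties broken by
#' identifier); each sequence joins the first existing representative to
#' which its global percent identity is at least `100 * threshold`,
#' otherwise it founds a new cluster.
#'
#' @param sequences Named character vector of (unaligned) sequences.
#' @param threshold Identity proportion in (0, 1); default 0.80.
#' @return An object of class `cluster_set`: list with `clusters` (list of
#'   `representative_id` / `member_ids`), `identity_threshold`, and the
#'   `assignments` data.frame.
#' @export
reduce_redundancy <- function(sequences, threshold = 0.80) {
  if (length(sequences) == 0L) stop("no sequences")
  stopifnot(threshold > 0, threshold < 1)
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  ord <- order(-nchar(sequences), ids)
  reps <- character(0)
  members <- list()
  assign_rep <- character(length(sequences))
  names(assign_rep) <- ids
  for (i in ord) {
    id <- ids[i]
    placed <- FALSE
    for (r in reps) {
      pid <- pairwise_identity(sequences[[i]], sequences[[which(ids == r)]])
      if (pid >= 100 * threshold) {
        members[[r]] <- c(members[[r]], id)
        assign_rep[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[id]] <- character(0)
      assign_rep[id] <- id
    }
  }
  clusters <- lapply(reps, function(r)
    list(representative_id = r, member_ids = members[[r]]))
  structure(list(
    clusters = clusters,
    identity_threshold = threshold,
    assignments = data.frame(sequence_id = ids,
                             representative = unname(assign_rep[ids]))
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d sequences at %.0f%% identity\n",
              length(x$clusters), nrow(x$assignments),
              100 * x$identity_threshold))
  invisible(x)
}

#' Tabulate subtype counts by taxon over cluster representatives
#'
#' Counts are computed over cluster representatives only, so redundancy does
#' not inflate taxon tallies. Records lacking taxonomy are binned under
#' `"unclassified"`, never dropped.
#'
#' @param records Survey table from [survey_proteomes].
#' @param clusters A `cluster_set` from [reduce_redundancy] over the same
#'   sequence-id universe.
#' @return A data.frame with `label`, `phylum`, `class`, `genus`,
#'   `n_representatives`, in deterministic (sorted) row order. The attribute
#'   `genus_counts` gives distinct-genus counts per label.
#' @export
tabulate_taxa <- function(records, clusters) {
  reps <- vapply(clusters$clusters, `[[`, "", "representative_id")
  missing <- setdiff(reps, records$sequence_id)
  if (length(missing) > 0L)
    stop(sprintf("representative '%s' lacks a survey record", missing[1]))
  r <- records[records$sequence_id %in% reps, , drop = FALSE]
  r <- r[!duplicated(paste(r$sequence_id, r$label)), , drop = FALSE]
  for (col in c("phylum", "class", "genus"))
    r[[col]] <- ifelse(is.na(r[[col]]) | r[[col]] == "",
                       "unclassified", r[[col]])
  key <- paste(r$label, r$phylum, r$class, r$genus, sep = "\t")
  tab <- table(key)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  out <- data.frame(
    label = vapply(parts, `[[`, "", 1L),
    phylum = vapply(parts, `[[`, "", 2L),
    class = vapply(parts, `[[`, "", 3L),
    genus = vapply(parts, `[[`, "", 4L),
    n_representatives = as.integer(tab))
  out <- out[order(out$label, out$phylum, out$class, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  gc <- tapply(r$genus, r$label, function(g) length(unique(g)))
  attr(out, "genus_counts") <- gc
  out
}
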