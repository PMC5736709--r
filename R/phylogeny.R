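#' Maximum-likelihood pairwise distance under an empirical model
#'
#' Maximises `sum_sites log(pi_a P_ab(t))` over `t >= 0` for one sequence
#' pair, with pairwise deletion of columns gapped (or ambiguous) in either
#' sequence and a uniform rate across sites (no gamma heterogeneity).
#' Distances are capped at `cap` substitutions/site when the likelihood is
#' still increasing there (saturated pairs).
#'
#' @param seq_a,seq_b Aligned amino-acid strings (equal length, gaps `-`).
#' @param model A [rate_model].
#' @param cap Saturation cap in substitutions/site (default 10).
#' @return Distance in substitutions/site.
#' @export
ml_distance <- function(seq_a, seq_b, model = rate_model(), cap = 10) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ia <- match(a, AA_ALPHABET)
  ib <- match(b, AA_ALPHABET)
  use <- !is.na(ia) & !is.na(ib)
  if (!any(use)) stop("no comparable sites")
  N <- table(factor(ia[use], levels = 1:20), factor(ib[use], levels = 1:20))
  N <- unclass(N)
  if (sum(N) == sum(diag(N))) return(0)
  lpi <- log(model$pi)
  ll <- function(t) {
    P <- prob_matrix(model, t)
    lp <- log(P)
    lp[N == 0] <- 0                       # avoid 0 * -Inf
    sum(N * (lp + lpi))
  }
  opt <- optimize(ll, c(1e-8, cap), maximum = TRUE, tol = 1e-9)
  # monotone likelihood up to the cap -> saturated
  if (ll(cap) >= opt$objective) return(cap)
  if (ll(1e-9) >= opt$objective) return(0)
  opt$maximum
}

#' All-pairs ML distance matrix
#'
#' @param alignment An [aa_alignment] (>= 3 sequences).
#' @param model A [rate_model].
#' @param cap Saturation cap (see [ml_distance]).
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id, in substitutions/site.
#' @export
ml_distance_matrix <- function(alignment, model = rate_model(), cap = 10) {
  aln <- aa_alignment(alignment)
  n <- length(aln$ids)
  if (n < 3L) stop("need at least 3 sequences")
  s <- apply(aln$mat, 1L, paste, collapse = "")
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(ml_distance(s[i], s[j], model, cap),
                  error = function(e) stop(sprintf(
                    "pair (%s, %s): %s", aln$ids[i], aln$ids[j],
                    conditionMessage(e)), call. = FALSE))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (rate-corrected criterion, two-point branch
#' length formulas). Negative estimated branch lengths are clamped to zero
#' and the total clamped deficit is reported via a message.
#'
#' @param D Symmetric non-negative distance matrix with labels (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("negative distances")
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative branch length(s); deficit %.6g",
                    sum(neg), -sum(tr$edge.length[neg])))
    tr$edge.length[neg] <- 0
  }
  tr
}

# canonical keys for the non-trivial bipartitions of an unrooted tree:
# each split is represented by the side NOT containing the reference taxon
# (first label sorted), as a sorted comma-joined string
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= length(labs) - 2L)
      keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

# split compatibility for taxon-1-excluded sides: disjoint or nested
.splits_compatible <- function(a, b) {
  ia <- intersect(a, b)
  length(ia) == 0L || length(ia) == length(a) || length(ia) == length(b)
}

# build a rooted-display newick from a compatible split set with supports
.tree_from_splits <- function(splits, support, taxa) {
  if (length(splits) > 0L) {
    ord <- order(lengths(splits))
    splits <- splits[ord]
    support <- support[ord]
  }
  build <- function(members, idx) {
    kids <- idx[order(-lengths(splits[idx]))]
    taken <- character(0)
    parts <- character(0)
    for (k in kids) {
      s <- splits[[k]]
      if (all(s %in% members) && !any(s %in% taken)) {
        sub_idx <- setdiff(idx, k)
        sub_idx <- sub_idx[vapply(sub_idx, function(j)
          all(splits[[j]] %in% s), logical(1))]
        parts <- c(parts, paste0(build(s, sub_idx),
                                 sprintf("%g", support[k])))
        taken <- c(taken, s)
      }
    }
    singles <- setdiff(members, taken)
    paste0("(", paste(c(sort(singles), parts), collapse = ","), ")")
  }
  nwk <- paste0(build(taxa, seq_along(splits)), ";")
  ape::read.tree(text = nwk)
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, recomputes the ML distance
#' matrix and NJ tree for each replicate, and reports, for every internal
#' bipartition of the full-data NJ tree, the percentage of replicates that
#' contain it. A majority-rule consensus tree is returned as well; with
#' `extended = TRUE` (default) remaining compatible bipartitions are added
#' greedily in order of decreasing frequency.
#'
#' Replicates in which some pair has no comparable sites are dropped (and
#' counted in `n_dropped`) with a warning.
#'
#' @param alignment An [aa_alignment] (>= 4 sequences for internal edges).
#' @param model A [rate_model].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the run is fully reproducible given
#'   `(alignment, model, n_reps, seed)`.
#' @param cap Distance saturation cap.
#' @param extended Use extended majority rule for the consensus.
#' @return List of class `bootstrap_nj`: `tree` (full-data NJ `phylo` with
#'   supports as `node.label`, in %), `supports` (data.frame `split`,
#'   `support_pct`), `consensus` (`phylo`), `n_reps_used`, `n_dropped`.
#' @export
bootstrap_tree <- function(alignment, model = rate_model(), n_reps = 100,
                           seed = NULL, cap = 10, extended = TRUE) {
  stopifnot(n_reps >= 1)
  aln <- aa_alignment(alignment)
  D <- ml_distance_matrix(aln, model, cap)
  full <- neighbor_joining(D)
  C <- aln$n_columns

  rep_splits <- list()
  n_dropped <- 0L
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(C, C, replace = TRUE)
      rep_aln <- aa_alignment(aln$mat[, cols, drop = FALSE], ids = aln$ids)
      tr <- tryCatch(
        suppressMessages(neighbor_joining(
          ml_distance_matrix(rep_aln, model, cap))),
        error = function(e) NULL)
      if (is.null(tr)) {
        n_dropped <- n_dropped + 1L
        next
      }
      rep_splits[[length(rep_splits) + 1L]] <- tree_splits(tr)
    }
  })
  if (n_dropped > 0L)
    warning(sprintf("%d bootstrap replicate(s) dropped (incomparable pair)",
                    n_dropped))
  n_used <- length(rep_splits)
  if (n_used == 0L) stop("all bootstrap replicates failed")

  all_keys <- unlist(rep_splits)
  freq <- table(all_keys) / n_used * 100

  full_keys <- tree_splits(full)
  supp <- vapply(full_keys, function(k)
    if (k %in% names(freq)) unname(freq[k]) else 0, numeric(1))
  supports <- data.frame(split = full_keys, support_pct = unname(supp))

  # annotate the full tree's internal nodes
  tips <- sort(full$tip.label)
  ref <- tips[1L]
  pp <- ape::prop.part(full)
  labs <- attr(pp, "labels")
  node_lab <- character(full$Nnode)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = ",")
    j <- match(key, supports$split)
    node_lab[i] <- if (!is.na(j))
      sprintf("%g", supports$support_pct[j]) else ""
  }
  full$node.label <- node_lab

  # consensus: majority rule, optionally extended with compatible splits
  ord <- order(-freq, names(freq))
  keys <- names(freq)[ord]
  fr <- as.numeric(freq)[ord]
  sel <- list(); sel_fr <- numeric(0)
  for (i in seq_along(keys)) {
    s <- strsplit(keys[i], ",", fixed = TRUE)[[1]]
    compat <- all(vapply(sel, .splits_compatible, logical(1), b = s))
    if (!compat) next
    if (fr[i] > 50 || extended) {
      sel[[length(sel) + 1L]] <- s
      sel_fr <- c(sel_fr, fr[i])
    }
  }
  cons <- .tree_from_splits(sel, sel_fr, tips)

  structure(list(tree = full, supports = supports, consensus = cons,
                 n_reps_used = n_used, n_dropped = n_dropped),
            class = "bootstrap_nj")
}

#' @export
print.bootstrap_nj <- function(x, ...) {
  cat(sprintf("bootstrap_nj: %d taxa, %d replicates used (%d dropped)\n",
              length(x$tree$tip.label), x$n_reps_used, x$n_dropped))
  if (nrow(x$supports) > 0L) {
    cat("internal-edge supports (%):\n")
    print(x$supports, row.names = FALSE)
  }
  invisible(x)
}

#' Support of the split separating a given taxon set
#'
#' Convenience accessor: looks up the bootstrap support (in %) of the
#' bipartition separating `taxa` from the rest, or `NA` if that split is
#' not an internal edge of the full-data tree.
#'
#' @param bs A `bootstrap_nj` object.
#' @param taxa Character vector of tip labels on one side of the split.
#' @export
split_support <- function(bs, taxa) {
  tips <- sort(bs$tree$tip.label)
  side <- sort(taxa)
  if (tips[1L] %in% side) side <- sort(setdiff(tips, side))
  key <- paste(side, collapse = ",")
  j <- match(key, bs$supports$split)
  if (is.na(j)) NA_real_ else bs$supports$support_pct[j]
}
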