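#' Build a profile hidden Markov model from a seed alignment
#'
#' Estimates a local-alignment profile HMM in the usual match/insert/delete
#' architecture. Columns whose gap fraction is below `match_fraction` become
#' match states; the rest are insert columns. Match (and insert) emission
#' probabilities are weighted residue counts plus `pseudocount_weight` times
#' the background distribution, renormalised. Transition probabilities are
#' estimated from the observed per-sequence state paths with add-one
#' (Laplace) pseudocounts. Local entry is uniform over ordered pairs of
#' match states, so bit scores are comparable across models of different
#' length.
#'
#' @param alignment An [aa_alignment] (or anything coercible to one).
#' @param name Model name used in hit tables.
#' @param match_fraction Columns with gap fraction strictly below this become
#'   match states; default 0.5.
#' @param pseudocount_weight Total pseudocount mass added to each emission
#'   distribution, spread proportionally to the background; default 1.
#' @param background Length-20 background residue distribution in the order
#'   `ARNDCQEGHILKMFPSTWYV`; default uniform.
#' @return An object of class `profile_hmm`.
#' @examples
#' m <- build_profile(aa_alignment(c(a = "ACD", b = "ACD")),
#'                    pseudocount_weight = 0)
#' m$n_match_states
#' @export
build_profile <- function(alignment, name = "model", match_fraction = 0.5,
                          pseudocount_weight = 1, background = NULL) {
  aln <- aa_alignment(alignment)
  if (length(aln$ids) == 0L) stop("no sequences")
  stopifnot(match_fraction > 0, match_fraction <= 1, pseudocount_weight >= 0)
  bg <- background %||% rep(1 / 20, 20)
  stopifnot(length(bg) == 20L, all(bg > 0))
  bg <- bg / sum(bg)
  names(bg) <- AA_ALPHABET

  mask <- match_mask(aln, match_fraction)
  K <- sum(mask)
  if (K == 0L) stop("no match columns")
  if (any(aln$mat %in% AA_AMBIGUOUS))
    stop("seed alignment contains ambiguity codes; disambiguate first")

  n <- length(aln$ids)
  C <- aln$n_columns
  node_of_col <- cumsum(mask)           # match-node index reached at column c

  # --- emissions -----------------------------------------------------------
  count_col <- function(col) {
    r <- aln$mat[, col]
    r <- r[r != "-"]
    tab <- table(factor(r, levels = AA_ALPHABET))
    as.numeric(tab)
  }
  match_cols <- which(mask)
  me <- t(vapply(match_cols, count_col, numeric(20)))
  me <- me + pseudocount_weight * rep(bg, each = K)
  if (any(rowSums(me) == 0))
    stop("empty match column emission; increase pseudocount_weight")
  me <- me / rowSums(me)
  colnames(me) <- AA_ALPHABET

  ie <- matrix(bg, nrow = max(K - 1L, 1L), ncol = 20, byrow = TRUE)
  colnames(ie) <- AA_ALPHABET
  if (K > 1L) {
    ins_cols <- which(!mask)
    # pooled insert counts per node
    icnt <- matrix(0, nrow = K - 1L, ncol = 20)
    for (c0 in ins_cols) {
      k <- node_of_col[c0]
      if (k >= 1L && k <= K - 1L) icnt[k, ] <- icnt[k, ] + count_col(c0)
    }
    icnt <- icnt + pseudocount_weight * rep(bg, each = K - 1L)
    tot <- rowSums(icnt)
    use <- tot > 0
    ie[use, ] <- icnt[use, , drop = FALSE] / tot[use]
    colnames(ie) <- AA_ALPHABET
  }

  # --- transitions from observed state paths -------------------------------
  # states along a sequence: M_k / D_k at match columns, I_k at insert
  # columns carrying a residue (k = last match node passed; flanking inserts
  # before node 1 are not counted - the model is local)
  cMM <- cMI <- cMD <- cIM <- cII <- cDM <- cDD <- rep(0, max(K - 1L, 0L))
  if (K > 1L) {
    for (s in seq_len(n)) {
      prev_state <- NULL  # c(type, node) with type in "M","I","D"
      for (c0 in seq_len(C)) {
        ch <- aln$mat[s, c0]
        if (mask[c0]) {
          k <- node_of_col[c0]
          st <- c(if (ch == "-") "D" else "M", k)
        } else {
          if (ch == "-") next
          k <- node_of_col[c0]
          if (k < 1L || k > K - 1L) next
          st <- c("I", k)
        }
        if (!is.null(prev_state)) {
          pt <- prev_state[1]; pk <- as.integer(prev_state[2])
          tt <- st[1]; tk <- as.integer(st[2])
          if (pt == "M" && tt == "M" && tk == pk + 1L) cMM[pk] <- cMM[pk] + 1
          if (pt == "M" && tt == "I" && tk == pk)      cMI[pk] <- cMI[pk] + 1
          if (pt == "M" && tt == "D" && tk == pk + 1L) cMD[pk] <- cMD[pk] + 1
          if (pt == "I" && tt == "M" && tk == pk + 1L) cIM[pk] <- cIM[pk] + 1
          if (pt == "I" && tt == "I" && tk == pk)      cII[pk] <- cII[pk] + 1
          if (pt == "D" && tt == "M" && tk == pk + 1L) cDM[pk] <- cDM[pk] + 1
          if (pt == "D" && tt == "D" && tk == pk + 1L) cDD[pk] <- cDD[pk] + 1
        }
        prev_state <- st
      }
    }
  }
  norm2 <- function(a, b) {
    s <- a + b
    cbind(a / s, b / s)
  }
  if (K > 1L) {
    m3 <- cbind(cMM, cMI, cMD) + 1   # Laplace
    m3 <- m3 / rowSums(m3)
    i2 <- norm2(cIM + 1, cII + 1)
    d2 <- norm2(cDM + 1, cDD + 1)
    tr <- list(MM = m3[, 1], MI = m3[, 2], MD = m3[, 3],
               IM = i2[, 1], II = i2[, 2], DM = d2[, 1], DD = d2[, 2])
  } else {
    tr <- list(MM = numeric(0), MI = numeric(0), MD = numeric(0),
               IM = numeric(0), II = numeric(0),
               DM = numeric(0), DD = numeric(0))
  }

  hmm <- structure(list(
    name = name,
    n_match_states = K,
    match_emissions = me,
    insert_emissions = ie,
    transitions = tr,
    background = bg,
    match_fraction = match_fraction,
    pseudocount_weight = pseudocount_weight
  ), class = "profile_hmm")
  validate_profile_hmm(hmm, strict = pseudocount_weight > 0)
  hmm
}

validate_profile_hmm <- function(hmm, strict = TRUE, tol = 1e-9) {
  stopifnot(hmm$n_match_states >= 1L)
  if (any(abs(rowSums(hmm$match_emissions) - 1) > tol))
    stop("match emission distributions do not sum to 1")
  if (any(abs(rowSums(hmm$insert_emissions) - 1) > tol))
    stop("insert emission distributions do not sum to 1")
  K <- hmm$n_match_states
  tr <- hmm$transitions
  if (K > 1L) {
    if (any(abs(tr$MM + tr$MI + tr$MD - 1) > tol) ||
        any(abs(tr$IM + tr$II - 1) > tol) ||
        any(abs(tr$DM + tr$DD - 1) > tol))
      stop("transition distributions do not sum to 1")
    if (strict && (any(c(tr$MM, tr$MI, tr$MD, tr$IM, tr$II, tr$DM, tr$DD) <= 0)))
      stop("zero transition probability after pseudocounting")
  }
  if (strict && any(hmm$match_emissions <= 0))
    stop("zero emission probability after pseudocounting")
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': %d match states\n", x$name, x$n_match_states))
  invisible(x)
}

# residue indices; ambiguity codes -> NA (scored neutrally)
.residue_index <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  if (length(ch) == 0L) stop("empty sequence")
  idx <- match(ch, AA_ALPHABET)
  amb <- is.na(idx) & ch %in% AA_AMBIGUOUS
  bad <- is.na(idx) & !amb
  if (any(bad)) {
    p <- which(bad)[1L]
    stop(sprintf("unknown residue character '%s' at position %d", ch[p], p))
  }
  idx  # NA marks ambiguity
}

# log2-odds emission matrices (K x L), masked positions -> -Inf
.logodds_tables <- function(hmm, idx, mask = NULL) {
  K <- hmm$n_match_states
  L <- length(idx)
  lom <- log2(hmm$match_emissions / rep(hmm$background, each = K))
  loi <- log2(hmm$insert_emissions / rep(hmm$background,
                                         each = nrow(hmm$insert_emissions)))
  lm <- matrix(0, K, L)
  li <- matrix(0, K, L)
  known <- !is.na(idx)
  lm[, known] <- lom[, idx[known], drop = FALSE]
  if (K > 1L) li[seq_len(K - 1L), known] <- loi[, idx[known], drop = FALSE]
  if (!is.null(mask) && any(mask)) {
    lm[, mask] <- -Inf
    li[, mask] <- -Inf
  }
  list(lm = lm, li = li)
}

.log_tr <- function(hmm) lapply(hmm$transitions, log2)

.lentry <- function(K) log2(2 / (K * (K + 1)))

#' Forward bit score of a sequence under a profile HMM
#'
#' Sums the probability of every local alignment (all entry/exit match-state
#' pairs, all start positions, all match/insert/delete paths) and returns the
#' log2 odds against the background null model. Flanking residues are scored
#' by the null in both numerator and denominator and cancel. Ambiguity codes
#' (B, Z, X, J, U, O) contribute zero log-odds.
#'
#' @param hmm A `profile_hmm`.
#' @param sequence Amino-acid string.
#' @param mask Optional logical vector (length `nchar(sequence)`); masked
#'   positions cannot be emitted by the model (used by [scan_sequence]).
#' @return Bit score (log2 odds), a finite scalar unless everything is masked.
#' @export
score_forward <- function(hmm, sequence, mask = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"))
  idx <- .residue_index(sequence)
  tb <- .logodds_tables(hmm, idx, mask)
  tr <- .log_tr(hmm)
  .fwd_logodds(tb$lm, tb$li, tr$MM, tr$MI, tr$MD, tr$IM, tr$II,
               tr$DM, tr$DD, .lentry(hmm$n_match_states))
}

#' Best local alignment (Viterbi) of a sequence to a profile HMM
#'
#' @inheritParams score_forward
#' @return A list with `bit_score`, `path` (data.frame with columns `state`
#'   in M/I/D, `node`, `pos`; `pos` is `NA` for delete states) and `envelope`,
#'   the 0-based half-open residue interval consumed by the best alignment.
#' @export
viterbi_align <- function(hmm, sequence, mask = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"))
  idx <- .residue_index(sequence)
  tb <- .logodds_tables(hmm, idx, mask)
  tr <- .log_tr(hmm)
  v <- .vit_logodds(tb$lm, tb$li, tr$MM, tr$MI, tr$MD, tr$IM, tr$II,
                    tr$DM, tr$DD, .lentry(hmm$n_match_states))
  if (!is.finite(v$score) || length(v$states) == 0L) {
    return(list(bit_score = -Inf,
                path = data.frame(state = character(0), node = integer(0),
                                  pos = integer(0)),
                envelope = c(0L, 0L)))
  }
  st <- c("M", "I", "D")[v$states]
  pos <- ifelse(v$pos == 0L, NA_integer_, v$pos)
  emitted <- pos[!is.na(pos)]
  list(bit_score = v$score,
       path = data.frame(state = st, node = v$nodes, pos = pos),
       envelope = c(min(emitted) - 1L, max(emitted)))
}

#' Recompute the bit score of an explicit state path
#'
#' Self-consistency helper: the probability of the path returned by
#' [viterbi_align] reproduces its bit score.
#'
#' @param hmm A `profile_hmm`.
#' @param sequence Amino-acid string.
#' @param path Data frame as returned in `viterbi_align()$path`.
#' @export
path_bit_score <- function(hmm, sequence, path) {
  idx <- .residue_index(sequence)
  tb <- .logodds_tables(hmm, idx)
  tr <- .log_tr(hmm)
  s <- .lentry(hmm$n_match_states)
  for (r in seq_len(nrow(path))) {
    st <- path$state[r]; k <- path$node[r]; p <- path$pos[r]
    if (st == "M") s <- s + tb$lm[k, p]
    if (st == "I") s <- s + tb$li[k, p]
    if (r < nrow(path)) {
      nx <- path$state[r + 1L]
      key <- paste0(st, nx)
      s <- s + tr[[key]][k]
    }
  }
  s
}

#' Scan a protein with one or more profile HMMs
#'
#' Finds non-overlapping domain envelopes by iterated masked Viterbi search
#' per model, then resolves envelopes that overlap across models (more than
#' `overlap_frac` of the shorter envelope) in favour of the higher-scoring
#' hit. Every reported hit carries forward bit scores of **all** supplied
#' models over its envelope, enabling cross-model classification.
#'
#' @param models A `profile_hmm` or list of them; list names default to each
#'   model's own `name`.
#' @param sequence Amino-acid string.
#' @param report_threshold_bits Minimum Viterbi bit score for a hit
#'   (default 10).
#' @param sequence_id Identifier copied into the hit table.
#' @param max_hits_per_model Safety bound on iterated search (default 10).
#' @param overlap_frac Overlap fraction of the shorter envelope above which
#'   two hits conflict (default 0.5).
#' @return A data.frame with columns `sequence_id`, `start`, `end` (0-based
#'   half-open), `model`, `bits` and one `bits_<model>` column per supplied
#'   model, sorted by `start`. Zero rows if nothing scores above threshold.
#' @export
scan_sequence <- function(models, sequence, report_threshold_bits = 10,
                          sequence_id = "seq", max_hits_per_model = 10L,
                          overlap_frac = 0.5) {
  if (inherits(models, "profile_hmm")) models <- list(models)
  stopifnot(length(models) >= 1L)
  nm <- names(models) %||% vapply(models, `[[`, "", "name")
  if (is.null(names(models))) names(models) <- nm
  nm[nm == ""] <- vapply(models[nm == ""], `[[`, "", "name")
  names(models) <- nm
  L <- nchar(sequence)

  hits <- list()
  for (mn in nm) {
    m <- models[[mn]]
    mask <- rep(FALSE, L)
    for (h in seq_len(max_hits_per_model)) {
      v <- viterbi_align(m, sequence, mask = mask)
      if (!is.finite(v$bit_score) || v$bit_score < report_threshold_bits) break
      hits[[length(hits) + 1L]] <- data.frame(
        model = mn, start = v$envelope[1], end = v$envelope[2],
        bits = v$bit_score)
      mask[(v$envelope[1] + 1L):v$envelope[2]] <- TRUE
    }
  }
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), model = character(0),
                      bits = numeric(0))
  for (mn in nm) empty[[paste0("bits_", mn)]] <- numeric(0)
  if (length(hits) == 0L) return(empty)
  hits <- do.call(rbind, hits)

  # resolve cross-model overlaps: keep the higher-scoring envelope
  hits <- hits[order(-hits$bits), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j <= i || !keep[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov > overlap_frac * shorter) keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]

  # per-model forward scores over each kept envelope
  out <- data.frame(sequence_id = sequence_id, start = hits$start,
                    end = hits$end, model = hits$model, bits = NA_real_)
  for (mn in nm) {
    col <- paste0("bits_", mn)
    out[[col]] <- vapply(seq_len(nrow(hits)), function(i) {
      sub <- substr(sequence, hits$start[i] + 1L, hits$end[i])
      score_forward(models[[mn]], sub)
    }, numeric(1))
  }
  out$bits <- vapply(seq_len(nrow(out)), function(i)
    out[[paste0("bits_", out$model[i])]][i], numeric(1))
  rownames(out) <- NULL
  out
}

#' Classify CBM40 hits as canonical, Vibrio-type or reject
#'
#' Applies the cross-model score comparison: a hit is labelled with the
#' higher-scoring CBM40 subtype when that score exceeds every decoy model's
#' score by at least `margin_bits` and is at or above the reporting
#' threshold; otherwise it is rejected as a related, non-CBM40 domain.
#' An exact tie between the canonical and Vibrio scores is labelled
#' canonical and flagged.
#'
#' @param hits Hit table from [scan_sequence] (needs the `bits_<model>`
#'   columns for all models named here).
#' @param canonical,vibrio Model names of the two CBM40 subtypes.
#' @param decoys Character vector of decoy model names (may be empty).
#' @param margin_bits Required margin of the best CBM40 score over the best
#'   decoy score (default 0).
#' @param report_threshold_bits Minimum best-CBM40 score (default 10).
#' @return `hits` with added columns `label` (canonical/vibrio/reject),
#'   `margin_bits` (best CBM40 minus best competing score) and `tie`.
#' @export
classify_hits <- function(hits, canonical = "canonical", vibrio = "vibrio",
                          decoys = character(0), margin_bits = 0,
                          report_threshold_bits = 10) {
  need <- paste0("bits_", c(canonical, vibrio, decoys))
  missing <- setdiff(need, names(hits))
  if (length(missing) > 0L)
    stop(sprintf("missing score entry for model '%s'",
                 sub("^bits_", "", missing[1])))
  n <- nrow(hits)
  label <- character(n); margin <- numeric(n); tie <- logical(n)
  for (i in seq_len(n)) {
    sc_can <- hits[[paste0("bits_", canonical)]][i]
    sc_vib <- hits[[paste0("bits_", vibrio)]][i]
    sc_dec <- if (length(decoys) > 0L)
      max(vapply(decoys, function(d) hits[[paste0("bits_", d)]][i],
                 numeric(1))) else -Inf
    best_cbm <- max(sc_can, sc_vib)
    other_cbm <- min(sc_can, sc_vib)
    competing <- max(other_cbm, sc_dec)
    margin[i] <- best_cbm - competing
    tie[i] <- sc_can == sc_vib
    if (best_cbm < report_threshold_bits ||
        (best_cbm - sc_dec) < margin_bits) {
      label[i] <- "reject"
    } else if (sc_can >= sc_vib) {
      label[i] <- "canonical"
    } else {
      label[i] <- "vibrio"
    }
  }
  hits$label <- label
  hits$margin_bits <- margin
  hits$tie <- tie
  hits
}
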