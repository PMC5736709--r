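# Shared fixtures (memoised: generated once per test run) and independent
# oracles used across test files.

.fx <- new.env()

fx_model <- function() {
  if (is.null(.fx$model)) .fx$model <- rate_model()
  .fx$model
}

fx_families <- function() {
  if (is.null(.fx$fam)) .fx$fam <- sim_families(seed = 42)
  .fx$fam
}

fx_gh33 <- function() {
  if (is.null(.fx$gh33))
    .fx$gh33 <- sialobind:::sim_single_family(6, 150, 0.5, "gh33",
                                              fx_model(), seed = 142)
  .fx$gh33
}

fx_decoy <- function() {
  if (is.null(.fx$decoy))
    .fx$decoy <- sialobind:::sim_single_family(6, 110, 0.5, "decoy",
                                               fx_model(), seed = 242)
  .fx$decoy
}

fx_hmms <- function() {
  if (is.null(.fx$hmms)) {
    fam <- fx_families()
    .fx$hmms <- list(
      canonical = build_profile(fam$alignments$canonical, name = "canonical"),
      vibrio = build_profile(fam$alignments$vibrio, name = "vibrio"),
      decoy = build_profile(fx_decoy(), name = "decoy"),
      gh33 = build_profile(fx_gh33(), name = "gh33"),
      combined = build_profile(fam$pooled, name = "combined"))
  }
  .fx$hmms
}

AA <- sialobind:::AA_ALPHABET

# random residue string under a uniform background
random_protein <- function(n) paste(sample(AA, n, replace = TRUE),
                                    collapse = "")

# small random seed alignment -> profile HMM, for property sweeps
random_small_hmm <- function(seed, n_seq = 3, n_col = 4,
                             pseudocount_weight = 1) {
  set.seed(seed)
  m <- matrix(sample(AA[1:6], n_seq * n_col, replace = TRUE), n_seq, n_col)
  # sprinkle a few gaps but keep at least one match column
  g <- matrix(runif(length(m)) < 0.15, n_seq, n_col)
  g[, 1] <- FALSE
  m[g] <- "-"
  build_profile(aa_alignment(m), name = paste0("rnd", seed),
                pseudocount_weight = pseudocount_weight)
}

# ---- independent oracle: exhaustive enumeration of all local paths -------
# Path space identical to the scoring model's definition: entry at any
# (match state, position) with weight 2/(K(K+1)), walk via M/I/D, exit free
# after any match state. Probabilities summed directly (tiny models only).
enum_forward_prob <- function(hmm, sequence) {
  idx <- match(strsplit(sequence, "")[[1]], AA)
  stopifnot(!anyNA(idx))
  K <- hmm$n_match_states
  L <- length(idx)
  odds_m <- hmm$match_emissions / rep(hmm$background, each = K)
  odds_i <- hmm$insert_emissions /
    rep(hmm$background, each = nrow(hmm$insert_emissions))
  tr <- hmm$transitions
  total <- 0
  at_M <- function(k, i, w) {
    w <- w * odds_m[k, idx[i]]
    total <<- total + w                 # exit here
    if (k < K) {
      if (i < L) at_M(k + 1, i + 1, w * tr$MM[k])
      if (i < L) at_I(k, i + 1, w * tr$MI[k])
      at_D(k + 1, i, w * tr$MD[k])
    }
  }
  at_I <- function(k, i, w) {
    w <- w * odds_i[k, idx[i]]
    if (i < L) {
      at_M(k + 1, i + 1, w * tr$IM[k])
      at_I(k, i + 1, w * tr$II[k])
    }
  }
  at_D <- function(k, i, w) {
    if (k < K) {
      if (i < L) at_M(k + 1, i + 1, w * tr$DM[k])
      at_D(k + 1, i, w * tr$DD[k])
    }
  }
  w0 <- 2 / (K * (K + 1))
  for (k1 in seq_len(K)) for (s in seq_len(L)) at_M(k1, s, w0)
  unname(total)
}

enum_forward_bits <- function(hmm, sequence) log2(enum_forward_prob(hmm, sequence))

# ---- independent oracle: grid search for the ML pairwise distance --------
grid_ml_distance <- function(seq_a, seq_b, model, cap = 10) {
  a <- match(strsplit(seq_a, "")[[1]], AA)
  b <- match(strsplit(seq_b, "")[[1]], AA)
  use <- !is.na(a) & !is.na(b)
  N <- table(factor(a[use], levels = 1:20), factor(b[use], levels = 1:20))
  N <- unclass(N)
  ll <- function(t) {
    lp <- log(prob_matrix(model, t))
    lp[N == 0] <- 0
    sum(N * lp)
  }
  coarse <- seq(1e-4, cap, by = 0.01)
  v <- vapply(coarse, ll, numeric(1))
  t0 <- coarse[which.max(v)]
  fine <- seq(max(t0 - 0.02, 1e-6), min(t0 + 0.02, cap), by = 1e-5)
  vf <- vapply(fine, ll, numeric(1))
  tf <- fine[which.max(vf)]
  if (ll(cap) >= max(vf)) return(cap)
  if (ll(1e-9) >= max(vf)) return(0)
  tf
}

# log-likelihood curvature -> observed-information standard error of t-hat
ml_distance_se <- function(seq_a, seq_b, model, t_hat, h = 1e-3) {
  a <- match(strsplit(seq_a, "")[[1]], AA)
  b <- match(strsplit(seq_b, "")[[1]], AA)
  use <- !is.na(a) & !is.na(b)
  N <- unclass(table(factor(a[use], levels = 1:20),
                     factor(b[use], levels = 1:20)))
  ll <- function(t) {
    lp <- log(prob_matrix(model, t))
    lp[N == 0] <- 0
    sum(N * lp)
  }
  d2 <- (ll(t_hat + h) - 2 * ll(t_hat) + ll(t_hat - h)) / h^2
  1 / sqrt(-d2)
}

# assemble a protein with planted domain segments; returns sequence + truth
plant_protein <- function(segments, linker_lengths) {
  stopifnot(length(linker_lengths) == length(segments) + 1L)
  seq <- random_protein(linker_lengths[1])
  truth <- list()
  for (i in seq_along(segments)) {
    start <- nchar(seq)
    seq <- paste0(seq, segments[[i]]$seq)
    truth[[i]] <- data.frame(domain = segments[[i]]$dom, start = start,
                             end = nchar(seq))
    seq <- paste0(seq, random_protein(linker_lengths[i + 1]))
  }
  list(sequence = seq, truth = do.call(rbind, truth))
}
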