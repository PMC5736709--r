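#' Serialize a profile HMM to a plain-text file
#'
#' A documented key-value format with per-state probability tables written
#' at full double precision (`%.17g`), so that
#' `read_profile_hmm(write_profile_hmm(m, f))` round-trips bit-exactly.
#'
#' Layout: header lines `name`, `n_match_states`, `match_fraction`,
#' `pseudocount_weight`, `alphabet`, `background`; then one `match k ...`
#' and (for k < K) one `insert k ...` line of 20 probabilities per state;
#' then one `trans k MM MI MD IM II DM DD` line per internal node.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_hmm <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  g <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(...), con)
  w("sialobind_profile_hmm", "1")
  w("name", hmm$name)
  w("n_match_states", hmm$n_match_states)
  w("match_fraction", g(hmm$match_fraction))
  w("pseudocount_weight", g(hmm$pseudocount_weight))
  w("alphabet", paste(AA_ALPHABET, collapse = ""))
  w("background", paste(g(hmm$background), collapse = " "))
  K <- hmm$n_match_states
  for (k in seq_len(K))
    w("match", k, paste(g(hmm$match_emissions[k, ]), collapse = " "))
  if (K > 1L)
    for (k in seq_len(K - 1L))
      w("insert", k, paste(g(hmm$insert_emissions[k, ]), collapse = " "))
  tr <- hmm$transitions
  if (K > 1L)
    for (k in seq_len(K - 1L))
      w("trans", k, paste(g(c(tr$MM[k], tr$MI[k], tr$MD[k], tr$IM[k],
                              tr$II[k], tr$DM[k], tr$DD[k])), collapse = " "))
  invisible(path)
}

#' Read a profile HMM written by [write_profile_hmm]
#'
#' @param path Model file.
#' @return A `profile_hmm`.
#' @export
read_profile_hmm <- function(path) {
  ln <- readLines(path)
  tok <- strsplit(ln, " ")
  key <- vapply(tok, `[[`, "", 1L)
  if (key[1] != "sialobind_profile_hmm")
    stop(sprintf("'%s' is not a sialobind profile HMM file", path))
  get1 <- function(k) {
    i <- which(key == k)[1L]
    if (is.na(i)) stop(sprintf("missing field '%s' in %s", k, path))
    tok[[i]][-1L]
  }
  K <- as.integer(get1("n_match_states"))
  me <- matrix(NA_real_, K, 20, dimnames = list(NULL, AA_ALPHABET))
  ie <- matrix(NA_real_, max(K - 1L, 1L), 20,
               dimnames = list(NULL, AA_ALPHABET))
  tr <- list(MM = numeric(0), MI = numeric(0), MD = numeric(0),
             IM = numeric(0), II = numeric(0),
             DM = numeric(0), DD = numeric(0))
  if (K > 1L) tr <- lapply(tr, function(x) rep(NA_real_, K - 1L))
  for (i in seq_along(tok)) {
    t <- tok[[i]]
    if (t[1] == "match") me[as.integer(t[2]), ] <- as.numeric(t[-(1:2)])
    if (t[1] == "insert") ie[as.integer(t[2]), ] <- as.numeric(t[-(1:2)])
    if (t[1] == "trans") {
      k <- as.integer(t[2]); v <- as.numeric(t[-(1:2)])
      tr$MM[k] <- v[1]; tr$MI[k] <- v[2]; tr$MD[k] <- v[3]
      tr$IM[k] <- v[4]; tr$II[k] <- v[5]; tr$DM[k] <- v[6]; tr$DD[k] <- v[7]
    }
  }
  if (K == 1L) ie[1, ] <- as.numeric(get1("background"))
  hmm <- structure(list(
    name = paste(get1("name"), collapse = " "),
    n_match_states = K,
    match_emissions = me,
    insert_emissions = ie,
    transitions = tr,
    background = setNames(as.numeric(get1("background")), AA_ALPHABET),
    match_fraction = as.numeric(get1("match_fraction")),
    pseudocount_weight = as.numeric(get1("pseudocount_weight"))
  ), class = "profile_hmm")
  validate_profile_hmm(hmm, strict = FALSE)
  hmm
}
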