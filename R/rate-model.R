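#' Empirical amino-acid substitution rate model
#'
#' Builds a general time-reversible amino-acid rate matrix from an empirical
#' exchangeability matrix and stationary frequencies. The generator `Q` is
#' scaled so that the expected number of substitutions per site per unit
#' time is 1, i.e. distances are in substitutions/site. The model slot is
#' pluggable: any matrix in PAML `.dat` format can be supplied, or any of
#' the empirical models bundled with phangorn can be named (default
#' `"Blosum62"`, the blocks-derived matrix).
#'
#' @param name Model name known to phangorn (e.g. `"Blosum62"`, `"WAG"`,
#'   `"LG"`, `"JTT"`); ignored when `paml_file` or `exchange` is given.
#' @param paml_file Path to a PAML-format data file: 19 lines of the lower
#'   triangle of the symmetric exchangeability matrix followed by a line of
#'   20 stationary frequencies (residue order `ARNDCQEGHILKMFPSTWYV`).
#' @param exchange Optional 20 x 20 symmetric non-negative exchangeability
#'   matrix (diagonal ignored).
#' @param freq Optional length-20 stationary distribution.
#' @return An object of class `rate_model` with elements `name`, `exchange`,
#'   `pi`, `Q` (scaled generator) and a cached eigendecomposition.
#' @examples
#' m <- rate_model()
#' range(rowSums(prob_matrix(m, 0.5)))  # rows of P(t) sum to 1
#' @export
rate_model <- function(name = "Blosum62", paml_file = NULL,
                       exchange = NULL, freq = NULL) {
  if (!is.null(paml_file)) {
    p <- read_paml_dat(paml_file)
    exchange <- p$exchange
    freq <- p$freq
    name <- p$name %||% basename(paml_file)
  } else if (is.null(exchange)) {
    em <- .phangorn_aamodel(name)
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- em$Q
    exchange <- S + t(S)
    freq <- unname(em$bf)
  }
  stopifnot(is.matrix(exchange), dim(exchange) == c(20, 20),
            length(freq) == 20L, all(freq > 0))
  if (max(abs(exchange - t(exchange))) > 1e-8)
    stop("exchangeability matrix must be symmetric")
  diag(exchange) <- 0
  if (any(exchange < 0)) stop("negative exchangeability")
  pi <- freq / sum(freq)
  Q <- exchange * rep(pi, each = 20)       # Q_ab = s_ab * pi_b
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(AA_ALPHABET, AA_ALPHABET)
  # reversible Q is similar to a symmetric matrix: B = D^1/2 Q D^-1/2
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(name = name, exchange = exchange,
                 pi = setNames(pi, AA_ALPHABET), Q = Q,
                 eig = list(values = e$values,
                            left = e$vectors * (1 / sp),
                            right = t(e$vectors * sp))),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("rate_model '%s' (20-state GTR, 1 substitution/site/unit time)\n",
              x$name))
  invisible(x)
}

# named empirical models from the installed phangorn (internal accessor;
# stable in the pinned version)
.phangorn_aamodel <- function(name) {
  obj <- tryCatch(get(paste0(".", name), environment(phangorn::pml)),
                  error = function(e) NULL)
  if (is.null(obj) || !all(c("Q", "bf") %in% names(obj)))
    stop(sprintf("amino-acid model '%s' not available from phangorn", name))
  obj
}

#' Read a PAML-format amino-acid model data file
#'
#' @param path `.dat` file: 19 rows of the lower triangle of the
#'   exchangeability matrix, then 20 stationary frequencies.
#' @return List with `exchange` (20 x 20 symmetric) and `freq`.
#' @export
read_paml_dat <- function(path) {
  tok <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  if (length(tok) < 190 + 20)
    stop(sprintf("'%s' does not look like a PAML amino-acid model file", path))
  S <- matrix(0, 20, 20)
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- tok[k]
    k <- k + 1L
  }
  S <- S + t(S)
  freq <- tok[190 + seq_len(20)]
  list(exchange = S, freq = freq / sum(freq), name = basename(path))
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A [rate_model].
#' @param t Time (expected substitutions per site), `t >= 0`.
#' @return 20 x 20 stochastic matrix.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(inherits(model, "rate_model"), t >= 0)
  e <- model$eig
  P <- e$left %*% (exp(e$values * t) * e$right)
  P[P < 0] <- 0                     # clip eigen round-off
  dimnames(P) <- dimnames(model$Q)
  P
}

#' Expected fraction of identical sites after divergence t
#'
#' `sum_a pi_a P_aa(t)`: used to calibrate synthetic families to identity
#' targets.
#'
#' @inheritParams prob_matrix
#' @export
expected_identity <- function(model, t) {
  sum(model$pi * diag(prob_matrix(model, t)))
}

#' Divergence time with a given expected identity
#'
#' Inverts [expected_identity]. Identities at or below the saturation value
#' `sum(pi^2)` are unattainable and raise an error.
#'
#' @param model A [rate_model].
#' @param identity Target identity proportion in (saturation, 1].
#' @param t_max Search bound (default 50).
#' @export
identity_time <- function(model, identity, t_max = 50) {
  sat <- sum(model$pi^2)
  if (identity >= 1) return(0)
  if (identity <= sat + 1e-4)
    stop(sprintf("identity target %.3f at or below saturation %.3f",
                 identity, sat))
  uniroot(function(t) expected_identity(model, t) - identity,
          c(0, t_max), tol = 1e-10)$root
}

# evolve one sequence (integer residue indices) along a branch of length t
.evolve <- function(idx, model, t) {
  P <- prob_matrix(model, t)
  vapply(idx, function(a) sample.int(20L, 1L, prob = P[a, ]), integer(1))
}

.sample_root <- function(n_sites, model) {
  sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
}
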