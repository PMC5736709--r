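test_that("the rate model satisfies the reversible-generator invariants", {
  m <- fx_model()
  # stationarity, unit substitution rate, detailed balance
  expect_lt(max(abs(m$pi %*% m$Q)), 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-9)
  flux <- m$pi * m$Q
  expect_lt(max(abs(flux - t(flux))), 1e-12)
  # P(0) = I; rows sum to 1; pi is a fixed point of P(t)
  expect_equal(prob_matrix(m, 0), diag(20), ignore_attr = TRUE,
               tolerance = 1e-12)
  for (t in c(0.1, 0.7, 3)) {
    P <- prob_matrix(m, t)
    expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-9)
    expect_equal(as.numeric(m$pi %*% P), unname(m$pi), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
})

test_that("PAML-format model files load into an equivalent model", {
  m <- fx_model()
  f <- withr::local_tempfile(fileext = ".dat")
  ex <- m$exchange
  lines <- vapply(2:20, function(i)
    paste(sprintf("%.10g", ex[i, 1:(i - 1)]), collapse = " "), "")
  writeLines(c(lines, "", paste(sprintf("%.10g", m$pi), collapse = " ")), f)
  m2 <- rate_model(paml_file = f)
  expect_equal(m2$Q, m$Q, tolerance = 1e-8)
  expect_equal(unname(m2$pi), unname(m$pi), tolerance = 1e-9)
})

test_that("ML distances agree with the brute-force grid-search oracle", {
  m <- fx_model()
  expect_equal(ml_distance("ACDEFGHIKL", "ACDEFGHIKL", m), 0)

  set.seed(51)
  for (t_true in c(0.1, 0.5, 1.5)) {
    a <- sialobind:::.sample_root(400, m)
    b <- sialobind:::.evolve(a, m, t_true)
    sa <- paste(AA[a], collapse = "")
    sb <- paste(AA[b], collapse = "")
    d <- ml_distance(sa, sb, m)
    expect_equal(d, grid_ml_distance(sa, sb, m), tolerance = 1e-4,
                 label = sprintf("t_true=%g", t_true))
  }
  # a gappy pair still works under pairwise deletion
  expect_equal(ml_distance("AC-DE", "ACQD-", m),
               grid_ml_distance("AC-DE", "ACQD-", m), tolerance = 1e-4)
  expect_error(ml_distance("---", "AAA", m), "no comparable sites")
})

test_that("simulated divergence is recovered within 3 observed-information SEs", {
  m <- fx_model()
  set.seed(52)
  a <- sialobind:::.sample_root(2000, m)
  b <- sialobind:::.evolve(a, m, 0.5)
  sa <- paste(AA[a], collapse = "")
  sb <- paste(AA[b], collapse = "")
  d <- ml_distance(sa, sb, m)
  se <- ml_distance_se(sa, sb, m, d)
  expect_lt(abs(d - 0.5), 3 * se)
})

test_that("distance matrices are symmetric, capped and match the per-pair oracle", {
  m <- fx_model()
  aln <- aa_alignment(c(a = "ACDEF", b = "ACDEF", c = "ACDEF"))
  expect_equal(unname(ml_distance_matrix(aln, m)), matrix(0, 3, 3))

  set.seed(53)
  root <- sialobind:::.sample_root(300, m)
  seqs <- vapply(c(0.2, 0.6, 1.1, 0.4), function(t)
    paste(AA[sialobind:::.evolve(root, m, t)], collapse = ""), "")
  names(seqs) <- letters[1:4]
  D <- ml_distance_matrix(aa_alignment(seqs), m)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(D[i, j], ml_distance(seqs[i], seqs[j], m), tolerance = 1e-10)

  # unrelated random sequences never exceed the saturation cap
  set.seed(54)
  rnd <- setNames(replicate(3, random_protein(80)), c("x", "y", "z"))
  expect_lte(max(ml_distance_matrix(aa_alignment(rnd), m)), 10)
})

test_that("neighbour-joining is exact on additive matrices", {
  # ((A:1,B:2):1,(C:3,D:4)): path-sum distances
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(D), rownames(D)]),
               unname(D), tolerance = 1e-12)
  # AB|CD is the single internal split
  expect_equal(sialobind:::tree_splits(tr), "C,D")

  # 3 taxa: closed-form branch lengths a = (dAB + dAC - dBC)/2 etc.
  D3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(len[c("A", "B", "C")]), c(2, 3, 7))

  # label-permutation invariance of the unrooted tree
  perm <- c("C", "A", "D", "B")
  trp <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(tr, trp), 0, ignore_attr = TRUE)
  expect_equal(unname(ape::cophenetic.phylo(trp)[rownames(D), rownames(D)]),
               unname(D), tolerance = 1e-12)

  # random additive trees reconstruct exactly (more seeds in acceptance)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    tr0 <- ape::unroot(tr0)
    D0 <- ape::cophenetic.phylo(tr0)
    rec <- neighbor_joining(D0)
    expect_equal(ape::dist.topo(rec, tr0), 0, ignore_attr = TRUE)
    expect_equal(unname(ape::cophenetic.phylo(rec)[rownames(D0),
                                                   colnames(D0)]),
                 unname(D0), tolerance = 1e-8)
  }
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  Dbad <- D; Dbad[1, 2] <- 4
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("bootstrap supports are reproducible and honest about uncertainty", {
  m <- fx_model()
  fam <- fx_families()

  # a single replicate can only give 0 or 100
  b1 <- bootstrap_tree(fam$pooled, m, n_reps = 1, seed = 5)
  expect_true(all(b1$supports$support_pct %in% c(0, 100)))

  # same seed, same supports; different taxon order, same supports
  b2a <- bootstrap_tree(fam$pooled, m, n_reps = 10, seed = 9)
  b2b <- bootstrap_tree(fam$pooled, m, n_reps = 10, seed = 9)
  expect_identical(b2a$supports, b2b$supports)
  perm <- sample(seq_len(16))
  pooled_perm <- aa_alignment(fam$pooled$mat[perm, , drop = FALSE])
  b2c <- bootstrap_tree(pooled_perm, m, n_reps = 10, seed = 9)
  expect_setequal(b2c$supports$split, b2a$supports$split)

  # star-like data (5 equidistant taxa): no internal edge is forced
  set.seed(55)
  root <- sialobind:::.sample_root(150, m)
  star <- vapply(1:5, function(i)
    paste(AA[sialobind:::.evolve(root, m, 0.5)], collapse = ""), "")
  names(star) <- paste0("t", 1:5)
  bs <- bootstrap_tree(aa_alignment(star), m, n_reps = 40, seed = 6)
  expect_true(all(bs$supports$support_pct <= 90))

  # consensus tree has the same tip set
  expect_setequal(bs$consensus$tip.label, names(star))
})
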