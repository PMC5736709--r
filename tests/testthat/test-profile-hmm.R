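test_that("match-column rule, emissions and pseudocounts follow the builder contract", {
  # two identical gap-free sequences, no pseudocounts: point-mass emissions
  m0 <- build_profile(aa_alignment(c(a = "ACD", b = "ACD")),
                      pseudocount_weight = 0)
  expect_equal(m0$n_match_states, 3L)
  expect_equal(unname(m0$match_emissions[1, "A"]), 1)
  expect_equal(unname(m0$match_emissions[2, "C"]), 1)
  expect_equal(unname(m0$match_emissions[3, "D"]), 1)
  expect_equal(unname(rowSums(m0$match_emissions)), rep(1, 3))

  # any positive pseudocount forces every emission into (0, 1)
  m1 <- build_profile(aa_alignment(c(a = "ACD", b = "ACD")),
                      pseudocount_weight = 0.5)
  expect_true(all(m1$match_emissions > 0 & m1$match_emissions < 1))

  # column gapped in 3 of 4 sequences (gap fraction 0.75 >= 0.5): insert
  aln <- aa_alignment(c(s1 = "AAC", s2 = "A-C", s3 = "A-C", s4 = "A-C"))
  m2 <- build_profile(aln)
  expect_equal(m2$n_match_states, 2L)

  expect_error(build_profile(character(0)), "no sequences")
  expect_error(build_profile(aa_alignment(c(a = "--", b = "--"))),
               "no match columns")
})

test_that("forward probability equals exhaustive path enumeration on tiny models", {
  # 1-match-state point-mass model, sequence "A": <= 3 possible paths
  m <- build_profile(aa_alignment(c(x = "A", y = "A")),
                     pseudocount_weight = 0)
  expect_equal(score_forward(m, "A"), enum_forward_bits(m, "A"),
               tolerance = 1e-12)

  cases <- list(
    list(aln = c(a = "ACD", b = "ACD"), pc = 0,
         seqs = c("ACD", "A", "ACDA", "DCA")),
    list(aln = c(a = "ACD", b = "ACD"), pc = 1,
         seqs = c("ACD", "WACD", "AD", "CCCC")),
    list(aln = c(a = "AC-", b = "ACD", c = "GCD"), pc = 1,
         seqs = c("ACD", "GC", "ACDG")))
  for (cs in cases) {
    hmm <- build_profile(aa_alignment(cs$aln), pseudocount_weight = cs$pc)
    for (s in cs$seqs) {
      expect_equal(score_forward(hmm, s), enum_forward_bits(hmm, s),
                   tolerance = 1e-10, label = paste("enum", s))
      p_dp <- 2^score_forward(hmm, s)
      expect_equal(p_dp, enum_forward_prob(hmm, s), tolerance = 1e-9)
    }
  }
  for (seed in 1:5) {
    hmm <- random_small_hmm(seed)
    set.seed(seed + 100)
    for (r in 1:3) {
      s <- random_protein(sample(2:4, 1))
      expect_equal(score_forward(hmm, s), enum_forward_bits(hmm, s),
                   tolerance = 1e-10)
    }
  }
})

test_that("forward dominates Viterbi and the returned path reproduces its score", {
  set.seed(7)
  for (seed in 1:8) {
    hmm <- random_small_hmm(seed, n_seq = 4, n_col = 6)
    for (r in 1:3) {
      s <- random_protein(sample(3:10, 1))
      fwd <- score_forward(hmm, s)
      v <- viterbi_align(hmm, s)
      expect_gte(fwd, v$bit_score - 1e-12)
      expect_equal(path_bit_score(hmm, s, v$path), v$bit_score,
                   tolerance = 1e-9)
      expect_true(v$envelope[1] >= 0 && v$envelope[2] <= nchar(s) &&
                    v$envelope[1] < v$envelope[2])
    }
  }
})

test_that("Viterbi alignment recovers exact and near-exact matches", {
  m0 <- build_profile(aa_alignment(c(a = "ACD", b = "ACD")),
                      pseudocount_weight = 0)
  v <- viterbi_align(m0, "ACD")
  expect_equal(v$path$state, c("M", "M", "M"))
  expect_equal(v$path$node, 1:3)
  expect_equal(v$envelope, c(0L, 3L))

  # an inserted residue: envelope still covers the matched core, and the
  # path contains exactly one insert state
  m1 <- build_profile(aa_alignment(c(a = "ACD", b = "ACD")),
                      pseudocount_weight = 1)
  v1 <- viterbi_align(m1, "AWCD")
  expect_equal(v1$envelope, c(0L, 4L))
  expect_equal(sum(v1$path$state == "I"), 1L)
})

test_that("model-sampled sequences outscore background draws on average", {
  hmm <- fx_hmms()$canonical
  set.seed(11)
  bg_scores <- replicate(200, score_forward(hmm, random_protein(120)))
  mod_scores <- replicate(200, score_forward(hmm, sample_from_profile(hmm)))
  expect_lt(mean(bg_scores), mean(mod_scores))
})

test_that("scan finds planted domains with accurate envelopes and respects thresholds", {
  hmms <- fx_hmms()
  models <- hmms[c("canonical", "gh33")]

  # a random protein matches nothing at 10 bits
  set.seed(21)
  expect_equal(nrow(scan_sequence(models, random_protein(300), 10)), 0L)

  # planted CBM40 + GH33 segments: exactly two hits, correct model
  # assignment, envelopes within +/- 5 residues of the planted intervals
  set.seed(22)
  pieces <- list(list(dom = "canonical",
                      seq = sample_from_profile(hmms$canonical)),
                 list(dom = "gh33", seq = sample_from_profile(hmms$gh33)))
  pp <- plant_protein(pieces, c(40, 55, 35))
  hits <- scan_sequence(models, pp$sequence, 10)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$model, pp$truth$domain)
  expect_true(all(abs(hits$start - pp$truth$start) <= 5))
  expect_true(all(abs(hits$end - pp$truth$end) <= 5))

  # raising the threshold never adds hits
  lo <- scan_sequence(models, pp$sequence, 5)
  hi <- scan_sequence(models, pp$sequence, 50)
  expect_lte(nrow(hi), nrow(lo))
  expect_lte(nrow(scan_sequence(models, pp$sequence, 1e6)), 0L)
})

test_that("classification follows the cross-model score comparison", {
  mk <- function(can, vib, dec) {
    data.frame(sequence_id = "p", start = 0, end = 50, model = "canonical",
               bits = max(can, vib), bits_canonical = can, bits_vibrio = vib,
               bits_decoy = dec)
  }
  cl <- function(h, ...) classify_hits(h, decoys = "decoy", ...)

  expect_equal(cl(mk(60, 12, 5))$label, "canonical")
  expect_equal(cl(mk(12, 60, 5))$label, "vibrio")
  # decoy dominance: discard as a related, non-CBM40 domain
  expect_equal(cl(mk(8, 7, 20), report_threshold_bits = 0)$label, "reject")
  # below the reporting threshold
  expect_equal(cl(mk(8, 7, -10))$label, "reject")
  # margin requirement
  expect_equal(cl(mk(30, 5, 28), margin_bits = 5)$label, "reject")
  expect_equal(cl(mk(30, 5, 28), margin_bits = 1)$label, "canonical")
  # exact canonical/vibrio tie: canonical, flagged
  tie <- cl(mk(30, 30, 5))
  expect_equal(tie$label, "canonical")
  expect_true(tie$tie)
  expect_equal(cl(mk(60, 12, 5))$margin_bits, 48)
  expect_error(classify_hits(mk(1, 2, 3), decoys = "missing_model"),
               "missing_model")
})

test_that("plain-text model serialization round-trips bit-exactly", {
  hmm <- fx_hmms()$canonical
  f <- withr::local_tempfile(fileext = ".shm")
  write_profile_hmm(hmm, f)
  hmm2 <- read_profile_hmm(f)
  expect_identical(hmm2$match_emissions, hmm$match_emissions)
  expect_identical(hmm2$insert_emissions, hmm$insert_emissions)
  expect_identical(hmm2$transitions, hmm$transitions)
  expect_identical(hmm2$background, hmm$background)
  expect_identical(hmm2$name, hmm$name)
  s <- sample_from_profile(hmm)
  expect_identical(score_forward(hmm2, s), score_forward(hmm, s))
})
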