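test_that("pairwise identity matches hand counts in both modes", {
  expect_equal(pairwise_identity("ACDEFGH", "ACDEFGH"), 100)
  expect_equal(pairwise_identity("ACDEFGH", "ACDEFGH", "aligned_columns"), 100)
  # gap vs residue counts as mismatch: 3 identities over 4 columns
  expect_equal(pairwise_identity("AC-D", "ACED", "aligned_columns"), 75)
  # both-gap columns are excluded (pairwise deletion)
  expect_equal(pairwise_identity("AC--D", "AC--D", "aligned_columns"), 100)
  expect_equal(pairwise_identity("AAAA", "CCCC", "aligned_columns"), 0)
  expect_error(pairwise_identity("ACD", "ACDE", "aligned_columns"),
               "length mismatch")
})

test_that("greedy redundancy reduction honours the identity threshold", {
  s100 <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  # two identical sequences form one cluster of two
  cs <- reduce_redundancy(c(a = s100, b = s100))
  expect_equal(length(cs$clusters), 1L)
  expect_setequal(c(cs$clusters[[1]]$representative_id,
                    cs$clusters[[1]]$member_ids), c("a", "b"))

  mutate_n <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    for (i in sample(length(ch), k))
      ch[i] <- sample(setdiff(AA, ch[i]), 1)
    paste(ch, collapse = "")
  }
  # three sequences mutually ~85% identical: one cluster under greedy rule
  tri <- c(a = s100, b = mutate_n(s100, 15, 1), c = mutate_n(s100, 15, 2))
  expect_equal(length(reduce_redundancy(tri)$clusters), 1L)
  # two sequences ~50% identical: two singletons at the 80% level
  duo <- c(a = s100, b = mutate_n(s100, 50, 3))
  expect_equal(length(reduce_redundancy(duo)$clusters), 2L)
  expect_error(reduce_redundancy(character(0)), "no sequences")
})

test_that("clustering is idempotent and cluster counts grow with the threshold", {
  set.seed(31)
  base <- replicate(4, random_protein(80))
  seqs <- character(0)
  for (b in base) {
    seqs <- c(seqs, b)
    ch <- strsplit(b, "")[[1]]
    for (i in sample(80, 8)) ch[i] <- sample(AA, 1)
    seqs <- c(seqs, paste(ch, collapse = ""))
  }
  names(seqs) <- sprintf("s%02d", seq_along(seqs))

  cs <- reduce_redundancy(seqs, 0.80)
  # every sequence lands in exactly one cluster
  expect_setequal(cs$assignments$sequence_id, names(seqs))
  expect_equal(anyDuplicated(cs$assignments$sequence_id), 0L)
  # representatives re-clustered at the same threshold are all singletons
  reps <- vapply(cs$clusters, `[[`, "", "representative_id")
  cs2 <- reduce_redundancy(seqs[reps], 0.80)
  expect_equal(length(cs2$clusters), length(reps))
  expect_true(all(lengths(lapply(cs2$clusters, `[[`, "member_ids")) == 0))
  # raising the threshold never decreases the number of clusters
  n_cl <- vapply(c(0.5, 0.7, 0.8, 0.95),
                 function(th) length(reduce_redundancy(seqs, th)$clusters),
                 numeric(1))
  expect_true(all(diff(n_cl) >= 0))
})

test_that("proteome survey recovers the planted truth table", {
  hmms <- fx_hmms()
  set.seed(41)
  mk_prot <- function(with_cbm, with_gh33) {
    pieces <- list()
    if (with_cbm)
      pieces <- c(pieces, list(list(
        dom = "canonical", seq = sample_from_profile(hmms$canonical))))
    if (with_gh33)
      pieces <- c(pieces, list(list(
        dom = "gh33", seq = sample_from_profile(hmms$gh33))))
    if (length(pieces) == 0L) return(random_protein(250))
    plant_protein(pieces, rep(40, length(pieces) + 1L))$sequence
  }
  prots <- c(
    setNames(vapply(1:20, function(i) mk_prot(TRUE, TRUE), ""),
             sprintf("both%02d", 1:20)),
    setNames(vapply(1:10, function(i) mk_prot(TRUE, FALSE), ""),
             sprintf("cbm%02d", 1:10)),
    setNames(vapply(1:20, function(i) mk_prot(FALSE, FALSE), ""),
             sprintf("neg%02d", 1:20)))

  sv <- survey_proteomes(prots, hmms[c("canonical", "vibrio", "decoy")],
                         hmms$gh33)
  ids <- unique(sv$sequence_id)
  expect_equal(length(ids), 30L)
  expect_setequal(ids, names(prots)[1:30])
  per_prot <- sv[!duplicated(sv$sequence_id), ]
  expect_equal(sum(per_prot$has_sialidase), 20L)
  expect_true(all(per_prot$label == "canonical"))
  # deterministic ordering by sequence id
  expect_equal(sv$sequence_id, sort(sv$sequence_id))

  # empty proteome and decoy-only proteome give empty surveys
  expect_equal(nrow(survey_proteomes(
    setNames(character(0), character(0)),
    hmms[c("canonical", "vibrio")], hmms$gh33)), 0L)
  set.seed(42)
  dec_prots <- setNames(
    vapply(1:5, function(i) plant_protein(
      list(list(dom = "decoy", seq = sample_from_profile(hmms$decoy))),
      c(30, 30))$sequence, ""),
    sprintf("dec%02d", 1:5))
  expect_equal(nrow(survey_proteomes(
    dec_prots, hmms[c("canonical", "vibrio", "decoy")], hmms$gh33)), 0L)

  expect_error(survey_proteomes(setNames(c("ACD", "ACD"), c("x", "x")),
                                hmms[c("canonical", "vibrio")]),
               "duplicate sequence ids")
})

test_that("co-occurrence fractions hit the planted rate", {
  df <- function(n, label, sial) data.frame(
    sequence_id = sprintf("%s%03d", label, seq_len(n)), label = label,
    has_sialidase = sial)
  expect_equal(cooccurrence_fraction(df(10, "vibrio", TRUE), "vibrio"), 1)
  expect_equal(cooccurrence_fraction(df(10, "canonical", FALSE), "canonical"), 0)
  expect_error(cooccurrence_fraction(df(10, "canonical", TRUE), "vibrio"),
               "empty class")

  # planted 0.92 at n = 100: recovered within binomial standard error
  set.seed(43)
  fam <- fx_families()
  pr <- sim_proteome(fam, fx_gh33(), fx_decoy(), n_proteins = 100,
                     cbm40_rate = 1, cooccurrence_rate = 0.92, seed = 7)
  planted <- mean(pr$protein_truth$has_gh33)
  expect_lt(abs(planted - 0.92), 1.96 * sqrt(0.92 * 0.08 / 100) + 1e-12)
})

test_that("taxon tabulation counts representatives, binning unknowns", {
  rec <- data.frame(
    sequence_id = c(sprintf("c%02d", 1:12), sprintf("v%02d", 1:4), "u01"),
    label = c(rep("canonical", 12), rep("vibrio", 4), "canonical"),
    phylum = c(rep("Firmicutes", 12), rep("Proteobacteria", 4), NA),
    class = c(rep("Clostridia", 12), rep("Gammaproteobacteria", 4), NA),
    genus = c(sprintf("G%d", rep(1:5, length.out = 12)),
              sprintf("VG%d", rep(1:2, length.out = 4)), NA),
    has_sialidase = TRUE)
  # every record its own representative
  cs <- structure(list(
    clusters = lapply(rec$sequence_id, function(id)
      list(representative_id = id, member_ids = character(0))),
    identity_threshold = 0.8,
    assignments = data.frame(sequence_id = rec$sequence_id,
                             representative = rec$sequence_id)),
    class = "cluster_set")
  tab <- tabulate_taxa(rec, cs)
  expect_equal(sum(tab$n_representatives), 17L)
  expect_equal(sum(tab$n_representatives[tab$label == "canonical"]), 13L)
  gc <- attr(tab, "genus_counts")
  expect_equal(unname(gc[["canonical"]]), 6L)  # 5 genera + unclassified
  expect_equal(unname(gc[["vibrio"]]), 2L)
  expect_true("unclassified" %in% tab$genus)

  # single record -> one row with count 1
  one <- tabulate_taxa(rec[1, ], structure(list(
    clusters = list(list(representative_id = "c01",
                         member_ids = character(0))),
    identity_threshold = 0.8,
    assignments = data.frame(sequence_id = "c01", representative = "c01")),
    class = "cluster_set"))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_representatives, 1L)

  # a representative without a survey record is an error
  bad <- structure(list(
    clusters = list(list(representative_id = "ghost",
                         member_ids = character(0))),
    identity_threshold = 0.8,
    assignments = data.frame(sequence_id = "ghost",
                             representative = "ghost")),
    class = "cluster_set")
  expect_error(tabulate_taxa(rec, bad), "ghost")
})
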