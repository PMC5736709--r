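#' Simulate two divergent domain families along a tree
#'
#' Generates amino-acid sequences for two families (canonical-like and
#' Vibrio-like by default) by evolving a common root under the rate model:
#' within-family and between-family mean identities are calibrated to the
#' targets via [identity_time] and checked on the realised data, with
#' rejection resampling (bounded retries) when outside +/- 10 percentage
#' points. Defaults emulate the observed identity structure of the CBM40
#' family: within-family identities of order 20-70% (target mean 0.45)
#' and between-family identity near the 0.17 ceiling.
#'
#' @param n_per_family Sequences per family (>= 2), default 8.
#' @param n_sites Alignment columns, default 120.
#' @param within_identity,between_identity Target mean pairwise identity
#'   proportions (defaults 0.45 and 0.17).
#' @param family_names Length-2 labels, default canonical/vibrio.
#' @param model A [rate_model].
#' @param seed Integer seed; same (config, seed) reproduces identical
#'   output.
#' @param max_retries Rejection-resampling bound, default 50.
#' @return List with `alignments` (named list of [aa_alignment] per
#'   family), `pooled` (combined [aa_alignment]), `tree` (the generating
#'   `phylo`), `truth` (data.frame `sequence_id`, `family`),
#'   `realized` (named identity summary), `seed`.
#' @export
sim_families <- function(n_per_family = 8, n_sites = 120,
                         within_identity = 0.45, between_identity = 0.17,
                         family_names = c("canonical", "vibrio"),
                         model = rate_model(), seed = NULL,
                         max_retries = 50) {
  stopifnot(n_per_family >= 2, length(family_names) == 2L)
  t_w <- identity_time(model, within_identity)
  t_between <- identity_time(model, between_identity)
  t_anc <- max(t_between - t_w, 1e-6)

  mean_ident <- function(mat_a, mat_b = NULL) {
    if (is.null(mat_b)) {
      n <- nrow(mat_a)
      v <- c()
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        v <- c(v, mean(mat_a[i, ] == mat_a[j, ]))
      mean(v)
    } else {
      v <- c()
      for (i in seq_len(nrow(mat_a))) for (j in seq_len(nrow(mat_b)))
        v <- c(v, mean(mat_a[i, ] == mat_b[j, ]))
      mean(v)
    }
  }

  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      root <- .sample_root(n_sites, model)
      anc <- lapply(1:2, function(i) .evolve(root, model, t_anc / 2))
      fam <- lapply(anc, function(a)
        t(vapply(seq_len(n_per_family),
                 function(i) .evolve(a, model, t_w / 2),
                 integer(n_sites))))
      w1 <- mean_ident(fam[[1]])
      w2 <- mean_ident(fam[[2]])
      bt <- mean_ident(fam[[1]], fam[[2]])
      ok <- abs(w1 - within_identity) <= 0.10 &&
        abs(w2 - within_identity) <= 0.10 &&
        abs(bt - between_identity) <= 0.10
      if (ok) break
      if (try == max_retries)
        stop("identity targets unattainable after max retries")
    }
    ids <- lapply(1:2, function(f)
      sprintf("%s_%02d", family_names[f], seq_len(n_per_family)))
    alns <- lapply(1:2, function(f) {
      m <- matrix(AA_ALPHABET[fam[[f]]], nrow = n_per_family)
      rownames(m) <- ids[[f]]
      aa_alignment(m)
    })
    names(alns) <- family_names
    pooled <- aa_alignment(rbind(alns[[1]]$mat, alns[[2]]$mat))
    nwk <- sprintf("((%s):%g,(%s):%g);",
                   paste(sprintf("%s:%g", ids[[1]], t_w / 2), collapse = ","),
                   t_anc / 2,
                   paste(sprintf("%s:%g", ids[[2]], t_w / 2), collapse = ","),
                   t_anc / 2)
    list(alignments = alns, pooled = pooled,
         tree = ape::read.tree(text = nwk),
         truth = data.frame(
           sequence_id = c(ids[[1]], ids[[2]]),
           family = rep(family_names, each = n_per_family)),
         realized = c(within_1 = w1, within_2 = w2, between = bt),
         seed = seed)
  })
}

#' Simulate one domain family
#'
#' Evolves `n_members` sequences from a common root at the divergence
#' implied by the within-family identity target. Used for the extra
#' families a survey needs alongside the two CBM40 subtypes: the GH33
#' sialidase domain and non-CBM40 decoy domains.
#'
#' @param n_members Sequences in the family.
#' @param n_sites Alignment columns.
#' @param within_identity Target mean pairwise identity proportion.
#' @param prefix Sequence-id prefix.
#' @param model A [rate_model].
#' @param seed Integer seed.
#' @return An [aa_alignment].
#' @export
sim_single_family <- function(n_members = 6, n_sites = 120,
                              within_identity = 0.5, prefix = "fam",
                              model = rate_model(), seed = NULL) {
  t_w <- identity_time(model, within_identity)
  with_seed(seed, {
    root <- .sample_root(n_sites, model)
    m <- t(vapply(seq_len(n_members),
                  function(i) .evolve(root, model, t_w / 2),
                  integer(n_sites)))
    m <- matrix(AA_ALPHABET[m], nrow = n_members)
    rownames(m) <- sprintf("%s_%02d", prefix, seq_len(n_members))
    aa_alignment(m)
  })
}

#' Sample a domain sequence from a profile HMM
#'
#' Emits one residue per match state from the match emission
#' distributions (no inserts/deletes): a typical family member as the
#' profile sees it. Used to plant domain instances with known envelopes.
#'
#' @param hmm A `profile_hmm`.
#' @return Amino-acid string of length `n_match_states`.
#' @export
sample_from_profile <- function(hmm) {
  stopifnot(inherits(hmm, "profile_hmm"))
  idx <- apply(hmm$match_emissions, 1L, function(p)
    sample.int(20L, 1L, prob = p))
  paste(AA_ALPHABET[idx], collapse = "")
}

# sample a new family member: evolve a random seed-alignment row
.spawn_instance <- function(aln, model, divergence = 0.25) {
  i <- sample.int(nrow(aln$mat), 1L)
  idx <- match(aln$mat[i, ], AA_ALPHABET)
  paste(AA_ALPHABET[.evolve(idx, model, divergence)], collapse = "")
}

#' Sample new family members from a seed alignment
#'
#' Each instance is a randomly chosen alignment row evolved for
#' `divergence` substitutions/site under the rate model, i.e. a plausible
#' unseen member of the family.
#'
#' @param alignment An [aa_alignment] (gap-free family seed).
#' @param n Number of instances.
#' @param divergence Branch length to the seed member (default 0.25).
#' @param model A [rate_model].
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
sim_domain_instances <- function(alignment, n, divergence = 0.25,
                                 model = rate_model(), seed = NULL) {
  aln <- aa_alignment(alignment)
  with_seed(seed, {
    vapply(seq_len(n), function(i) .spawn_instance(aln, model, divergence),
           character(1))
  })
}

.random_linker <- function(n, model) {
  paste(AA_ALPHABET[.sample_root(n, model)], collapse = "")
}

#' Simulate a proteome with planted CBM40/GH33/decoy domains
#'
#' Builds proteins as random background linkers with planted domain
#' instances (new sequences evolved from the seed families), a controllable
#' sialidase co-occurrence rate among CBM40-positive proteins, and decoy
#' domains from an unrelated family. A taxonomy table is generated with
#' canonical-type proteins placed in Firmicutes and Vibrio-type proteins in
#' Gammaproteobacteria, mirroring the observed phylotypic split.
#'
#' @param families Output of [sim_families] (the two CBM40 families).
#' @param gh33_family,decoy_family [aa_alignment]s for the sialidase and
#'   decoy domains (defaults generated from `seed`).
#' @param n_proteins Number of proteins, default 50.
#' @param cbm40_rate Fraction of proteins carrying a CBM40 domain.
#' @param vibrio_frac Fraction of CBM40-positive proteins of Vibrio type.
#' @param cooccurrence_rate P(GH33 | CBM40), default 0.92, the canonical
#'   co-occurrence level.
#' @param decoy_rate Fraction of proteins carrying a decoy domain.
#' @param divergence Branch length from seed family to planted instance.
#' @param linker_range Min/max linker length (residues).
#' @param model A [rate_model].
#' @param seed Integer seed.
#' @return List with `proteins` (named character), `taxonomy` (data.frame
#'   `sequence_id`, `phylum`, `class`, `genus`), `truth` (data.frame of
#'   planted domains: `sequence_id`, `domain`, `start`, `end`),
#'   `protein_truth` (per-protein flags) and `seed`.
#' @export
sim_proteome <- function(families, gh33_family = NULL, decoy_family = NULL,
                         n_proteins = 50, cbm40_rate = 0.6,
                         vibrio_frac = 0.3, cooccurrence_rate = 0.92,
                         decoy_rate = 0.2, divergence = 0.25,
                         linker_range = c(30, 80), model = rate_model(),
                         seed = NULL) {
  stopifnot(cbm40_rate >= 0, cbm40_rate <= 1,
            cooccurrence_rate >= 0, cooccurrence_rate <= 1,
            decoy_rate >= 0, decoy_rate <= 1)
  if (is.null(gh33_family))
    gh33_family <- sim_single_family(6, 150, 0.5, "gh33", model,
                                     seed = if (is.null(seed)) NULL else seed + 101L)
  if (is.null(decoy_family))
    decoy_family <- sim_single_family(6, 110, 0.5, "decoy", model,
                                      seed = if (is.null(seed)) NULL else seed + 202L)
  can_aln <- families$alignments[[1]]
  vib_aln <- families$alignments[[2]]

  canon_genera <- sprintf("FirmiGenus%02d", 1:18)
  canon_classes <- c("Bacilli", "Clostridia")
  vib_genera <- sprintf("GammaGenus%02d", 1:5)

  with_seed(seed, {
    proteins <- character(n_proteins)
    ids <- sprintf("prot%03d", seq_len(n_proteins))
    names(proteins) <- ids
    tax <- vector("list", n_proteins)
    dom_rows <- list()
    prot_rows <- list()
    for (i in seq_len(n_proteins)) {
      has_cbm <- runif(1) < cbm40_rate
      type <- if (has_cbm && runif(1) < vibrio_frac) "vibrio"
              else if (has_cbm) "canonical" else NA_character_
      has_gh33 <- has_cbm && runif(1) < cooccurrence_rate
      has_decoy <- runif(1) < decoy_rate
      segs <- character(0)
      pieces <- list()
      if (has_cbm)
        pieces <- c(pieces, list(list(
          dom = paste0("cbm40_", type),
          seq = .spawn_instance(if (type == "vibrio") vib_aln else can_aln,
                                model, divergence))))
      if (has_gh33)
        pieces <- c(pieces, list(list(
          dom = "gh33", seq = .spawn_instance(gh33_family, model, divergence))))
      if (has_decoy)
        pieces <- c(pieces, list(list(
          dom = "decoy", seq = .spawn_instance(decoy_family, model, divergence))))
      if (length(pieces) > 1L) pieces <- pieces[sample.int(length(pieces))]
      pos <- 0L
      prot <- ""
      for (p in pieces) {
        lk <- .random_linker(sample(linker_range[1]:linker_range[2], 1L), model)
        prot <- paste0(prot, lk)
        pos <- nchar(prot)
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          sequence_id = ids[i], domain = p$dom,
          start = pos, end = pos + nchar(p$seq))
        prot <- paste0(prot, p$seq)
      }
      prot <- paste0(prot, .random_linker(
        sample(linker_range[1]:linker_range[2], 1L), model))
      proteins[i] <- prot
      if (!is.na(type) && type == "canonical") {
        tax[[i]] <- data.frame(sequence_id = ids[i], phylum = "Firmicutes",
                               class = sample(canon_classes, 1L),
                               genus = sample(canon_genera, 1L))
      } else if (!is.na(type) && type == "vibrio") {
        tax[[i]] <- data.frame(sequence_id = ids[i], phylum = "Proteobacteria",
                               class = "Gammaproteobacteria",
                               genus = sample(vib_genera, 1L))
      } else {
        tax[[i]] <- data.frame(sequence_id = ids[i], phylum = "Firmicutes",
                               class = "Clostridia",
                               genus = sample(canon_genera, 1L))
      }
      prot_rows[[i]] <- data.frame(sequence_id = ids[i], has_cbm40 = has_cbm,
                                   type = type, has_gh33 = has_gh33,
                                   has_decoy = has_decoy)
    }
    list(proteins = proteins,
         taxonomy = do.call(rbind, tax),
         truth = if (length(dom_rows) > 0) do.call(rbind, dom_rows)
                 else data.frame(sequence_id = character(0),
                                 domain = character(0), start = integer(0),
                                 end = integer(0)),
         protein_truth = do.call(rbind, prot_rows),
         seed = seed)
  })
}

#' Simulate STD NMR build-up curves
#'
#' `y = a * (1 - exp(-b * t))` plus Gaussian noise at the standard
#' saturation-time grid 0.5-5 s.
#'
#' @param protons Named list of true parameters, each `c(a = , b = )`.
#' @param times Saturation times (s), default `c(0.5, 1, 2, 3, 4, 5)`.
#' @param noise_sd Gaussian noise SD (intensity units), default 0.
#' @param ligand Ligand label.
#' @param seed Integer seed.
#' @return List with `data` (data.frame `ligand`, `proton`, `time_s`,
#'   `std_pct`) and `truth` (data.frame `proton`, `a`, `b`,
#'   `initial_slope`).
#' @export
sim_std <- function(protons, times = c(0.5, 1, 2, 3, 4, 5), noise_sd = 0,
                    ligand = "ligand", seed = NULL) {
  stopifnot(length(protons) >= 1, noise_sd >= 0)
  with_seed(seed, {
    rows <- lapply(names(protons), function(p) {
      a <- protons[[p]][["a"]]; b <- protons[[p]][["b"]]
      stopifnot(a > 0, b > 0)
      y <- a * (1 - exp(-b * times)) + rnorm(length(times), 0, noise_sd)
      data.frame(ligand = ligand, proton = p, time_s = times, std_pct = y)
    })
    truth <- data.frame(
      proton = names(protons),
      a = vapply(protons, `[[`, numeric(1), "a"),
      b = vapply(protons, `[[`, numeric(1), "b"))
    truth$initial_slope <- truth$a * truth$b
    rownames(truth) <- NULL
    list(data = do.call(rbind, rows), truth = truth, seed = seed)
  })
}

#' Simulate a single-site ITC titration
#'
#' Heats from [itc_forward] under the stated cell/syringe conditions plus
#' Gaussian noise and an optional constant dilution heat; when
#' `dilution_heat_uJ` is non-zero a matching buffer-control series is
#' generated alongside.
#'
#' @param kd_mM,dH_kJmol True binding parameters.
#' @param cell_conc_uM Cell protein (uM), default 115.
#' @param syringe_conc_mM Syringe ligand (mM), default 10.
#' @param cell_volume_ul Cell volume (ul), default 200.
#' @param n_injections,inj_volume_ul Injection schedule (19 x 2 ul default).
#' @param n_sites True stoichiometry, default 1.
#' @param dilution_heat_uJ Constant dilution heat per injection, default 0.
#' @param noise_sd_uJ Gaussian noise SD (uJ), default 0.
#' @param temperature_K Temperature (K).
#' @param seed Integer seed.
#' @return List with `titration` (an [itc_titration], control series
#'   attached when generated) and `truth`.
#' @export
sim_itc <- function(kd_mM, dH_kJmol = -40, cell_conc_uM = 115,
                    syringe_conc_mM = 10, cell_volume_ul = 200,
                    n_injections = 19, inj_volume_ul = 2, n_sites = 1,
                    dilution_heat_uJ = 0, noise_sd_uJ = 0,
                    temperature_K = 298.15, seed = NULL) {
  v <- rep(inj_volume_ul, n_injections)
  q0 <- itc_forward(kd_mM, dH_kJmol, v, n_sites = n_sites,
                    cell_conc_uM = cell_conc_uM,
                    syringe_conc_mM = syringe_conc_mM,
                    cell_volume_ul = cell_volume_ul)
  with_seed(seed, {
    q <- q0 + dilution_heat_uJ + rnorm(n_injections, 0, noise_sd_uJ)
    control <- if (dilution_heat_uJ != 0)
      dilution_heat_uJ + rnorm(n_injections, 0, noise_sd_uJ) else NULL
    tit <- itc_titration(v, q, cell_conc_uM, syringe_conc_mM,
                         cell_volume_ul, control_heats_uJ = control,
                         temperature_K = temperature_K)
    list(titration = tit,
         truth = list(kd_mM = kd_mM, dH_kJmol = dH_kJmol,
                      n_sites = n_sites,
                      dilution_heat_uJ = dilution_heat_uJ),
         seed = seed)
  })
}

#' Simulate a replicate glycan-array RFU table
#'
#' Replicate RFUs are the true mean plus Gaussian noise, floored at zero.
#'
#' @param means Named numeric vector of true per-glycan mean RFUs (>= 0).
#' @param n_reps Replicates per glycan, default 4.
#' @param noise_sd Gaussian noise SD (RFU), default 0.
#' @param seed Integer seed.
#' @return List with `data` (long data.frame `glycan_id`, `replicate`,
#'   `rfu`) and `truth`.
#' @export
sim_rfu <- function(means, n_reps = 4, noise_sd = 0, seed = NULL) {
  stopifnot(all(means >= 0), n_reps >= 1)
  with_seed(seed, {
    rows <- lapply(names(means), function(g) {
      r <- pmax(means[[g]] + rnorm(n_reps, 0, noise_sd), 0)
      data.frame(glycan_id = g, replicate = seq_len(n_reps), rfu = r)
    })
    d <- do.call(rbind, rows)
    names(d$rfu) <- NULL
    list(data = d,
         truth = data.frame(glycan_id = names(means),
                            true_mean = unname(means)),
         seed = seed)
  })
}
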