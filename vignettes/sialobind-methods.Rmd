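---
title: "Methods: models, parameters and design choices in sialobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sialobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sialobind re-implements, as one tested toolkit, the computational stages of
a study of sialic-acid recognition by a gut-symbiont carbohydrate-binding
module (CBM40) appended to an intramolecular trans-sialidase: discovery and
subtype classification of CBM40 domains with profile hidden Markov models,
a sialidase (GH33) co-occurrence screen with redundancy reduction and taxon
tabulation, a distance-based phylogeny with bootstrap supports, STD NMR
binding-epitope mapping, single-site ITC isotherm fitting, and the small
assay normalisations around them. A synthetic-data module generates every
input with planted ground truth, so the whole pipeline runs and is tested
without any external downloads. This vignette documents the models, the
parameters that matter, and the design choices made where the underlying
procedures are conventionally under-specified.

## Profile HMMs for CBM40 detection and typing

`build_profile()` estimates the usual match/insert/delete architecture from
a seed alignment:

* **Match-column rule.** A column is a match state when its gap fraction is
  strictly below `match_fraction` (default 0.5). This is the common
  heuristic of profile builders; the original analysis pipeline's rule is
  not documented, and the parameter is exposed.
* **Emissions.** Weighted residue counts plus `pseudocount_weight` (default
  1.0) times the background distribution, renormalised. Background
  defaults to uniform over the 20 residues; with a positive pseudocount
  every probability is strictly positive. Additive background-proportional
  pseudocounts were chosen over Dirichlet mixtures: at desk scale (seed
  alignments of 6-16 sequences) the extra machinery buys little, and the
  weight is configurable.
* **Transitions.** Counted from the observed per-sequence state paths with
  add-one (Laplace) pseudocounts, normalised per source state.
* **Local alignment mode.** Entry is uniform over ordered pairs of match
  states with total weight `2/(K(K+1))`; exit after any match state is
  free; alignment may start at any sequence position. Flanking residues
  are emitted by the background in both numerator and denominator of the
  odds ratio and cancel, so `score_forward()` returns a log2-odds (bit)
  score of the sum over *all* local alignments, and `viterbi_align()` the
  best single one. Bit scores are therefore comparable across models of
  different lengths, which is what the cross-model classification needs.
  No E-value calibration is attempted: classification uses bit-score
  comparison only.
* **Ambiguity codes.** `B Z X J U O` are scored neutrally (zero log-odds):
  they neither support nor penalise a hit. Any other character is an error
  naming the character and its position.
* **Reporting threshold.** Default 10 bits, configurable. Random 300-mers
  under the background stay below it while planted domains score in the
  hundreds of bits; the threshold is deliberately conservative rather than
  calibrated, since no significance model is fitted.
* **Hit resolution.** `scan_sequence()` finds non-overlapping envelopes per
  model by iterated masked Viterbi search; envelopes from different models
  overlapping by more than half of the shorter one are resolved in favour
  of the higher score. Every reported hit carries forward scores of all
  supplied models over its envelope; `classify_hits()` labels a hit with
  the best-scoring CBM40 subtype when it beats every decoy by
  `margin_bits` (default 0) and the reporting threshold, and rejects it
  otherwise. An exact canonical/Vibrio tie is labelled canonical and
  flagged — deterministic and visible, since a margin of exactly zero bits
  carries no information either way.

The forward/Viterbi recursions run in C++; correctness is established
against an exhaustive path-enumeration oracle on models with up to three
match states and sequences of up to four residues (agreement to 1e-9 on
the probability scale), plus the `forward >= Viterbi` and
path-score-consistency properties on randomly built models.

## Survey, redundancy reduction and taxon tables

`survey_proteomes()` records one row per classified CBM40 hit, screens the
full protein with a GH33 model for sialidase co-occurrence, and attaches
caller-supplied taxonomy (no remote lookups). `cooccurrence_fraction()`
computes the per-subtype fraction of proteins that also carry GH33.

`reduce_redundancy()` clusters greedily at a global-identity threshold
(default 0.80): sequences in order of decreasing length (ties by id) join
the first representative at or above the threshold, else found a cluster.
Identity is computed over all columns of a Needleman-Wunsch global
alignment (BLOSUM62, gap open 10, gap extension 0.5), with gaps counting
in the denominator — the conservative convention, chosen because the
original procedure does not define its denominator; `pairwise_identity()`
also offers an `aligned_columns` mode with pairwise deletion of both-gap
columns. Whether the published 80% reduction operated on full proteins or
domain envelopes is unknowable from the text; this implementation takes
whatever sequences it is given, so either convention can be applied.
`tabulate_taxa()` counts cluster representatives only, and bins missing
taxonomy as `unclassified` rather than dropping records.

## Distances, neighbour joining and bootstrap

Pairwise distances are maximum-likelihood under a reversible empirical
amino-acid model with a uniform rate across sites (no gamma), pairwise
deletion of gapped columns, and optimisation of
`sum_sites log(pi_a P_ab(t))` over `t >= 0`.

* **Model constants.** The model slot is pluggable: `rate_model()` accepts
  any PAML-format matrix file or any empirical model shipped with
  phangorn. The default is Blosum62 — like the PMB matrix it descends
  from the BLOCKS alignment database, and every test and oracle here is
  model-agnostic, so swapping in a PMB file changes no code. The
  generator is scaled to one expected substitution per site per unit
  time; `P(t) = exp(Qt)` is computed from the symmetrised
  eigendecomposition.
* **Saturation cap.** When the likelihood is still rising at 10
  substitutions/site the pair is reported at the cap — matching common
  distance-tool behaviour and keeping matrices finite.
* **NJ.** Agglomeration is delegated to `ape::nj()` behind
  `neighbor_joining()`, with negative estimated branch lengths clamped to
  zero and the deficit reported. Exactness on additive matrices is tested
  against path-sum distances from random trees of up to 12 taxa.
* **Bootstrap.** Columns are resampled with replacement; distances and NJ
  are recomputed per replicate; the support of each internal bipartition
  of the full-data NJ tree is the percentage of replicates containing it.
  Replicates in which some pair loses all comparable sites are dropped
  and counted. Supports are reported on the full-data tree (the display
  convention of the original figure); a consensus tree is also returned,
  extended majority rule by default (majority splits plus remaining
  compatible splits in frequency order — implemented in-package, since
  ape provides plain majority only), with plain majority behind a flag.

## STD NMR build-up fitting and epitope maps

Saturation-transfer build-up is fitted per proton to
`y = a (1 - exp(-b t))` by unweighted least squares (no weighting scheme is
documented for the reference analysis), with `a0 = max(y)`, `b0` from the
first two points, and fallback starts under Levenberg-Marquardt. The
printed form of this equation, `a (1 - exp(b t))`, only saturates for
negative `b`; it is implemented with the explicit negative sign and `b > 0`
reported, which changes no magnitudes. The binding-epitope quantity is the
initial slope `a*b`; `epitope_map()` normalises slopes to the reference
proton — H7 of the sialic-acid ring by convention, exactly 100% by
construction — and bins them for display: blue 0-24%, yellow 25-50%, red
51-100%, and a separate class above 100%. Continuous values are binned at
the boundaries 25 (into yellow), above 50 (red) and above 100. The
reference proton is a parameter because for N-glycolyl ligands the
reference convention is only implied. Maps are invariant under uniform
intensity rescaling (the model is linear in `a`), which the tests assert.

## Single-site ITC

`itc_forward()` implements the standard overfill-displacement convention:
after cumulative injected volume `dV` into a cell of volume `V0`, total
concentrations are `Mt = M0 (1 - dV/2V0)/(1 + dV/2V0)` and
`Xt = X0 (dV/V0)/(1 + dV/2V0)`; bound ligand follows from the single-site
quadratic in closed form, and the i-th injection heat is
`Q_i - Q_{i-1} + (v_i/V0)(Q_i + Q_{i-1})/2` plus a constant baseline. The
vendor's exact convention is not documented; this is the dominant published
one, and under it the cumulative tight-binding heat approaches
`M0 V0 dH` to within the few percent of protein displaced before binding —
the tests assert that limit with a 5% band.

`fit_isotherm()` does nonlinear least squares over `(log Kd, dH, baseline)`
with stoichiometry fixed at 1.0 (the crystallographic value; `fix_n =
FALSE` frees it). Fitting in log-Kd space conditions the problem; Kd is
reported in mM. Buffer-control heats are subtracted first when present;
the baseline is fitted by default (as vendor software does) and can be
fixed at zero; discarding the first injection is available but off by
default, since the reference analysis does not say whether injection 1 was
excluded. The Wiseman parameter `c = M0 N / Kd` flags fits with
`c < 0.01` as `"unreliable (low c-value)"` — the cut-off is this package's
choice for when a Kd should be called an estimate, matching the regime of
the weakest monosaccharide titrations (115 uM protein against a ~20 mM
Kd gives c near 0.006). `thermo_summary()` derives `dG = RT ln Kd` and
`-TdS = dG - dH`; the identity `dG = dH + (-TdS)` holds exactly as stored,
and an interaction with `dH < dG` is enthalpy-driven with unfavourable
entropy.

## Assay normalisations

Four small, exactly specified computations: glycan-array ranking
(`100 * mean RFU / max mean RFU`, sample SD over the four replicates —
sample rather than population SD, since the convention is unstated),
area-weighted sialylation fraction over assigned O-glycan peaks, ELISA
normalisation to a reference well set to exactly 100%, squared Pearson
correlation, and internal-standard quantification with a configurable
response factor (default 1). Ranking is scale-invariant, the sialylation
fraction is invariant to row order and peak splitting, and ELISA
normalisation cancels any common gain; all three invariances are tested.

## The synthetic-data module

The generators define the study conditions under which everything is
tested:

* `sim_families()` evolves two domain families from a common root under
  the rate model, calibrated by inverting the expected-identity curve
  `I(t) = sum_a pi_a P_aa(t)` and verified on the realised data
  (rejection resampling, at most 50 retries, +/- 10 percentage points).
  Defaults — 8 + 8 taxa, 120 columns, within-family identity target 0.45,
  between-family 0.17 — emulate the observed CBM40 identity structure:
  canonical pairs in the 20-70% band and a canonical-vs-Vibrio ceiling
  near 17%.
* `sim_proteome()` assembles proteins from background linkers (30-80
  residues) with planted CBM40, GH33 and decoy instances (seed members
  evolved 0.25 substitutions/site), a configurable CBM40 rate and a
  sialidase co-occurrence rate defaulting to 0.92 — the canonical-type
  co-occurrence level; taxonomy places canonical types in Firmicutes
  genera and Vibrio types in Gammaproteobacteria.
* `sim_std()` uses the experimental saturation-time grid
  {0.5, 1, 2, 3, 4, 5} s; `sim_itc()` the instrument geometry (200 ul
  cell, 19 x 2 ul injections) and stated concentrations (115 uM protein,
  10 mM ligand; 25 mM for the monosaccharide; 230 and 173 uM for the
  6'SL and mutant runs); `sim_rfu()` four replicates per glycan.

Everything is deterministic given (config, seed) and carries a planted
truth table. What the generators do **not** emulate: indels within domains
(families are generated gap-free, so insert/delete states are exercised by
the seed alignments and by mismatched queries, not by planted indels),
compositional bias and disorder in linkers, correlated noise and baseline
drift in ITC thermograms, spectral overlap in STD intensities, and real
taxonomy breadth. Passing tests therefore demonstrate correctness of the
computations under clean, in-model conditions — not robustness to every
artefact of real data.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized for a single CPU:
families of 8 + 8 sequences with 120 columns, proteomes of 50-100
proteins, 100 bootstrap replicates, 50-seed Monte-Carlo recovery for ITC,
and enumeration oracles on models of at most 3 match states. These sizes
were chosen so each property is informative (e.g. binomial error at
n = 100 is small enough to distinguish 0.92 from 1.0) while the whole
suite runs in about a minute. The published survey's absolute counts
(tens of thousands of hits over tens of thousands of genomes, 51
non-redundant representatives) depend on a 2017 database snapshot and are
deliberately out of scope; the pipeline reproduces their *structure* —
combined-model recall, subtype separation, co-occurrence rate, bootstrap
dichotomy — on planted data instead.

## Known limitations

* Bit-score semantics are this package's own well-defined local-alignment
  model; no attempt is made to match any published HMM package
  score-for-score, and no E-values are computed.
* The default rate-model constants are Blosum62, not PMB; supply a PMB
  PAML file via `rate_model(paml_file = ...)` for exact constants.
* The ITC model is strictly single-site with a constant baseline; no
  multi-site or displacement-titration schemes.
* STD fitting takes integrated intensities as input; no spectral
  processing is attempted.
* `reduce_redundancy()` is quadratic in the number of sequences — fine for
  domain surveys at desk scale, not for millions of proteins.
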