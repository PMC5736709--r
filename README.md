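# sialobind

Tools for studying how gut bacteria recognise sialic acid. Mucin-degrading
symbionts such as *Ruminococcus gnavus* carry an intramolecular
trans-sialidase whose GH33 catalytic domain is paired with a sialic
acid–specific carbohydrate-binding module (CBM40); the CBM40 doubles as a
mucus adhesin, targeting the bacterium to sialylated regions of the gut.
sialobind packages the computational side of characterising such a module,
for bioinformaticians and glycobiologists who want the analyses
reproducible end to end:

* **Domain discovery and typing** — profile hidden Markov models built
  from seed alignments; local forward/Viterbi bit scores; scanning of
  proteomes; classification of each hit as *canonical* CBM40,
  *Vibrio*-type CBM40, or reject, by cross-model score comparison against
  decoy models.
* **Survey statistics** — sialidase (GH33) co-occurrence fractions,
  greedy redundancy reduction at an identity threshold (80% by default),
  and taxon tables over cluster representatives.
* **Phylogeny** — maximum-likelihood pairwise distances under a pluggable
  empirical amino-acid model (uniform rate, pairwise deletion),
  neighbour-joining trees, bootstrap supports by column resampling, and
  majority-rule consensus (extended by default).
* **Binding biophysics** — STD NMR build-up curves fitted to
  *y* = *a*(1 − e^(−*bt*)); binding-epitope maps from initial slopes
  *a·b* normalised to the H7 reference proton (≡ 100%); single-site ITC
  isotherms with N fixed at 1.0, fitted for *K*d and ΔH, with
  ΔG = RT ln *K*d and −TΔS = ΔG − ΔH, and a Wiseman-c reliability flag
  for weak titrations.
* **Assay normalisations** — glycan-array ranking
  (100 × mean RFU / max mean RFU), area-weighted sialylation fractions,
  ELISA normalisation to a 100% reference, r², internal-standard
  quantification.
* **Synthetic data** — seeded generators for every input (domain
  families, proteomes with planted truth, build-up curves, thermograms,
  RFU tables), so all stages run with no downloads.

## Worked example

Simulate two CBM40 families plus a GH33 family, build models, survey a
proteome, and check the subtype dichotomy and a binding isotherm:

```r
library(sialobind)

fam      <- sim_families(seed = 42)           # 8 + 8 taxa, two families
gh33_fam <- sim_single_family(6, 150, 0.5, "gh33", seed = 142)
models   <- list(
  canonical = build_profile(fam$alignments$canonical, name = "canonical"),
  vibrio    = build_profile(fam$alignments$vibrio,    name = "vibrio"))
gh33     <- build_profile(gh33_fam, name = "gh33")

prot <- sim_proteome(fam, gh33_family = gh33_fam, n_proteins = 20, seed = 7)
sv   <- survey_proteomes(prot$proteins, models, gh33, prot$taxonomy)
head(sv[, c("sequence_id","start","end","label","bits","has_sialidase","genus")], 4)
#>   sequence_id start end     label     bits has_sialidase        genus
#> 1     prot003   247 367 canonical 172.9320          TRUE FirmiGenus11
#> 2     prot004   406 524 canonical 142.7170          TRUE FirmiGenus07
#> 3     prot007    76 195 canonical 178.4685          TRUE FirmiGenus08
#> 4     prot008    74 190    vibrio 161.1046          TRUE GammaGenus05
```

Each row is one domain hit: a 0-based half-open envelope on the protein,
its subtype label from the cross-model score comparison (`bits` is the
forward log2-odds score over the envelope), whether the same protein also
carries a sialidase domain, and the caller-supplied taxonomy.

```r
bs <- bootstrap_tree(fam$pooled, n_reps = 100, seed = 1)
split_support(bs, fam$truth$sequence_id[fam$truth$family == "vibrio"])
#> [1] 100
```

The bipartition separating the two families is present in 100 of 100
column-resampled replicates — the two CBM40 subtypes are distinct clades.

```r
s <- sim_itc(0.57, -40, cell_conc_uM = 115, syringe_conc_mM = 10)
fit_isotherm(s$titration)
#> binding_fit: Kd = 0.57 mM (c = 0.202), dH = -40 kJ/mol
#>   dG = -18.52 kJ/mol, -TdS = 21.48 kJ/mol at 298.15 K
```

A noiseless 19 × 2 µl titration (200 µl cell, 115 µM protein, 10 mM
ligand) generated at *K*d = 0.57 mM is refitted exactly with N = 1.0; the
derived thermodynamics show millimolar, enthalpy-driven binding with
unfavourable entropy (−TΔS > 0).

```r
std <- sim_std(list(H7 = c(a = 2, b = 0.5), H3ax = c(a = 1.5, b = 0.4),
                    NAc = c(a = 3, b = 0.8)))
epitope_map(std$data)[, c("proton", "initial_slope", "normalized_pct", "bin")]
#>   proton initial_slope normalized_pct     bin
#> 1   H3ax           0.6             60     red
#> 2     H7           1.0            100     red
#> 3    NAc           2.4            240 over100
```

Initial slopes *a·b* normalised to H7 = 100% give the binding epitope;
bins follow the display convention blue 0–24%, yellow 25–50%,
red 51–100%, with a separate class above 100%.

A thin command-line wrapper over the same functions ships at
`inst/cli/sbs.R` (`Rscript sbs.R hmm build ...`, `... hmm scan`,
`... tree bootstrap`, `... std epitope`, `... itc fit`, `... assay rank`).

## Package layout

* `R/` — alignment and FASTA handling, profile HMMs (+ plain-text model
  serialization), survey/clustering, rate models and phylogeny, STD and
  ITC fitting, assay normalisations, synthetic-data generators.
* `src/` — the forward/Viterbi dynamic programming (Rcpp).
* `tests/testthat/` — unit and property tests per module, with
  independent oracles (exhaustive path enumeration, grid-search distance
  maximisation, additive-matrix reconstruction).
* `vignettes/sialobind-methods.Rmd` — models, parameters, design
  decisions and limitations.
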