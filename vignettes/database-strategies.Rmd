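---
title: "Benchmarking metaproteomic database strategies with synthetic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking metaproteomic database strategies with synthetic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprotdb)
library(data.table)
```

## The problem

In metaproteomics, tandem mass spectra of tryptic peptides are identified by
searching them against a protein sequence database, and the database decides
what can be found. A database missing the proteins of an organism present in
the sample cannot identify its spectra; a database bloated with irrelevant
proteins raises the score an identification must reach to survive
false-discovery-rate (FDR) control, and so silently discards marginal but
correct identifications. For microbial communities the choice is acute:
public repositories hold many genomes for well-studied taxa and none at all
for uncultivated ones, while shotgun metagenomic sequencing of the sample
itself recovers expressed genes - including those of unsequenced organisms -
but incompletely and with partially unresolved taxonomy.

`metaprotdb` implements, as a tested and reusable pipeline, the
database-construction strategies that arise from this trade-off and the
machinery to compare them:

* **synthetic community generation** with ground truth, so that every stage
  (database construction, search, FDR control, classification, benchmark
  statistics) can be validated end to end without any external downloads;
* **in silico tryptic digestion** and a weighted tryptic-peptide
  completeness metric for a database;
* **database builders** for the competing strategies - global,
  pooled/sample-matched public-sequence, reference-strain-only,
  pooled/sample-matched translated-shotgun, and hybrid;
* a **deterministic target-decoy search engine** with q-value computation,
  a two-step search, result condensation, and an import path for MS-GF+
  TSV results;
* **hierarchical PSM classification**, peptide-validity filtering, greedy
  unique-protein counting and taxonomic assignment;
* **benchmark metrics**: relative identification rates, paired Wilcoxon
  comparisons, presumptive false-positive rates, spectral-count functional
  differential abundance, replicate-overlap partitions, and the
  strains-versus-species augmentation experiment.

## The synthetic community model

`community_config()` fixes the study conditions. A universe of
`n_species` (default 16) bacterial species is generated, each with 2-4
strains of 12-20 proteins of 60-140 residues. Amino-acid composition is
uniform over the 20 standard residues, which puts lysine and arginine at 5%
each, so tryptic peptides always exist. Strains of one species share a
fraction of identical sequences with the type strain
(`strain_shared_fraction`, default 0.25): strain collections are redundant,
but two strains are far from identical.

A fraction of species (`fraction_uncultivated`, default 0.25) has **zero
public genomes**: their proteomes exist in the community but not in the
repository, emulating uncultivated taxa. Each sample contains a random
subset of species (`richness_range`, default 2-5 of 16) - communities
differ in membership across participants, which is what makes a *pooled*
database genuinely larger than a *sample-matched* one - with relative
abundances drawn from a symmetric Dirichlet
(`abundance_concentration = 0.3`, giving the skewed, one-or-few-dominant
profiles typical of low-diversity vaginal communities). Each present
species expresses the proteome of one randomly chosen strain.

The shotgun ORF catalog captures each expressed protein independently with
probability `capture^( (1/S) / a_i )`, where `a_i` is the species'
relative abundance and `S` the number of species present. The exponent
makes capture improve monotonically with abundance while the configured
`shotgun_capture_fraction` (default 0.97) is attained exactly at uniform
abundance; dominant organisms are assembled nearly completely (as deep
sequencing of a low-diversity community does) while rare organisms are
sampled fragmentarily. A fraction of captured ORFs
(`shotgun_unresolved_fraction = 0.15`) is taxonomically unresolved and
labeled `"Unknown"`.

Spectra are simulated from fully tryptic peptides (length 6-30, at most one
missed cleavage) of the expressed proteome plus host and contaminant
proteins, sampled proportionally to species abundance; the host and
contaminant signal fractions are explicit knobs (`host_abundance = 0.25`,
`contaminant_abundance = 0.05`) because the source study does not quantify
the host-to-bacterial PSM ratio. A configured fraction of source peptides
(`replicate_shared_fraction = 0.52`) appears in both injection replicates;
because every selected peptide is guaranteed at least one spectrum in each
replicate it is assigned to, the realised overlap matches the configured
value essentially exactly.

Each spectrum holds the neutral monoisotopic precursor mass and the singly
charged b/y fragment-mass multiset, degraded by two noise processes: each
true fragment is dropped with probability `drop_rate` (default 0.68) and
spurious uniform peaks are added at `spurious_rate` (default 3) per true
peak. These defaults are deliberately harsh: they emulate ion-trap MS/MS
spectra in which most peaks are unassignable chemical noise and only part
of the fragment ladder is observed. That calibration matters
scientifically, not just cosmetically - the database-size penalty on which
the pooled-versus-sample-matched comparisons turn exists only when a
substantial share of correct identifications sits near the significance
threshold. With clean spectra every true match is overwhelming, decoy
competition is irrelevant, and *no* database strategy can lose; a
simulation in that regime would be unable to express the phenomenon under
study.

### What the generator does not model

Peptide fragmentation physics (intensity patterns, neutral losses, charge
states >1), retention time, post-translational modifications, protein
sequence homology between unrelated species, and I/L-isobaric sequence
ambiguity beyond what random sequences produce. Conclusions from passing
tests therefore concern the *statistical* mechanics of database choice -
coverage versus significance-threshold cost under target-decoy FDR
control - not instrument-level behaviour on real spectra.

## Digestion and the completeness metric

`digest_protein()` cleaves C-terminally of K/R; cleavage before proline is
suppressed by default (the standard trypsin rule; the source workflow is
silent on it, and the setting is exposed). With zero missed cleavages and
no length filter, the fragments concatenate back to the protein - a
property the tests assert.

The completeness metric `weighted_tryptic_metric()` computes

$$W = \sum_{i=1}^{n} \ln(1 + G_i)\, A_i$$

where `G_i` is the number of **unique tryptic peptides longer than five
residues** in the public repository for species `i` (fully tryptic, zero
missed cleavages - the strictest digest, since the published description
of this metric does not mention missed cleavages) and `A_i` the species'
relative abundance in the sample. Species with no repository records
contribute `G_i = 0`. `W` measures how much searchable public sequence the
community actually present can draw on; the log damps the repository-size
explosion of well-sequenced taxa.

## The search engine

The scorer is intentionally lightweight and fully deterministic; it stands
in for a production engine (MS-GF+ and kin) whose *statistics*, not
chemistry, are the object of study here.

* **Candidates**: tryptic peptides with up to 2 missed cleavages, length
  6-30, plus semi-tryptic sub-peptides ("at least partially tryptic" - one
  terminus must conform). The candidate index is built once per database
  and reused across samples.
* **Precursor window**: ±0.05 Da with isotope errors −1 to +2 neutrons
  tolerated.
* **Score**: number of theoretical b/y fragment masses matching observed
  peaks within ±0.5 Da, each observed peak usable once (maximum matching of
  sorted lists; greedy two-pointer, optimal because all tolerance windows
  are equal-width). Implemented in C++ for throughput.
* **Spectral probability**: survival probability of at least the observed
  number of matches under a Poisson null with rate
  `n_peaks × 2·tol × n_fragments / mass_range` - a documented closed form
  playing the role of a spectral E-value. Smaller is better; at raw score
  0 it is exactly 1.
* **Decoys**: one per target record, the full protein sequence reversed,
  id prefixed `XXX_`. Reversal is standard, deterministic, and preserves
  length and composition.
* **Ties**: equal raw scores break by lower spectral probability, then
  lexicographically smallest peptide, then smallest protein id - searches
  are bit-reproducible.

`compute_qvalues()` ranks PSMs by score, estimates FDR at each rank as
`#decoys / max(1, #targets)` at-or-above, and monotonizes from the bottom;
decoy PSMs keep their q-values for audit. `two_step_search()` implements
the two-pass strategy: pass one records every matched target protein
regardless of significance; the subset database (hits plus the host and
contaminant core) is searched afresh with newly generated decoys - the
published description does not say whether decoys were regenerated for the
second pass, and regeneration is the choice here because the decoy set
should always mirror the searched target set. `condense_results()` keeps
the best PSM per spectrum across chunked searches, ordering by raw score
with the same tie-breaks (the alternative SpecEValue ordering differs only
on ties).

## Classification and inference rules

Classification is hierarchical and total: decoy ≻ contaminant ≻ human ≻
fungal ≻ trichomonas ≻ bacterial, with translated ORFs counting as
bacterial. Contaminant precedence sits directly below decoy because
contaminant spectra are discarded the same way. Significance filtering is
strict (`q < 0.01`); a PSM at exactly 0.01 is excluded.

Peptides enter downstream analysis if a supporting PSM has spectral
probability below 1e-15, or the matched protein has **at least two**
distinct significant peptides - "one of two unique peptides" is read as a
minimum evidence bar, not an exact count. Greedy unique-protein counting
visits non-redundant proteins (identical sequences collapsed) in
descending order of distinct supporting peptides (ties by ascending record
id - the published procedure leaves the order open, and this order is
deterministic and absorbs the most evidence first); a protein is counted
if, against the current peptide pool, it has two distinct peptides, a
peptide observed more than once, or a sub-threshold-probability peptide,
and its peptides then leave the pool. Validity and protein counting are
evaluated across samples jointly; per-sample metrics filter per sample.

## Benchmark harnesses and problem sizes

The package-level evaluation suites run the full pipeline at these sizes,
chosen as the desk-scale emulation of the study design:

* **FDR control**: 20 fixtures × 2,000 spectra, one community each,
  searched against its hybrid database; the fraction of accepted
  (`q < 0.01`) PSMs whose peptide differs from the ground truth must stay
  within the target-decoy guarantee (≤3% allows sampling slack over the
  nominal 1%).
* **Strategy ranking**: 10 fixtures × 6 samples × 800 spectra (six samples
  mirrors the subset used for the most expensive published comparison),
  with `dominant_uncultivated = TRUE` so each community is dominated by a
  taxon absent from the repository - the regime in which hybrid databases
  earn their keep. Expected ordering of mean significant bacterial PSMs:
  Hybrid ≥ 16S-sample-matched > 16S-pooled, and shotgun-sample-matched >
  shotgun-pooled, each as a one-sided sign test over fixtures.
* **Bloat**: one baseline sample-matched database, 2 samples × 1,500
  spectra, augmented with 20-100 genomes from a redundant strain pool or a
  species pool, 3 random databases per cell, one-step searches. The
  published augmentation experiment also used one-step searches, and the
  ranking harness follows suit: the compared quantity is a threshold
  effect that the second pass rescales but does not reorder, and one-step
  searches halve the compute. The two-step path is exercised by its own
  tests.
* **Coverage correlation**: 10 fixtures grading `fraction_uncultivated`
  from 0 to 0.6; Spearman correlation between `W` and the ratio of
  16S-sample-matched to hybrid significant bacterial PSMs must be
  positive - more public sequence, less benefit from metagenomic
  sequencing.

A worked single-sample example is in the README; `scripts/acceptance.R`
reruns all four suites from scratch and writes the resulting numbers as
JSON.

## Numerical choices and degenerate inputs

* All masses are rounded to 1e-6 Da at creation, so plain-text TSV
  round-trips are exact (`write_fixture()` / readers reproduce objects
  identically); floating-point columns in PSM TSVs are written with 17
  significant digits for the same reason.
* Abundance draws that collapse to all-zero gamma variates (possible at
  tiny concentration) fall back to a random unit mass; simplex sums are
  exact to 1e-9.
* A spectrum whose peaks are all dropped by noise retains one random true
  peak (fragment multisets must be nonempty).
* The `>0.1%` database-inclusion threshold is strict; abundance exactly at
  the cutoff excludes the taxon. Profile species without repository
  records are skipped with a warning, not an error - the study's BVAB2
  precedent.
* Sequence deduplication (hybrid building, protein-count collapsing) is
  exact string equality; no I/L folding.
* Percentages are reported at the precision used in the field: one decimal
  for replicate overlap, integer for dominance shares.
* Paired Wilcoxon and Mann-Whitney tests delegate to `stats::wilcox.test`
  (exact for small untied samples, normal approximation with continuity
  correction otherwise); both are verified against exact enumeration
  oracles in the tests. Functional differential abundance applies a raw
  `P < 0.01` cutoff per term, as published, with an optional
  Benjamini-Hochberg switch (`adjust = TRUE`) that is deliberately not
  the default; zero spectral counts enter the log2 transform as
  `log2(x + eps)` with `eps` half the smallest nonzero relative abundance.

## Known limitations

The contaminant set ships the 16 standard identifiers with synthetic
placeholder sequences; supply real sequences through `normalize_records()`
and a custom `core_set()` for work with real data. The search engine does
not model modifications, charge states or protein-level FDR, and its
absolute PSM yields are not comparable to a production engine's - only the
*relative* behaviour of database strategies is meaningful. Real
communities violate the generator's independence assumptions (horizontal
gene transfer, shared core genomes across genera), which will compress the
taxonomic exclusivity the synthetic fixtures display.
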