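---
title: "Genome mosaicism profiling and phyletic-pattern clustering with rhizomer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome mosaicism profiling and phyletic-pattern clustering with rhizomer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizomer)
```

## The model

A single-gene phylogeny assigns a genome one evolutionary history, but
genomes of microbes, organelles and giant viruses are mosaics: different
genes entered by vertical descent, lateral transfer from cohabiting
lineages, or de novo creation. The *rhizome* representation accepts this
and asks, gene by gene, where each sequence most plausibly comes from.

The procedure, per gene of a query proteome:

1. **Search.** The gene is aligned against every sequence of a
   taxonomically labeled reference collection (affine-gap Smith–Waterman,
   BLOSUM62, gap open 11 / extend 1 — the standard protein-search
   settings; all configurable).
2. **Self-exclusion.** Hits to the query organism itself — same taxon id,
   same genus, or optionally the whole origin group — are removed first.
   Without this step every gene trivially matches its own genome and the
   profile collapses to self-identity.
3. **Thresholds.** Surviving hits must reach ≥ 20 % identity, ≥ 30 % query
   coverage and e-value ≤ 0.001 (the *rhizome* bundle).
4. **Attribution.** If no hit survives, the gene is an **ORFan** — a
   sequence devoid of detectable homologs in the supplied database at the
   study thresholds. Otherwise its origin is the origin group (Bacteria,
   Archaea, DPANN, Asgard, Eukaryota, CPR, Viruses, …) of the single top
   surviving hit.

The per-genome tally of attributions is the **mosaicism profile**
(counts and percentages per origin label), and the gene → group incidence
is the **rhizome network** exported as GEXF for drawing. A companion
analysis clusters genomes by gene *content*: a 0/1 presence/absence matrix
against a reference family set, Euclidean distances, and agglomerative
clustering.

## Decisions worth knowing about

**Top-1 attribution.** A gene's origin is the group of its single best
surviving hit under a fully deterministic ordering — bitscore descending,
then e-value ascending, identity descending, and finally lexicographic
subject id — so reruns are bit-for-bit reproducible and database input
order is irrelevant.

**Self-exclusion rank.** The default excludes the query's genus (plus its
own taxon ids under every rank); `exclusion_rank` widens this to the whole
origin group or narrows it to listed taxon ids. Genus is the sensible
default when the reference collection contains close relatives of the
query.

**Threshold semantics.** All bounds are attained (identity ≥ 20, coverage
≥ 30, e-value ≤ 0.001; for marker retrieval alignment length ≥ 70). On
continuous alignment statistics the difference between strict and attained
bounds is immaterial, and attained bounds make boundary behavior explicit
and testable.

**Identity and coverage conventions.** Percent identity is computed over
all alignment columns *including gaps* (the blast-tab convention), so
built-in and externally ingested hits share semantics. Coverage is
measured on the query — the aligned query span over query length — which
makes ORFan calling a property of the gene rather than of whichever
subject it happens to hit.

**E-value model.** Built-in scores are converted to e-values with the
Karlin–Altschul formula `E = K·m·n·exp(−λS)` using the published gapped
BLOSUM62 constants (λ = 0.267, K = 0.041) and the actual residue count of
the supplied database as `n`; the bitscore is `(λS − ln K)/ln 2`. When
hits come from an external search tool, its e-values are used as-is and
this model is bypassed entirely. Note what a calibrated e-value implies:
at a threshold of 0.001, of order one chance hit per thousand searches is
*expected*. That is a property of the statistic, not a defect of any
implementation of it.

**X residues score zero** against everything, so stretches of unknown
residues neither reward nor penalize an alignment.

**Rounding.** Profile percentages round half-up to two decimals — the
convention of printed tables (506 of 935 → 54.12) — rather than R's
round-half-even. Combined shares are computed from summed counts *before*
rounding.

## The phyletic module

Family presence is a one-way best-hit call: family *f* is present in
genome *g* iff any gene of *g* aligns to any representative of *f* at
≥ 30 % identity and e-value ≤ 0.001 (no coverage bound — a conserved
domain inside a longer gene should count). "At least one ortholog → 1" is
taken literally; multi-copy families are not distinguished. Reciprocal
best-hit detection is deliberately out of scope of the default: it needs
both proteomes as search targets and changes little on presence/absence
calls at these thresholds.

On 0/1 rows the Euclidean distance is `sqrt(Hamming)`; the distance matrix
feeds `stats::hclust`. **Average linkage (UPGMA) is the default**: the
clustering tools conventionally used for phyletic patterns default to it,
and it is robust to the block-plus-noise structure these matrices have.
Complete, single, McQuitty and Ward linkages are available. Cutting the
tree into *k* clusters is scored against reference labels with the
adjusted Rand index — the right statistic when the claim under test is a
partition topology ("these genomes form five separate clades"), not merge
heights. For degenerate cuts where the ARI denominator vanishes (e.g. an
all-singleton partition scored against an all-singleton truth) the score
is defined as 1 when the partitions coincide and 0 otherwise.

Dendrograms serialize to Newick with leaves at the full merge height, so a
two-genome tree merging at height *h* reads `(A:h,B:h);` and branch
lengths can be read directly as heights.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage can be tested against planted
ground truth without downloading anything.

* `generate_reference_db()` draws random sequences over a uniform residue
  background, partitioned into labeled origin groups, one taxon and genus
  per group. Uniform background is the simplest null under which unrelated
  sequences carry no detectable homology; a composition table can be
  supplied for more realism.
* `mutate_sequence()` applies i.i.d. point substitutions at rate
  `1 − identity_target`, always to a different residue, so realized
  identity is binomial around the target. There are no indels by default:
  donor copies keep ~100 % coverage, making the identity threshold the
  only binding constraint in recovery experiments.
* `generate_mosaic_genome()` plants origins with exact, deterministic
  per-label counts (largest-remainder apportionment) and records the truth
  table.
* `generate_phyletic_cohort()` plants lifestyle-like structure: families
  are split into group-characteristic blocks, present with probability
  0.9 inside a genome's own block and 0.05 elsewhere.

Default sequence lengths are 150–250 residues, in the range of typical
microbial proteins. Length matters more than it first appears: short
random queries (~100 residues) can produce long, low-identity gapped
chance alignments whose *query coverage* clears 30 %, at roughly the rate
the e-value threshold implies. At realistic lengths such chance alignments
rarely reach the coverage bound as well, but they are not impossible —
which leads to the one subtlety of the generator:

**Planted ORFans are rejection-sampled.** An ORFan is *defined* relative
to the database and thresholds. A purely random sequence is not guaranteed
to satisfy that definition: once in roughly a thousand draws it aligns to
an unrelated database sequence with E < 0.001, and a truth table labeling
such a draw "ORFan" would simply be wrong. The generator therefore redraws
any ORFan candidate that has a passing hit. This keeps the planted truth
correct by construction and leaves the attribution pipeline untouched; the
residual chance-hit rate of *unchecked* random sequences is itself a
tested property (≥ 99 % of them fail the thresholds).

Every generator is a pure function of its spec, seed included, and
distinct generator functions scramble the seed with distinct stream
constants, so reusing one integer seed across generators cannot make their
random streams overlap.

What the generator does **not** emulate: real phylogenetic sequence
evolution (no substitution-rate matrices, no trees, no indel processes),
compositional bias, paralogy, or partial-gene annotation artifacts.
Passing recovery tests therefore demonstrate that the pipeline's logic is
correct under its own model — high-identity homology is found, unrelated
sequences are rejected, counts are conserved — not that attribution of
real genes against a real database is 100 % accurate. On real data
accuracy is bounded by database completeness and by the biology itself
(chimeric genes, fast-evolving families).

## Problem sizes and numerical choices

The validation suite runs, per seed: genome-scale recovery with 935 genes
(planted proportions 54/30/15/1 across Bacteria, CPR, ORFan, Archaea;
donor identity 0.9) against a 60-sequence three-group reference
collection; aligner-vs-oracle agreement on 200 random pairs of length
≤ 12 against a plain-R full-matrix dynamic program; and phyletic recovery
on 5 × 12 genomes over 200 families, cut at k = 5. These sizes keep a full
run in minutes on one core while leaving every statistic far from its
decision boundary.

Tie-breaking is deterministic everywhere: hit ordering ends in
lexicographic subject id; apportionment breaks remainder ties by label
input order; merges follow `stats::hclust`'s ordering. Degenerate inputs
(empty hit lists, all-zero family columns, duplicated genomes) are
preserved, not dropped: an all-zero column still contributes to distances,
and a duplicated genome adds exactly one zero-height merge under average
linkage.

## Known limitations

* The built-in aligner is exact Smith–Waterman without heuristic seeding;
  it is meant for desk-scale studies (thousands of genes × hundreds of
  reference sequences), not for searching comprehensive databases. For
  large searches, run an external tool and ingest its 12-column tabular
  output — the downstream analysis is identical.
* E-values for built-in hits use asymptotic Karlin–Altschul constants
  without finite-size (edge) corrections; for sequences of a few hundred
  residues they are accurate to a small factor, which is irrelevant at the
  0.001 threshold except exactly at the boundary.
* Top-1 attribution cannot orient a transfer: the best hit is a putative
  donor *or* acceptor.
* The bundled family set under `inst/extdata/` is a small synthetic
  stand-in for reference family collections (its filename says so); real
  analyses should supply their own representative FASTA + family table.
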