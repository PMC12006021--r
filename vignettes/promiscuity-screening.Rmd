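---
title: "Screening drug targets against microbiome metaproteomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug targets against microbiome metaproteomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprom)
```

## The question the pipeline answers

A drug designed against a human or pathogen protein may also bind
proteins of the commensal microbiota that resemble its target. `metaprom`
quantifies that resemblance at three levels — sequence, clinical
association, and binding-site structure — for drug-target sets screened
against per-biome metaproteome catalogues (gut, oral, vaginal), and ties
the result to drug side-effect profiles. This vignette documents the
model choices, parameters, numerical conventions and limitations.

## Sequence screening

### Alignment engine

The screen is built on an exact affine-gap pairwise aligner (Rcpp):
Needleman–Wunsch for global alignments, Smith–Waterman for local ones,
in the three-state (match / gap-in-query / gap-in-subject) Gotoh
formulation. A gap of length $g$ costs $\mathrm{open} + \mathrm{extend}\,(g-1)$;
defaults are BLOSUM62 with open 11 and extend 1. Correctness is tested
against exhaustive enumeration of every gapped alignment on all short
sequence pairs over a reduced alphabet, and against an independent
aligner (`Biostrings::pairwiseAlignment`) on longer random pairs.

Statistical significance of local scores uses Karlin–Altschul statistics,
$E = K m n e^{-\lambda S}$, with the standard gapped BLOSUM62/11/1
parameters $\lambda = 0.267$, $K = 0.041$; no on-the-fly estimation is
performed.

Numerical conventions, stated once and used everywhere:

* **Traceback ties** break deterministically diagonal > up > left, so
  identical inputs always yield identical alignments.
* **Percent identity** in global mode is identical columns over *all*
  alignment columns, terminal and internal gaps included; in local mode
  it is computed over the columns of the local alignment (the BLAST
  `pident` convention). The mode used is recorded with the results.
* **X** (unknown residue, including mapped selenocysteine/pyrrolysine)
  scores 0 against everything and never counts as identical.
* Empty local alignments (no positive-scoring segment) report score 0,
  zero columns and 0% identity.

### Two-stage screening and the identity mode

Published screens of this kind describe BLAST-style searching but report
global identity thresholds; the two are not the same operation. The
package resolves this by using both, explicitly: the local alignment and
its E-value (cutoff $10^{-6}$, configurable) discover candidate pairs
cheaply, and the reported identity of each candidate is then recomputed
with a full global alignment (`identity_mode = "global"`, the default;
`"local"` switches to the BLAST convention). Both modes are exposed
because the choice changes the identity denominator and therefore the
threshold semantics.

Thresholds are strict by definition: a hit requires identity *above* 30%
(a plant at exactly 30.0% is not called), and function concordance
requires identity *above* 50%. These are the conventional homology bands:
\>30% suggests shared ancestry and fold, 40–60% shared function. All
qualifying pairs are retained rather than best-hit-only, because the
downstream per-target counts are per-protein tallies; species-level
summaries deduplicate later. "Identical" matches require 100% identity
over the full length of both sequences.

## Taxonomic aggregation

Lineages are GTDB-style rank-prefixed strings
(`d__;p__;c__;o__;f__;g__;s__`); the species field keeps the full
binomial. Species comparison (for the pathogen catalog) normalises case
and whitespace and truncates to the binomial, because catalog names and
GTDB names differ in formatting. GTDB/NCBI phylum synonyms (e.g.
Firmicutes/Bacillota) are *not* merged by default — merging changes
composition tables silently — but an optional synonym map argument is
provided. Two counting conventions are emitted and labelled: per-protein
counts for phylum composition (stacked-bar view) and unique-species
counts for overlap and pathogenicity tables. Hits from MAGs without a
species rank are kept as an explicit `NA` class, never dropped; for the
`NA` class the organism unit is the MAG, since unnamed species cannot be
deduplicated by name.

## Clinical stage

Targets with at least one hit form the *microbiome-affecting* group; a
drug is affecting if **any** of its linked targets is affecting. The
any-rule is the least selective reading and is recorded in the output
metadata; how mixed drugs should be handled is genuinely open, and the
rule is deliberately a single documented decision rather than an option
that silently changes results.

"Normalized prevalence" of a symptom in a group is defined here as the
fraction of the group's drugs reporting it, $p_g = n_g / N_g$ — the
minimal definition that makes a percent change well-posed. The screen
statistic for shared symptoms is $100\,(p_a - p_n)/p_n$, computed in
integer-count form
$100\,(n_a N_n - n_n N_a)/(n_n N_a)$ so that boundary cases (a change of
exactly 10%) are exact in floating point and the strict \>10% filter
behaves as stated. No multiple-testing correction is applied — the
output is a descriptive screen, not a set of tests — but a seeded
permutation null (label shuffling) is available for calibration
(`n_perm`).

## Structural stage

The structure stage consumes already-posed complexes (PDB); docking,
homology modelling and protonation are upstream tools' work and out of
scope. Contacts are protein-heavy-atom/ligand-heavy-atom pairs within
10.5 Å, classified into the 10 unordered element-pair classes over
{C, N, O, X}; both the cutoff and the class scheme follow the
contact-based affinity-model convention for small-molecule complexes and
are configurable. Affinity is a pure linear form in the 10 counts. The
shipped coefficient file is a synthetic default chosen by the package
authors so the predictor runs out of the box; it is data, not code, and
should be replaced (`read_affinity_model()`) for quantitative use.

Pocket residues are those with a heavy atom within 5.0 Å of any ligand
heavy atom — a conventional interacting-residue threshold. Pocket
comparison globally aligns the reference chain sequence to a comparison
sequence and projects each pocket residue through the alignment
(identical / substituted / deleted); insertions are gap-in-reference
columns flanked by two pocket residues consecutive in the reference
chain. Projections from alignments under 15% identity are refused as
unreliable. When pocket residues span several chains, the chain carrying
the most pocket residues is compared.

## Synthetic data: what it emulates and what it does not

The generator produces every input format the pipeline reads, with a
serialized truth object, under a single seed (regeneration is
byte-identical):

* **Metaproteomes** — background proteins drawn i.i.d. from BLOSUM62
  background residue frequencies (the null consistent with the scoring
  scheme); planted homologs derived from targets by substitution-only
  mutation; MAG lineages assembled so the three-biome species sets
  realise a prescribed Venn structure.
* **Side effects** — per-drug Bernoulli draws with per-group symptom
  prevalences, linked to targets so the grouping stage reconstructs the
  planted groups.
* **Complexes** — toy C$\alpha$-plus-planted-atom geometry in which
  pocket membership and every contact count are exact by construction.

Substitution-only planting makes the planted identity exact; because a
random substitution set can occasionally admit a gapped global alignment
whose optimal identity deviates from the ungapped value, the generator
verifies each draw against its own contract (realized optimal-alignment
identity equals the ungapped planted identity under the default scheme)
and redraws otherwise, still deterministically under the seed. An indel
mode is deliberately absent from the defaults; stress-testing alignment
with indels would require recording realized rather than nominal
identities.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: phylogenetic correlation among
background sequences (real catalogues contain deep homologous families,
so real screens produce many more marginal hits), catalogue redundancy
and MAG quality artefacts, MedDRA coding noise and reporting bias in
side-effect tables, and real binding-site geometry. The synthetic tests
establish that the machinery is correct, not that any particular
biological effect size is recoverable from real catalogues.

Default study conditions (also used by the acceptance script): 20
targets (10 human, 10 pathogen, lengths 150–250), 200 background
proteins per biome plus a planted identity ladder spanning 20–100%
(including sub-threshold and exact-duplicate plants), a species pool
realising a 5-species three-way overlap, 100 drugs per clinical group
with one planted infection-symptom enrichment (prevalence 0.6 vs 0.2,
an expected +200% change), and one synthetic complex with a planted
pocket and contact profile. These sizes keep a full run in seconds while
leaving every stage's signal unambiguous; they are the package's
reference conditions, not tuning knobs.

## Degenerate inputs and edge behaviour

Empty FASTA files, duplicate ids, non-residue characters (reported with
position), unknown biomes, and annotation rows missing sequences are
errors; unparseable lineages are dropped *with a report* attached to the
result. An empty pathogen catalog is an error, an absent one skips only
the pathogenicity stage. A clinical group with zero drugs is an error;
division by zero in the percent change cannot occur for shared symptoms
by construction but is guarded regardless. Pipeline stages fail with the
stage name; reruns on identical inputs and configuration are
byte-identical (the run manifest records a configuration hash and input
checksums, never timestamps).

## Known limitations

* Desk-scale exact dynamic programming: no k-mer seeding or batching
  beyond an embarrassingly parallel map; screening millions of proteins
  would need a prefilter.
* Karlin–Altschul parameters are fixed constants for the default
  scheme; users supplying exotic matrices must supply matching
  parameters.
* The affinity model's default coefficients are synthetic placeholders.
* Sequence-only promiscuity evidence: conservation of a binding pocket
  is assessed only for complexes the user supplies.
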