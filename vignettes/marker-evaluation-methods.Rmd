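---
title: "Methods: evaluating DNA barcoding markers with barcodegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating DNA barcoding markers with barcodegap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

Closely related plant species — the duckweeds (*Lemnaceae*) are the
motivating case — are often impossible to tell apart morphologically,
and plastid barcode markers are the practical alternative. Whether a
marker works as a barcode hinges on one property: the distribution of
genetic distances *within* species must sit clearly below the
distribution of distances *between* species (the "barcoding gap"). This
package implements the complete evaluation chain used to rank candidate
markers on that property: pairwise distances, divergence summaries and
gap tests, threshold-based species assignment, and tree-based monophyly
scoring, together with a fully seeded sequence simulator so the whole
chain can be validated end to end without any sequence downloads.

The sampling unit throughout is the *ecotype*: a clonally maintained
accession of a species from a known origin. A species with two or more
sampled ecotypes contributes intraspecific distances and identification
queries; singleton species contribute references only.

## Distances

Two distance models are computed from aligned sequences:

* uncorrected p-distance, the proportion of differing sites among
  compared sites; and
* the Kimura 2-parameter (K2P) distance
  \(d = -\tfrac12 \ln\bigl[(1 - 2P - Q)\sqrt{1 - 2Q}\bigr]\),
  where \(P\) and \(Q\) are the transition (A↔G, C↔T) and transversion
  proportions.

Site handling follows the "suppressed indels" convention: for each
pair, columns where either sequence carries a gap, `N` or any IUPAC
ambiguity code are excluded (*pairwise* deletion, matching the default
of the standard distance software in this field; whether complete
deletion was ever intended is unknowable from the published methods, so
pairwise deletion is the package's documented choice — it retains far
more signal in ragged spacer alignments). A pair is only reported when
its post-deletion overlap reaches `min_overlap` — 300 bp by default,
230 bp for the short psbK-psbI spacer — otherwise the entry propagates
as a flagged missing value, never as a zero. Saturated K2P pairs
(non-positive logarithm argument) are likewise flagged rather than
clamped.

`k2p_distance()` reduces exactly to the Jukes–Cantor form when
transitions make up one third of differences, and `K2P >= p` always,
with equality only at distance zero; both properties are enforced in
the test suite.

## Divergence summaries and the barcoding gap

Intraspecific divergence is summarized per species first — the mean
over all conspecific pairs, one value per multi-ecotype species — so
heavily sampled species do not dominate the average. Interspecific
divergence defaults to pooling every between-species ecotype pair
(`all_pairs`); the `species_means` mode (mean per species pair, then
pooled) is retained as an option because published tables rarely state
which convention produced them. The reported spread is the population
standard deviation of the pooled value list; a standard-error switch is
available since "±" columns in the literature are frequently ambiguous.

The gap itself is assessed with two nonparametric tests of the pooled
intra vs inter lists: a two-sided Mann–Whitney U test and Mood's median
test (grand-median dichotomization; chi-square without continuity
correction, switching to Fisher's exact test whenever an expected cell
count drops below 5). Degenerate all-equal pools return p = 1 by
convention with a warning. Markers are ranked against each other with
two-sided Wilcoxon signed-rank tests on paired per-species(-pair)
values. No multiple-testing correction is applied across marker pairs,
deliberately mirroring standard practice in marker-evaluation studies.

## Similarity-based identification

Identification uses uncorrected p-distances (independently of the K2P
matrices used for trees) and a leave-one-out protocol: every ecotype of
a multi-ecotype species is queried in turn against all remaining
records, including singleton species, which can attract incorrect
calls. *Best match* assigns the species of the nearest reference;
minimal-distance ties across species (within 1e-12, i.e. exact ties at
machine precision) are *ambiguous*. *Best close match* additionally
requires the nearest reference to lie within a threshold, else the
query is a *no match*.

The threshold is "the value below which 95% of all intraspecific
pairwise distances are found", implemented literally: the smallest
observed value with at least the requested percentage of the pooled
intraspecific distances strictly below it, falling back to the maximum
for degenerate lists. Threshold eligibility uses `<=` at the boundary
(the reference implementation's behavior at the boundary is
undocumented; a `strict` switch flips it). With an infinite threshold,
best close match reduces exactly to best match — a tested identity.
Categories always partition the queries, and raising the threshold can
only reduce the number of no-match outcomes.

Combined two-marker barcodes are evaluated by per-taxon concatenation
over the taxa shared by both markers, with dropped taxa reported.

## Tree-based identification

UPGMA trees are built from K2P distances by average-linkage
agglomeration; the height of a new node is half the between-cluster
mean distance, so trees are ultrametric by construction. Ties in the
minimal pair (within 1e-12) are broken by the lexicographically
smallest pair of cluster indices, which makes the output deterministic
and order-invariant; the tie rule of the original desktop software is
unknown, so determinism was preferred over emulation. Missing entries
are a hard error naming the offending pairs — the pipeline subsets to
complete records and logs the drops.

Maximum parsimony uses the Fitch algorithm (gap/ambiguity states enter
as missing data, consistent with the indel suppression used for
distances) with the search protocol of random stepwise addition
followed by close-neighbor-interchange hill climbing. "CNI at search
level 1" is interpreted as nearest-neighbor-interchange rearrangements
around each internal branch — the under-specified procedure of the
legacy software is documented here as exactly that interpretation. Ten
random-addition replicates are the default; equally best topologies are
all retained. MP topologies are midpoint-rooted on parsimony
(ACCTRAN) branch lengths for monophyly counting, since parsimony trees
are otherwise unrooted and monophyly is a rooted notion.

Bootstrap supports resample alignment columns with replacement and
report, for each internal node of the full-data tree, the percentage of
replicates containing the same rooted clade. A species counts as
*recovered* when some node's descendant leaf set equals exactly its
ecotypes; singletons are excluded from the denominator.

## The synthetic data generator

`generate_dataset()` emulates the structure of a multi-species plastid
barcode study: a random coalescent species tree, a star of ecotypes
within each species, and a strand-symmetric two-parameter substitution
process whose transition/transversion ratio `kappa` defaults to 2, a
typical plastid value. The substitution process is deliberately the
K2P model itself, so distance estimation is exactly matched to the
generator and parameter-recovery tests are sharp rather than
confounded by model misspecification.

Scaling choices, fixed once as the study conditions:

* The species tree is rescaled so that the expected divergence between
  ecotypes of *different* species — tree path plus the two terminal
  ecotype branches — equals `inter_divergence`.
* Internal node heights are floored at `min_divergence/2`
  (default `min_divergence = 0.02`) because real interspecific plastid
  barcode divergences in this family span roughly 0.02–0.16;
  an unfloored coalescent occasionally produces sister species closer
  than the intraspecific noise, which no barcode could separate. The
  floor touches only the most recent splits, so the realized mean stays
  within about a percent of the target.
* Ecotypes form a star (branches of `intra_divergence/2`); real
  within-species structure is not modeled.

Indel-rich spacers are emulated by species-level deletion events drawn
from a shared master coordinate frame (Poisson number, geometric
lengths): all ecotypes of a species share one gap pattern, homology is
known by construction, and pairwise deletion provably recovers the
pre-indel distances exactly. Events are independent across species
rather than inherited along the tree — adequate for length-variation
regimes, not a model of indel evolution.

Two anomaly injectors mirror classic barcode case studies: a *hybrid*
adds a record whose sequence is copied verbatim from a donor species
(maternal plastid inheritance) under another species' label, and a
*mislabel* relabels an existing ecotype. Both must be flagged by the
classifier and must break the label species' monophyly; note that an
exact hybrid copy also drags zero-distance donor ecotypes into
cross-species ties, which the truth table's `copy_of` column makes
traceable.

The named presets fix the regimes used across the analysis scripts and
tests: `table2_atpF` (19 species, ecotype counts 8,8,7,6,6,5,5,5,4,4,4,
4,3,3,3,3,3,2,2 — 85 records — at 622 bp, inter 0.0633, intra 0.0008)
and `spacer_psbK` (576 bp, inter 0.1648, intra 0.0072, indels on),
plus `hybrid_case` and `mislabel_case`. All randomness flows from the
single mandatory seed; identical config and seed give byte-identical
output files.

What passing tests on these simulations do *not* show: robustness to
alignment error (the generator knows true homology; real spacers must
survive an aligner), to sequencing error, to rate heterogeneity across
sites or lineages, or to intraspecific structure. Results on real data
therefore depend on upstream alignment quality in a way the simulation
cannot probe.

## In-silico PCR and annealing temperature

`insilico_pcr()` matches the forward primer on the template and the
reverse primer as its reverse complement downstream (retrying with the
template reverse-complemented), requires both sites to be unique at the
allowed mismatch count, and returns the primer-inclusive product.
`optimal_annealing_temp()` implements the published combining rule
`Ta = 0.3·Tm(primer) + 0.7·Tm(product) − 14.9` (Tm values defined at
50 mM monovalent ion, 200 nM nucleic acid); melting temperatures
themselves are inputs, not computed, because the original values came
from proprietary software. End trimming of raw reads removes terminal
runs of non-ACGT characters, capped at 30 bp per end by default — the
published "~30 bp" leaves the exact rule open, so the cap is exposed as
a parameter.

## Problem sizes and runtime choices

The validation suite runs entirely on generated data: 85-record
alignments at ~600 bp for the regime-level checks (20 seeds), 6-taxon
alignments for the exhaustive parsimony oracles (all 105 unrooted
topologies), and up to 8-taxon matrices for the UPGMA oracle (200
random instances). Bootstrap defaults to 500 replicates in the API but
the scripted analyses use 100, which is ample for near-saturated
supports. The MP analysis script searches a 10-species subset of the
85-record dataset; the full search is feasible but slow in interpreted
R, and the subset exercises the identical code path.

## Known limitations

* Parsimony search is plain R; for hundreds of taxa a compiled
  implementation would be needed.
* Mood's median test uses the asymptotic chi-square unless expected
  counts are small; pooled distance lists are large, so this is benign.
* Distance pairs, not columns, are the unit of missingness: a record
  overlapping nothing silently leaves the UPGMA stage to the pipeline's
  subsetting logic, which logs but does not impute.
* The generator's species tree is a single coalescent draw; it does not
  model gene-tree/species-tree discordance, recombination, or
  heterotachy.
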