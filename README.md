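# barcodegap

Evaluation of candidate DNA barcoding markers for species-level
identification in closely related plant groups, with the duckweeds
(*Lemnaceae*) as the motivating system. Duckweed species are tiny,
morphologically reduced and often indistinguishable by eye; plastid
barcode markers (coding genes such as *rpoB*, *rpoC1*, *rbcL*, *matK*
and intergenic spacers such as *atpF–atpH*, *psbK–psbI*, *trnH–psbA*)
are the practical route to identifying an accession. This package is
for anyone who needs to decide, from per-marker multiple sequence
alignments of a multi-species, multi-ecotype collection, **which marker
identifies species best** — and to audit *why*.

## What it computes

A marker is a good barcode when within-species distances sit clearly
below between-species distances (the *barcoding gap*). The package
implements the full evaluation chain:

* **Distances** — pairwise uncorrected p-distance and Kimura
  2-parameter distance,
  `d = -1/2 · ln[(1 − 2P − Q) · sqrt(1 − 2Q)]`
  with transition proportion `P` and transversion proportion `Q`,
  under pairwise gap/ambiguity deletion ("suppressed indels") and a
  minimum-overlap rule (300 bp; 230 bp for *psbK–psbI*).
* **Divergence & gap statistics** — per-species intraspecific means
  (unbalanced-sampling safe), pooled interspecific distances, mean
  substitution counts, intra-vs-inter histograms, Mann–Whitney U and
  Mood's median gap tests, and Wilcoxon signed-rank marker rankings.
* **Identification** — *best match* and *best close match*
  (leave-one-out nearest-neighbor assignment with the threshold set at
  the 95th percentile of pooled intraspecific distances), for single
  markers and two-marker concatenations; outcomes are
  correct / ambiguous / incorrect / no match.
* **Trees** — UPGMA from K2P distances (deterministic tie-breaking,
  ultrametric by construction), Fitch-parsimony scoring with a
  random-addition + close-neighbor-interchange search, column-resampled
  bootstrap supports, Newick export, and species-monophyly scoring.
* **In-silico PCR utilities** — primer-site matching with mismatch
  tolerance, amplicon extraction, the published annealing-temperature
  rule `Ta = 0.3·Tm(primer) + 0.7·Tm(product) − 14.9`, and terminal
  trimming of ambiguous read ends.
* **A seeded simulator** — multi-species, multi-ecotype marker
  datasets with controlled inter/intra divergence, species-level
  indels, and hybrid / mislabeled accessions, so every stage above is
  testable without downloading a single sequence.

Real data enter as one aligned FASTA per marker plus a taxon table
(TSV: `accession  genus  species  ecotype  origin`); FASTA headers
follow `accession|Genus_species|ecotypeID|marker`.

## Worked example

Simulate the well-behaved barcode regime (19 species, 85 ecotypes,
622 bp, interspecific divergence 0.0633, intraspecific 0.0008) and run
the chain:

```r
library(barcodegap)

ds <- generate_dataset(sim_preset("table2_atpF", seed = 11))
dk <- pairwise_matrix(ds$alignment, "K2P")
dp <- pairwise_matrix(ds$alignment, "p")

divergence_summary(ds$alignment)[, c("mean_inter_k2p", "mean_intra_k2p")]
#> inter K2P 0.0589 +/- 0.0216, intra 0.0011 +/- 0.0010

barcoding_gap_tests(intraspecific_pairs(dp), interspecific_values(dp))
#>         mwu_p median_test_p
#> 1.859165e-112  2.923451e-39

evaluate_marker(ds$alignment)
#> <id_report> atpF-atpH: 85 queries, threshold 0.64%
#>   correct    85 (100.00%)
#>   ambiguous   0 (0.00%)
#>   incorrect   0 (0.00%)
#>   no_match    0 (0.00%)

monophyly_report(upgma(dk), ds$alignment$taxa)
#> <monophyly_report> UPGMA: 19/19 multi-ecotype species recovered
```

Read: on this draw the realized divergences bracket the configured
regime (single-seed means wander; across seeds they recover the
targets), the gap is decisive under both tests (p ≪ 0.0001), every one
of the 85 leave-one-out queries is assigned to its own species under
the 0.64% threshold, and all 19 multi-ecotype species come back as
clades on the UPGMA tree. A hybrid accession (plastid copied from a
donor species under another label) or a misidentified accession breaks
exactly this picture — see `analysis/05_anomalies.R`.

## Analysis workflow

Numbered drivers under `analysis/` narrate the full study on the
synthetic regimes and write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generates the four preset datasets (FASTA + truth tables) |
| `02_distances_divergence.R` | divergence summaries, gap histograms and tests, marker ranking |
| `03_identification.R` | best-close-match reports, single and combined markers |
| `04_trees.R` | UPGMA + bootstrap, MP search, monophyly scoring |
| `05_anomalies.R` | hybrid and mislabel case studies |
| `06_full_report.R` | `run_pipeline()` end-to-end, rendering the four-table report bundle |

Run any of them from the repository root with `Rscript analysis/<script>`.

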