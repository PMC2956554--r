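test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_preset("table2_atpF", seed = 101)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$alignment$seqs, d2$alignment$seqs)
  expect_identical(d1$truth, d2$truth)
  expect_equal(ape::write.tree(d1$species_tree),
               ape::write.tree(d2$species_tree))

  # byte-identical files
  dir <- withr::local_tempdir()
  p1 <- write_dataset(d1, file.path(dir, "a"))
  p2 <- write_dataset(d2, file.path(dir, "b"))
  expect_identical(readLines(p1$fasta), readLines(p2$fasta))
  expect_identical(readLines(p1$truth), readLines(p2$truth))

  t1 <- simulate_species_tree(8, 0.06, seed = 9)
  t2 <- simulate_species_tree(8, 0.06, seed = 9)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("species tree hits the target mean divergence and the floor", {
  set.seed(102)
  means <- replicate(100, {
    tr <- simulate_species_tree(10, 0.0633, min_divergence = 0)
    coph <- ape::cophenetic.phylo(tr)
    mean(coph[upper.tri(coph)])
  })
  expect_equal(mean(means), 0.0633, tolerance = 1e-9)

  # min_divergence floors every tip pair
  for (s in 1:10) {
    tr <- simulate_species_tree(12, 0.0633, seed = s, min_divergence = 0.02)
    coph <- ape::cophenetic.phylo(tr)
    expect_gte(min(coph[upper.tri(coph)]), 0.02 - 1e-12)
  }

  expect_equal(simulate_species_tree(2, 0.05, seed = 1)$Nnode, 1L)
})

test_that("branch evolution honors branch length and kappa", {
  cfg <- small_config(seed = 103)
  tr <- ape::read.tree(text = "(sp01:0,sp02:0);")
  s <- evolve_sequences(tr, sim_config(n_species = 2L,
                                       ecotypes_per_species = 1L,
                                       marker_length = 500L,
                                       inter_divergence = 0.05,
                                       intra_divergence = 0, seed = 103))
  # zero-length branches: children identical to root and to each other
  expect_identical(s$species_states[1, ], s$species_states[2, ])

  # near-infinite kappa: transversions vanish
  set.seed(104)
  cfg_ts <- sim_config(n_species = 2L, ecotypes_per_species = 1L,
                       marker_length = 20000L, inter_divergence = 0.1,
                       intra_divergence = 0, kappa = 1e9, seed = 104)
  tr2 <- ape::read.tree(text = "(sp01:0.05,sp02:0.05);")
  s2 <- evolve_sequences(tr2, cfg_ts)
  x <- paste(c("A", "C", "G", "T")[s2$states[1, ]], collapse = "")
  y <- paste(c("A", "C", "G", "T")[s2$states[2, ]], collapse = "")
  cnt <- classify_site_pairs(x, y)
  expect_equal(cnt$n_transversions, 0L)
  expect_gt(cnt$n_transitions, 0L)

  # K2P estimate recovers the path length within 5% at length 600
  set.seed(105)
  ds <- sapply(1:40, function(i) {
    tr3 <- ape::read.tree(text = "(sp01:0.08,sp02:0.08);")
    s3 <- evolve_sequences(tr3, sim_config(n_species = 2L,
                                           ecotypes_per_species = 1L,
                                           marker_length = 600L,
                                           inter_divergence = 0.16,
                                           intra_divergence = 0,
                                           seed = 105 + i))
    xx <- paste(c("A", "C", "G", "T")[s3$states[1, ]], collapse = "")
    yy <- paste(c("A", "C", "G", "T")[s3$states[2, ]], collapse = "")
    k2p_distance(classify_site_pairs(xx, yy))
  })
  expect_equal(mean(ds), 0.16, tolerance = 0.05)
})

test_that("indels vary ungapped lengths and leave distances unchanged", {
  cfg0 <- small_config(seed = 106, n_species = 6L, ecotypes = 2L,
                       len = 500L, indel_rate = 0)
  ds0 <- generate_dataset(cfg0)
  expect_false(any(grepl("-", ds0$alignment$seqs, fixed = TRUE)))

  cfg1 <- small_config(seed = 106, n_species = 6L, ecotypes = 2L,
                       len = 500L, indel_rate = 0.004,
                       indel_length_geometric_p = 0.04)
  ds1 <- generate_dataset(cfg1)
  ungapped <- nchar(gsub("-", "", ds1$alignment$seqs, fixed = TRUE))
  expect_gt(max(ungapped) - min(ungapped), 0)
  # gap pattern shared within species
  gaps_of <- function(s) gregexpr("-", s, fixed = TRUE)[[1]]
  sp <- ds1$alignment$taxa$species
  for (s in unique(sp)) {
    idx <- which(sp == s)
    if (length(idx) < 2) next
    expect_identical(gaps_of(ds1$alignment$seqs[idx[1]]),
                     gaps_of(ds1$alignment$seqs[idx[2]]))
  }

  # same seed, same substitution history: pairwise-deleted distances on
  # the gapped alignment equal the pre-indel distances exactly
  d_gap <- pairwise_matrix(ds1$alignment, "p", min_overlap = 1L)$d
  d_clean <- pairwise_matrix(ds0$alignment, "p", min_overlap = 1L)$d
  sp_pairs <- outer(sp, sp, "!=")
  # restrict to columns retained in both members of each pair
  mat0 <- do.call(rbind, strsplit(ds0$alignment$seqs, ""))
  mat1 <- do.call(rbind, strsplit(ds1$alignment$seqs, ""))
  for (i in 1:11) for (j in (i + 1):12) {
    keep <- mat1[i, ] != "-" & mat1[j, ] != "-"
    expect_equal(d_gap[i, j], mean(mat0[i, keep] != mat0[j, keep]))
  }
})

test_that("hybrids cluster with the donor and break label-species monophyly", {
  cfg <- sim_preset("hybrid_case", seed = 107)
  ds <- generate_dataset(cfg)
  expect_equal(sum(ds$truth$hybrid), 1L)
  hyb <- ds$truth[ds$truth$hybrid, ]
  expect_equal(hyb$species, "sp02")
  expect_equal(hyb$true_species, "sp01")

  # identical to its donor source sequence
  src <- which(ds$alignment$taxa$accession == hyb$copy_of)
  hyb_row <- which(ds$alignment$taxa$accession == hyb$accession)
  expect_identical(ds$alignment$seqs[hyb_row], ds$alignment$seqs[src])

  # classifier calls the donor species: incorrect under its label
  rep <- evaluate_marker(ds$alignment)
  out <- rep$outcomes[rep$outcomes$accession == hyb$accession, ]
  expect_true(out$category %in% c("incorrect", "ambiguous"))
  if (out$category == "incorrect") expect_equal(out$predicted, "Sim sp01")

  # label species loses monophyly on the UPGMA tree; donor clade holds both
  dk <- pairwise_matrix(ds$alignment, "K2P")
  tr <- upgma(dk)
  mono <- monophyly_report(tr, ds$alignment$taxa)
  v <- mono$verdicts
  expect_false(v$monophyletic[v$species == "Sim sp02"])

  # no hybrids requested -> dataset untouched
  base <- generate_dataset(sim_preset("table2_atpF", seed = 107))
  expect_equal(nrow(base$truth), 85L)
  expect_false(any(base$truth$hybrid))
  expect_error(inject_hybrid(base, "nope", "sp01"), "unknown donor")
})

test_that("mislabeled accessions break the label species' monophyly", {
  ds <- generate_dataset(sim_preset("mislabel_case", seed = 108))
  expect_equal(sum(ds$truth$mislabel), 1L)
  mis <- ds$truth[ds$truth$mislabel, ]
  expect_equal(mis$species, "sp02")
  expect_equal(mis$true_species, "sp01")

  dk <- pairwise_matrix(ds$alignment, "K2P")
  mono <- monophyly_report(upgma(dk), ds$alignment$taxa)
  v <- mono$verdicts
  expect_false(v$monophyletic[v$species == "Sim sp02"])

  rep <- evaluate_marker(ds$alignment)
  out <- rep$outcomes[rep$outcomes$accession == mis$accession, ]
  expect_true(out$category %in% c("incorrect", "ambiguous"))
})

test_that("truth flags predict exactly the classifier's failing queries", {
  for (s in c(109, 110)) {
    ds <- generate_dataset(sim_preset("hybrid_case", seed = s))
    rep <- evaluate_marker(ds$alignment)
    bad <- rep$outcomes$accession[rep$outcomes$category != "correct"]
    # every flagged record fails ...
    flagged <- ds$truth$accession[ds$truth$hybrid | ds$truth$mislabel]
    expect_true(all(flagged %in% bad))
    # ... and any additional failure is a donor-species ecotype whose
    # nearest-reference set is tied with the wrong-labeled hybrid copy
    dp <- pairwise_matrix(ds$alignment, "p")
    for (acc in setdiff(bad, flagged)) {
      i <- which(ds$truth$accession == acc)
      expect_equal(ds$truth$true_species[i], "sp01")
      drow <- dp$d[acc, ]
      drow <- drow[names(drow) != acc]
      expect_equal(drow[[flagged[1L]]], min(drow, na.rm = TRUE))
    }
  }
})

test_that("a gapless regime with intra = inter gives no barcoding gap", {
  insignificant <- vapply(1:5, function(s) {
    cfg <- sim_config(n_species = 8L, ecotypes_per_species = 3L,
                      marker_length = 500L, inter_divergence = 0.03,
                      intra_divergence = 0.03, min_divergence = 0,
                      seed = 200 + s)
    ds <- generate_dataset(cfg)
    dp <- pairwise_matrix(ds$alignment, "p", min_overlap = 1L)
    gt <- barcoding_gap_tests(intraspecific_pairs(dp),
                              interspecific_values(dp))
    gt$mwu_p >= 1e-4
  }, TRUE)
  expect_gte(sum(insignificant), 4L)
})
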