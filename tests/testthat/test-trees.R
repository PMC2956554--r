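test_that("UPGMA agglomeration reproduces hand-computed and oracle trees", {
  # 2 taxa at d = 0.2 -> root at height 0.1
  m2 <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  t2 <- upgma(m2)
  expect_s3_class(t2, "phylo")
  expect_equal(sort(t2$edge.length), c(0.1, 0.1))

  # 3 taxa: ((A,B),C) with node heights 0.1 and 0.3
  m3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(m3)
  coph <- ape::cophenetic.phylo(t3)
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], 0.6)
  depths <- ape::node.depth.edgelength(t3)[1:3]
  expect_equal(unname(max(depths)), 0.3)
  expect_true(is_ultrametric(t3))

  # random matrices: cophenetic distances equal stats::hclust average link
  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.01, 1)
    d <- d + t(d)
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- ape::cophenetic.phylo(upgma(d))
    ref <- as.matrix(stats::cophenetic(stats::hclust(stats::as.dist(d),
                                                     "average")))
    expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
  }
})

test_that("UPGMA rejects missing entries and ignores input order", {
  d <- matrix(c(0, NA, 0.3, NA, 0, 0.4, 0.3, 0.4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(upgma(d), "A--B")

  set.seed(42)
  n <- 7
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(21, 0.01, 1)
  m <- m + t(m)
  dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
  perm <- sample(n)
  coph1 <- ape::cophenetic.phylo(upgma(m))
  coph2 <- ape::cophenetic.phylo(upgma(m[perm, perm]))
  expect_equal(coph2[rownames(coph1), colnames(coph1)], coph1,
               tolerance = 1e-12)
})

test_that("Fitch score equals exhaustive state enumeration", {
  # one site, ((A,B),(C,D)) with states A,A,G,G -> 1 change
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  aln1 <- marker_alignment("m", data.frame(accession = c("A", "B", "C", "D"),
                                           genus = "G", species = "s",
                                           ecotype = 1:4),
                           c("A", "A", "G", "G"))
  expect_equal(fitch_score(tr, aln1), 1L)

  # invariant alignment scores 0 on any topology
  aln0 <- marker_alignment("m", aln1$taxa, rep(strrep("ACGT", 5), 4))
  expect_equal(fitch_score(tr, aln0), 0L)

  # random 5-taxon data vs brute force, including gaps as missing
  set.seed(43)
  for (i in 1:10) {
    tr5 <- ape::rtree(5, br = NULL)
    seqs <- random_seqs(5, 12, gap_frac = 0.1)
    names(seqs) <- tr5$tip.label
    aln <- marker_alignment("m", data.frame(accession = tr5$tip.label,
                                            genus = "G", species = "s",
                                            ecotype = 1:5), seqs)
    expect_equal(fitch_score(tr5, aln), oracle_parsimony(tr5, seqs))
  }

  # cross-check against phangorn on a larger case
  ds <- generate_dataset(small_config(seed = 44, n_species = 4L,
                                      ecotypes = 2L, len = 300L))
  trr <- ape::rtree(8, br = NULL)
  trr$tip.label <- ds$alignment$taxa$accession
  chm <- do.call(rbind, strsplit(tolower(ds$alignment$seqs), ""))
  rownames(chm) <- ds$alignment$taxa$accession
  pd <- phangorn::phyDat(chm, type = "DNA")
  expect_equal(fitch_score(trr, ds$alignment),
               phangorn::parsimony(trr, pd))

  expect_error(fitch_score(ape::read.tree(text = "((A,B),(C,X));"), aln1),
               "absent")
})

test_that("MP search attains the exhaustive optimum on strong 6-taxon signal", {
  set.seed(45)
  all6 <- phangorn::allTrees(6, tip.label = paste0("t", 1:6))
  hits <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    true <- ape::rtree(6, br = NULL)
    true$tip.label <- paste0("t", 1:6)
    true$edge.length <- rep(0.08, nrow(true$edge))
    cfg <- sim_config(n_species = 6L, ecotypes_per_species = 1L,
                      marker_length = 300L, inter_divergence = 0.1,
                      intra_divergence = 0, seed = s)
    # evolve on the fixed known topology
    seqs <- evolve_sequences(true, cfg)
    letters4 <- c("A", "C", "G", "T")
    aln <- marker_alignment("m", data.frame(accession = paste0("t", 1:6),
                                            genus = "G",
                                            species = seqs$taxa$species,
                                            ecotype = 1:6),
                            vapply(seq_len(6), function(i)
                              paste(letters4[seqs$states[i, ]],
                                    collapse = ""), ""))
    res <- mp_search(aln, n_random_addition = 10L, seed = s)
    chm <- do.call(rbind, strsplit(tolower(aln$seqs), ""))
    rownames(chm) <- aln$taxa$accession
    pd <- phangorn::phyDat(chm, type = "DNA")
    opt <- min(phangorn::parsimony(all6, pd))
    if (res$score == opt) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("MP search is deterministic under a fixed seed", {
  ds <- generate_dataset(small_config(seed = 46, n_species = 6L,
                                      ecotypes = 1L, len = 300L))
  r1 <- mp_search(ds$alignment, seed = 7L)
  r2 <- mp_search(ds$alignment, seed = 7L)
  expect_equal(r1$score, r2$score)
  expect_equal(ape::write.tree(r1$trees[[1]]), ape::write.tree(r2$trees[[1]]))

  # MP score never exceeds the UPGMA topology's score on the same data
  dk <- pairwise_matrix(ds$alignment, "K2P", min_overlap = 1L)
  expect_lte(r1$score, fitch_score(upgma(dk), ds$alignment))
})

test_that("bootstrap supports saturate for well-separated clades", {
  base1 <- strrep("ACGTACGTAC", 40)
  # ~10% divergent partner: strong but unsaturated signal
  base2 <- paste0(strrep("ACGTACGTAT", 35), strrep("CCGTACGTAT", 5))
  aln <- tiny_alignment(c(base1, base1, base1, base2, base2, base2),
                        c("sp1", "sp1", "sp1", "sp2", "sp2", "sp2"))
  tr <- bootstrap_support(aln, "UPGMA", replicates = 30L, seed = 5L,
                          min_overlap = 1L)
  supp <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(supp[-1][!is.na(supp[-1])] == 100))

  tr1 <- bootstrap_support(aln, "UPGMA", replicates = 1L, seed = 6L,
                           min_overlap = 1L)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("monophyly counting requires exact leaf-set clades", {
  taxa <- data.frame(accession = c("a1", "a2", "b1", "b2"),
                     genus = "G", species = c("s1", "s1", "s2", "s2"),
                     ecotype = 1:4)
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  rep1 <- monophyly_report(good, taxa)
  expect_equal(rep1$n_monophyletic, 2L)
  expect_equal(rep1$n_multi_species, 2L)

  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rep2 <- monophyly_report(bad, taxa)
  expect_equal(rep2$n_monophyletic, 0L)

  # singletons excluded from the denominator
  taxa3 <- rbind(taxa, data.frame(accession = "c1", genus = "G",
                                  species = "s3", ecotype = 5))
  t3 <- ape::read.tree(text = "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,c1:3);")
  rep3 <- monophyly_report(t3, taxa3)
  expect_equal(rep3$n_multi_species, 2L)
  expect_equal(rep3$n_monophyletic, 2L)
  expect_error(monophyly_report(ape::unroot(t3), taxa3), "rooted")
})

test_that("Newick output round-trips topology, lengths and supports", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  expect_equal(write_newick(tr), "(A:0.1,B:0.1);")

  ds <- generate_dataset(small_config(seed = 47, n_species = 4L,
                                      ecotypes = 2L, len = 400L))
  tr2 <- bootstrap_support(ds$alignment, "UPGMA", replicates = 10L,
                           seed = 3L, min_overlap = 1L)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.nwk")
  write_newick(tr2, p)
  back <- ape::read.tree(p)
  expect_equal(sort(back$tip.label), sort(tr2$tip.label))
  expect_equal(ape::cophenetic.phylo(back)[tr2$tip.label, tr2$tip.label],
               ape::cophenetic.phylo(tr2)[tr2$tip.label, tr2$tip.label],
               tolerance = 1e-9)
  expect_setequal(setdiff(back$node.label, ""),
                  setdiff(tr2$node.label, ""))
})
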