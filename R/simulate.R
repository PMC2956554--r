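#' Simulation configuration for synthetic marker datasets
#'
#' Defines the study conditions of a synthetic multi-species,
#' multi-ecotype marker dataset: a coalescent species tree scaled to a
#' target mean interspecific divergence, a star of ecotypes within each
#' species at a target intraspecific divergence, a two-parameter
#' (transition/transversion) substitution process, optional
#' species-level indels for spacer-like markers, and optional hybrid
#' and mislabeled accessions.
#'
#' @param n_species Number of species (>= 2).
#' @param ecotypes_per_species Single integer or per-species vector
#'   (1-8 typical).
#' @param marker_length Ungapped ancestral sequence length (bp).
#' @param inter_divergence Target mean pairwise K2P divergence between
#'   ecotypes of different species (expected substitutions per site
#'   along the full record-pair path, terminal ecotype branches
#'   included).
#' @param intra_divergence Target pairwise divergence between
#'   conspecific ecotypes.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process.
#' @param indel_rate Expected species-level deletion events per
#'   ancestral site (0 = length-conserved coding marker).
#' @param indel_length_geometric_p Geometric success probability for
#'   deletion lengths (mean length `1/p`).
#' @param n_hybrids Number of hybrid accessions to add (plastid copied
#'   from a donor species, labeled as another existing species).
#' @param n_mislabels Number of existing accessions to relabel with the
#'   wrong species.
#' @param min_divergence Floor on between-species divergence (keeps
#'   sister species separable, matching the ~0.02-0.16 interspecific
#'   range of plastid barcode data).
#' @param marker Marker name attached to the alignment.
#' @param seed Mandatory RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species = 19L,
                       ecotypes_per_species = 4L,
                       marker_length = 622L,
                       inter_divergence = 0.0633,
                       intra_divergence = 0.0008,
                       kappa = 2,
                       indel_rate = 0,
                       indel_length_geometric_p = 0.05,
                       n_hybrids = 0L,
                       n_mislabels = 0L,
                       min_divergence = 0.02,
                       marker = "sim-marker",
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(ecotypes_per_species) == 1L)
    ecotypes_per_species <- rep(as.integer(ecotypes_per_species), n_species)
  stopifnot(n_species >= 2L, length(ecotypes_per_species) == n_species,
            all(ecotypes_per_species >= 1L), marker_length >= 1L,
            inter_divergence >= 0, intra_divergence >= 0,
            kappa > 0, indel_rate >= 0,
            indel_length_geometric_p > 0, indel_length_geometric_p <= 1)
  structure(list(n_species = as.integer(n_species),
                 ecotypes_per_species = ecotypes_per_species,
                 marker_length = as.integer(marker_length),
                 inter_divergence = inter_divergence,
                 intra_divergence = intra_divergence,
                 kappa = kappa, indel_rate = indel_rate,
                 indel_length_geometric_p = indel_length_geometric_p,
                 n_hybrids = as.integer(n_hybrids),
                 n_mislabels = as.integer(n_mislabels),
                 min_divergence = min_divergence,
                 marker = marker, seed = as.integer(seed)),
            class = "sim_config")
}

#' Named preset configurations
#'
#' * `table2_atpF` — 19 species with (8,8,7,6,6,5,5,5,4,4,4,4,3,3,3,3,
#'   3,2,2) ecotypes (85 accessions), 622 bp, interspecific divergence
#'   0.0633, intraspecific 0.0008, no indels: the regime of a
#'   well-behaved, length-conserved spacer such as atpF-atpH.
#' * `spacer_psbK` — same sampling, 576 bp, inter 0.1648, intra 0.0072,
#'   species-level indels: an indel-rich, highly divergent spacer.
#' * `hybrid_case` — `table2_atpF` plus one hybrid accession (sequence
#'   copied from sp01, labeled sp02).
#' * `mislabel_case` — `table2_atpF` plus one accession of sp01
#'   relabeled as sp02.
#'
#' @param name Preset name.
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("table2_atpF", "spacer_psbK",
                                "hybrid_case", "mislabel_case"), seed) {
  name <- match.arg(name)
  eco <- c(8L, 8L, 7L, 6L, 6L, 5L, 5L, 5L, 4L, 4L, 4L, 4L,
           3L, 3L, 3L, 3L, 3L, 2L, 2L)
  base <- function(...) sim_config(n_species = 19L,
                                   ecotypes_per_species = eco,
                                   seed = seed, ...)
  switch(name,
    table2_atpF = base(marker = "atpF-atpH"),
    spacer_psbK = base(marker = "psbK-psbI", marker_length = 576L,
                       inter_divergence = 0.1648, intra_divergence = 0.0072,
                       indel_rate = 0.004, indel_length_geometric_p = 0.04),
    hybrid_case = base(marker = "atpF-atpH", n_hybrids = 1L),
    mislabel_case = base(marker = "atpF-atpH", n_mislabels = 1L)
  )
}

#' Simulate a species tree scaled to a target mean divergence
#'
#' A random coalescent tree is rescaled so that the mean tip-pair path
#' length equals `depth`, then internal node heights are floored at
#' `min_divergence / 2` so that no species pair falls below the
#' minimum interspecific divergence of the emulated data.
#'
#' @param n_species Number of tips.
#' @param depth Target mean tip-pair path length (expected
#'   substitutions per site).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @param min_divergence Minimum tip-pair path length.
#' @return Rooted ultrametric `phylo` with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(n_species, depth, seed = NULL,
                                  min_divergence = 0) {
  stopifnot(n_species >= 2L)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n_species, tip.label = sprintf("sp%02d", seq_len(n_species)))
  coph <- ape::cophenetic.phylo(tr)
  scale <- depth / mean(coph[upper.tri(coph)])
  tr$edge.length <- tr$edge.length * scale
  if (min_divergence > 0) {
    n <- n_species
    heights <- numeric(n + tr$Nnode)
    heights[(n + 1L):(n + tr$Nnode)] <-
      pmax(ape::branching.times(tr), min_divergence / 2)
    tr$edge.length <- heights[tr$edge[, 1L]] - heights[tr$edge[, 2L]]
  }
  tr
}

# K80 transition probabilities at branch length d (expected
# substitutions per site), rates normalized to alpha + 2*beta = 1.
k80_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1   # each of the two transversion targets
  c(ts = p_ts, tv = p_tv)
}

# Evolve an integer-coded sequence (A=1,C=2,G=3,T=4) along one branch.
evolve_branch <- function(x, d, kappa) {
  if (d <= 0) return(x)
  pr <- k80_probs(d, kappa)
  u <- stats::runif(length(x))
  ts_map <- c(3L, 4L, 1L, 2L)    # A<->G, C<->T
  tv1_map <- c(2L, 1L, 2L, 1L)   # one pyrimidine/purine partner
  tv2_map <- c(4L, 3L, 4L, 3L)   # the other
  out <- x
  is_ts <- u < pr[["ts"]]
  is_tv <- !is_ts & u < pr[["ts"]] + 2 * pr[["tv"]]
  out[is_ts] <- ts_map[x[is_ts]]
  pick <- stats::runif(sum(is_tv)) < 0.5
  out[is_tv] <- ifelse(pick, tv1_map[x[is_tv]], tv2_map[x[is_tv]])
  out
}

#' Evolve marker sequences for every ecotype on a species tree
#'
#' The root sequence is uniform random; substitutions accumulate along
#' the species-tree branches under the two-parameter process with
#' transition/transversion ratio `kappa`. Within each species the
#' ecotypes form a star: each diverges independently from the species
#' tip by a branch of `intra_divergence / 2`, so conspecific pairs are
#' separated by `intra_divergence` in expectation.
#'
#' @param tree Species tree from [simulate_species_tree()].
#' @param config A [sim_config()].
#' @return List with `taxa` (accession/genus/species/ecotype data
#'   frame), `states` (integer matrix, rows = ecotype records),
#'   `species_states`, and `branch` (per-record terminal branch
#'   length).
#' @export
evolve_sequences <- function(tree, config) {
  L <- config$marker_length
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  states <- matrix(0L, n_node, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE)
  edges <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    p <- edges$edge[e, 1L]; ch <- edges$edge[e, 2L]
    states[ch, ] <- evolve_branch(states[p, ], edges$edge.length[e],
                                  config$kappa)
  }
  species_states <- states[seq_len(n_tip), , drop = FALSE]
  rownames(species_states) <- tree$tip.label
  eco_counts <- config$ecotypes_per_species
  total <- sum(eco_counts)
  rec_states <- matrix(0L, total, L)
  taxa <- data.frame(accession = character(total), genus = "Sim",
                     species = character(total), ecotype = character(total),
                     stringsAsFactors = FALSE)
  half <- config$intra_divergence / 2
  k <- 0L
  # iterate species in label order so that record -> species assignment
  # is identical across markers simulated on different random trees
  for (s in seq_len(n_tip)) {
    sp <- sort(tree$tip.label)[s]
    i <- match(sp, tree$tip.label)
    for (j in seq_len(eco_counts[s])) {
      k <- k + 1L
      rec_states[k, ] <- evolve_branch(species_states[i, ], half,
                                       config$kappa)
      taxa$accession[k] <- sprintf("SIM%04d", k)
      taxa$species[k] <- sp
      taxa$ecotype[k] <- as.character(7000L + k)
    }
  }
  list(taxa = taxa, states = rec_states, species_states = species_states,
       branch = rep(half, total))
}

decode_states <- function(states, gaps = NULL) {
  letters4 <- c("A", "C", "G", "T")
  apply_row <- function(i) {
    ch <- letters4[states[i, ]]
    if (!is.null(gaps)) ch[gaps[i, ]] <- "-"
    paste(ch, collapse = "")
  }
  vapply(seq_len(nrow(states)), apply_row, "")
}

#' Place species-level indels and emit the gapped alignment
#'
#' Deletion events are drawn per species (`Poisson(indel_rate * L)`
#' events, geometric lengths) from a shared master coordinate frame, so
#' all ecotypes of a species share its gap pattern and true homology is
#' known by construction — the gapped alignment needs no aligner.
#' Pairwise deletion on the result recovers the pre-indel distances
#' exactly.
#'
#' @param seqs Output of [evolve_sequences()].
#' @param config A [sim_config()].
#' @return A [marker_alignment()]; attribute `species_gap_mask` is the
#'   species-by-column logical deletion mask.
#' @export
inject_indels <- function(seqs, config) {
  L <- config$marker_length
  sp_names <- rownames(seqs$species_states)
  mask <- matrix(FALSE, length(sp_names), L, dimnames = list(sp_names, NULL))
  if (config$indel_rate > 0) {
    for (i in seq_along(sp_names)) {
      n_events <- stats::rpois(1L, config$indel_rate * L)
      if (n_events == 0L) next
      starts <- sample.int(L, n_events, replace = TRUE)
      lens <- stats::rgeom(n_events, config$indel_length_geometric_p) + 1L
      for (e in seq_len(n_events))
        mask[i, starts[e]:min(L, starts[e] + lens[e] - 1L)] <- TRUE
    }
  }
  rec_gaps <- mask[seqs$taxa$species, , drop = FALSE]
  aln <- marker_alignment(config$marker, seqs$taxa,
                          decode_states(seqs$states, rec_gaps))
  attr(aln, "species_gap_mask") <- mask
  aln
}

#' Add a hybrid accession (plastid capture)
#'
#' Appends a record whose sequence is copied from the first ecotype of
#' `donor_species` but which is labeled `label_species`, emulating a
#' maternally inherited plastid in a hybrid: the new record clusters
#' with the donor and breaks the label species' monophyly.
#'
#' @param dataset A `sim_dataset` from [generate_dataset()].
#' @param donor_species,label_species Species labels present in the
#'   dataset.
#' @return The modified `sim_dataset`; the truth table flags the new
#'   record with `hybrid = TRUE` and records the donor.
#' @export
inject_hybrid <- function(dataset, donor_species, label_species) {
  truth <- dataset$truth
  if (!donor_species %in% truth$species)
    stop("unknown donor species: ", donor_species)
  if (!label_species %in% truth$species)
    stop("unknown label species: ", label_species)
  src <- which(truth$species == donor_species & !truth$hybrid)[1L]
  aln <- dataset$alignment
  acc <- sprintf("HYB%03d", sum(truth$hybrid) + 1L)
  new_taxa <- rbind(aln$taxa,
                    data.frame(accession = acc, genus = aln$taxa$genus[src],
                               species = label_species,
                               ecotype = as.character(9000L + nrow(truth)),
                               stringsAsFactors = FALSE))
  dataset$alignment <- marker_alignment(aln$marker, new_taxa,
                                        c(aln$seqs, aln$seqs[src]))
  dataset$truth <- rbind(truth,
    data.frame(accession = acc, genus = aln$taxa$genus[src],
               species = label_species,
               ecotype = as.character(9000L + nrow(truth)),
               true_species = truth$true_species[src],
               hybrid = TRUE, mislabel = FALSE,
               copy_of = truth$accession[src], stringsAsFactors = FALSE))
  dataset
}

#' Relabel an accession with the wrong species (misidentification)
#'
#' The first unflagged ecotype of `from_species` keeps its sequence but
#' is relabeled `to_species`, emulating a morphologically misidentified
#' accession that consistently clusters away from its nominal species.
#'
#' @param dataset A `sim_dataset`.
#' @param from_species True species whose record is relabeled.
#' @param to_species Species label assigned to the record.
#' @return The modified `sim_dataset` with `mislabel = TRUE` and
#'   `true_species` recorded in the truth table.
#' @export
inject_mislabel <- function(dataset, from_species, to_species) {
  truth <- dataset$truth
  if (!from_species %in% truth$species)
    stop("unknown source species: ", from_species)
  if (!to_species %in% truth$species)
    stop("unknown target species: ", to_species)
  idx <- which(truth$species == from_species & !truth$hybrid &
                 !truth$mislabel)
  if (length(idx) < 2L)
    stop("source species needs >= 2 clean ecotypes to spare one")
  idx <- idx[1L]
  dataset$truth$species[idx] <- to_species
  dataset$truth$mislabel[idx] <- TRUE
  dataset$alignment$taxa$species[idx] <- to_species
  dataset
}

#' Generate a complete labeled synthetic marker dataset
#'
#' Orchestrates [simulate_species_tree()], [evolve_sequences()],
#' [inject_indels()] and the hybrid/mislabel injectors under a single
#' seed. Hybrid `k` copies from `sp(2k-1)` and is labeled `sp(2k)`;
#' mislabel `k` relabels an ecotype of `sp(2k-1)` as `sp(2k)` (after
#' any hybrids).
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_dataset`: `alignment`
#'   ([marker_alignment()]), `truth` (per-record labels and flags),
#'   `species_tree` (`phylo`), `expected_divergence` (record-level
#'   expected pairwise path lengths), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  # between-species record pairs traverse the species-tree path plus two
  # ecotype branches (intra_divergence total), so the tree is scaled to
  # the remainder for the record-level divergence to hit the target
  depth <- max(config$inter_divergence - config$intra_divergence, 0)
  tree <- simulate_species_tree(config$n_species, depth, seed = NULL,
                                min_divergence = config$min_divergence)
  seqs <- evolve_sequences(tree, config)
  aln <- inject_indels(seqs, config)
  truth <- cbind(seqs$taxa,
                 data.frame(true_species = seqs$taxa$species,
                            hybrid = FALSE, mislabel = FALSE,
                            copy_of = NA_character_,
                            stringsAsFactors = FALSE))
  dataset <- structure(list(alignment = aln, truth = truth,
                            species_tree = tree, config = config),
                       class = "sim_dataset")
  for (k in seq_len(config$n_hybrids))
    dataset <- inject_hybrid(dataset, sprintf("sp%02d", 2L * k - 1L),
                             sprintf("sp%02d", 2L * k))
  for (k in seq_len(config$n_mislabels))
    dataset <- inject_mislabel(dataset, sprintf("sp%02d", 2L * k - 1L),
                               sprintf("sp%02d", 2L * k))
  dataset$expected_divergence <- expected_divergence_matrix(dataset)
  dataset
}

# Expected pairwise path length between records under the generating
# model (species-tree path + terminal ecotype branches; sequence copies
# share their source's position).
expected_divergence_matrix <- function(dataset) {
  truth <- dataset$truth
  coph <- ape::cophenetic.phylo(dataset$species_tree)
  half <- dataset$config$intra_divergence / 2
  src <- ifelse(is.na(truth$copy_of), truth$accession, truth$copy_of)
  pos <- match(src, truth$accession)
  n <- nrow(truth)
  m <- matrix(0, n, n, dimnames = list(truth$accession, truth$accession))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (pos[i] == pos[j]) next
    sp_i <- truth$true_species[pos[i]]; sp_j <- truth$true_species[pos[j]]
    d <- if (sp_i == sp_j) 2 * half else coph[sp_i, sp_j] + 2 * half
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", x$config$marker, ": ", nrow(x$truth), " records, ",
      x$config$n_species, " species (seed ", x$config$seed, ")\n", sep = "")
  if (any(x$truth$hybrid)) cat("  hybrids: ",
                               sum(x$truth$hybrid), "\n", sep = "")
  if (any(x$truth$mislabel)) cat("  mislabels: ",
                                 sum(x$truth$mislabel), "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `<marker>.fasta` (aligned FASTA), `truth.tsv` (taxon table
#' with hybrid/mislabel flags; readable by [read_marker_fasta()] as a
#' taxon table) and `expected_divergence.tsv`.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(dataset$alignment$marker, ".fasta"))
  truth <- file.path(dir, "truth.tsv")
  ediv <- file.path(dir, "expected_divergence.tsv")
  write_marker_fasta(dataset$alignment, fasta)
  write_taxon_table(dataset$truth, truth)
  ut <- which(upper.tri(dataset$expected_divergence), arr.ind = TRUE)
  acc <- rownames(dataset$expected_divergence)
  utils::write.table(
    data.frame(taxon_i = acc[ut[, 1L]], taxon_j = acc[ut[, 2L]],
               expected_divergence = dataset$expected_divergence[ut]),
    ediv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, truth = truth,
                 expected_divergence = ediv))
}

#' Read or write a simulation configuration as JSON
#' @param config A [sim_config()] (for writing).
#' @param path JSON file.
#' @return `write_sim_config` returns `path` invisibly;
#'   `read_sim_config` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, x)
}
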