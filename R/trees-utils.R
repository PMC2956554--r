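# Rooted clades of a tree as canonical sorted-label keys (one per
# internal node, in node order n_tip+1, n_tip+2, ...).
clade_keys <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  vapply(parts, function(p) paste(sort(labs[p]), collapse = ","), "")
}

# Resample alignment columns with replacement.
resample_columns <- function(aln, idx = NULL) {
  L <- aln$alignment_length
  if (is.null(idx)) idx <- sample.int(L, L, replace = TRUE)
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  marker_alignment(aln$marker, aln$taxa,
                   apply(mat[, idx, drop = FALSE], 1L, paste, collapse = ""))
}

#' Bootstrap clade support for a distance or parsimony tree
#'
#' Alignment columns are resampled with replacement; each replicate is
#' rebuilt with the same method and the support of each internal node
#' of the original tree is the percentage of replicates containing the
#' same rooted clade.
#'
#' @param aln A [marker_alignment()].
#' @param builder `"UPGMA"` (K2P distances) or `"MP"`, or a function
#'   `aln -> phylo` for custom builders.
#' @param replicates Number of bootstrap replicates.
#' @param seed RNG seed.
#' @param min_overlap Minimum pairwise overlap for distance trees; use
#'   a smaller value than for full-length data since resampling
#'   changes per-pair overlap.
#' @param ... Extra arguments passed to the builder (e.g.
#'   `n_random_addition` for MP).
#' @return The tree built from the full alignment, with `node.label`
#'   set to bootstrap percentages (root label empty).
#' @export
bootstrap_support <- function(aln, builder = c("UPGMA", "MP"),
                              replicates = 500L, seed = 1L,
                              min_overlap = NULL, ...) {
  build <- if (is.function(builder)) builder else {
    builder <- match.arg(builder)
    if (builder == "UPGMA") {
      function(a) upgma(pairwise_matrix(a, "K2P", min_overlap))
    } else {
      function(a) {
        res <- mp_search(a, seed = sample.int(2^30, 1L), ...)
        root_mp_tree(res$trees[[1L]], a)
      }
    }
  }
  main <- build(aln)
  keys <- clade_keys(main)
  hits <- numeric(length(keys))
  used <- 0L
  set.seed(seed)
  for (r in seq_len(replicates)) {
    rep_aln <- resample_columns(aln)
    tr <- tryCatch(build(rep_aln), error = function(e) NULL)
    if (is.null(tr)) next
    used <- used + 1L
    hits <- hits + (keys %in% clade_keys(tr))
  }
  if (used == 0L) stop("all bootstrap replicates failed")
  if (used < replicates)
    warning(replicates - used, " bootstrap replicate(s) failed and were skipped")
  supp <- round(100 * hits / used, 1)
  lab <- as.character(supp)
  lab[1L] <- ""  # root clade is trivially present
  main$node.label <- lab
  attr(main, "bootstrap_replicates") <- used
  main
}

#' Species monophyly report for a rooted tree
#'
#' A species with two or more sampled ecotypes counts as recovered when
#' some node's descendant leaf set equals exactly that species'
#' ecotypes. Singleton species are excluded from the denominator.
#'
#' @param tree Rooted `phylo`; tip labels are accessions. If
#'   `node.label` holds bootstrap percentages, the mean support of
#'   recovered clades is reported.
#' @param taxa Data frame with `accession`, `genus`, `species`.
#' @param method Label stored in the report (e.g. `"UPGMA"`).
#' @return Object of class `monophyly_report`: `method`,
#'   `n_multi_species`, `n_monophyletic`, `mean_support`, and the
#'   per-species `verdicts` data frame.
#' @export
monophyly_report <- function(tree, taxa, method = "UPGMA") {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  sp <- paste(taxa$genus, taxa$species)
  names(sp) <- taxa$accession
  sp <- sp[tree$tip.label]
  if (anyNA(sp)) stop("tip labels missing from taxon table")
  keys <- clade_keys(tree)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  counts <- table(sp)
  multi <- names(counts[counts >= 2L])
  verdicts <- do.call(rbind, lapply(multi, function(s) {
    key <- paste(sort(tree$tip.label[sp == s]), collapse = ",")
    hit <- match(key, keys)
    data.frame(species = s, n_ecotypes = as.integer(counts[[s]]),
               monophyletic = !is.na(hit),
               support = if (!is.na(hit) && length(supports))
                 supports[hit] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(verdicts))
    verdicts <- data.frame(species = character(0), n_ecotypes = integer(0),
                           monophyletic = logical(0), support = numeric(0))
  mean_support <- if (nrow(verdicts) && any(verdicts$monophyletic))
    mean(verdicts$support[verdicts$monophyletic], na.rm = TRUE) else NA_real_
  structure(list(method = method,
                 n_multi_species = length(multi),
                 n_monophyletic = sum(verdicts$monophyletic),
                 mean_support = mean_support,
                 verdicts = verdicts),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat("<monophyly_report> ", x$method, ": ", x$n_monophyletic, "/",
      x$n_multi_species, " multi-ecotype species recovered",
      if (!is.na(x$mean_support))
        sprintf(" (mean support %.1f)", x$mean_support) else "",
      "\n", sep = "")
  invisible(x)
}

#' Write a tree in Newick format
#'
#' Branch lengths are included when present and bootstrap supports are
#' written as internal-node labels; the output re-parses to the same
#' tree with [ape::read.tree()].
#'
#' @param tree A `phylo`.
#' @param path Optional file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
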