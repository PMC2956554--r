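# Bitmask state coding for Fitch: A=1, C=2, G=4, T=8; gap/ambiguity/N
# are treated as missing data (full state set 15), consistent with the
# indel suppression used for distances.
encode_fitch <- function(aln) {
  chars <- strsplit(chartr("U", "T", toupper(aln$seqs)), "")
  codes <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  m <- vapply(chars, function(ch) {
    v <- unname(codes[ch])
    v[is.na(v)] <- 15L
    v
  }, integer(aln$alignment_length))
  m <- if (is.matrix(m)) t(m) else matrix(m, ncol = 1L)
  rownames(m) <- aln$taxa$accession
  m
}

# Collapse identical columns into patterns with weights.
site_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  list(states = states[, first, drop = FALSE],
       weight = as.integer(table(key)[key[first]]))
}

# Ensure every node has exactly two children (root unrooted trees on
# the first terminal edge; Fitch score is rooting-invariant for binary
# trees).
as_binary_rooted <- function(tree) {
  if (!ape::is.binary(tree) && !ape::is.binary(ape::unroot(tree)))
    stop("tree contains polytomies beyond the basal trifurcation")
  if (ape::is.rooted(tree) && ape::is.binary(tree)) return(tree)
  ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
}

#' Fitch small-parsimony score of a tree for an alignment
#'
#' Minimal number of state changes over the tree summed across sites
#' (Fitch algorithm), with gap and ambiguity characters treated as
#' missing data. The score is independent of rooting for binary trees.
#'
#' @param tree A `phylo` whose tip labels are the alignment's
#'   accessions.
#' @param aln A [marker_alignment()], or a precomputed pattern list
#'   from the internal encoder (used by the search for speed).
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, aln) {
  pat <- if (inherits(aln, "marker_alignment")) {
    st <- encode_fitch(aln)
    miss <- setdiff(tree$tip.label, rownames(st))
    if (length(miss))
      stop("tip(s) absent from alignment: ", paste(miss, collapse = ", "))
    site_patterns(st)
  } else aln
  tree <- as_binary_rooted(tree)
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  npat <- length(pat$weight)
  states <- matrix(0L, n_node, npat)
  states[seq_len(n_tip), ] <- pat$states[tree$tip.label, , drop = FALSE]
  changes <- integer(npat)
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  seen <- logical(n_node)
  for (e in seq_along(parent)) {
    p <- parent[e]; ch <- child[e]
    if (!seen[p]) {
      states[p, ] <- states[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(states[p, ], states[ch, ])
      empty <- inter == 0L
      changes[empty] <- changes[empty] + 1L
      inter[empty] <- bitwOr(states[p, empty], states[ch, empty])
      states[p, ] <- inter
    }
  }
  sum(changes * pat$weight)
}

# --- lightweight edge-list tree representation for stepwise addition ---
# edges: 2-column character matrix of (parent, child) over arbitrary
# string ids; tips are ids equal to taxon labels.
rep_to_phylo <- function(edges) {
  parents <- edges[, 1L]; children <- edges[, 2L]
  ids <- unique(c(parents, children))
  tips <- setdiff(ids, parents)
  root <- setdiff(parents, children)
  stopifnot(length(root) == 1L)
  kids <- split(children, factor(parents, levels = unique(parents)))
  # preorder so that the root gets internal number n_tip + 1
  ord_internal <- character(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[1L]; stack <- stack[-1L]
    ord_internal <- c(ord_internal, nd)
    ch <- kids[[nd]]
    stack <- c(ch[ch %in% names(kids)], stack)
  }
  num <- c(seq_along(tips), length(tips) + seq_along(ord_internal))
  names(num) <- c(tips, ord_internal)
  phy <- list(edge = cbind(unname(num[parents]), unname(num[children])),
              tip.label = tips, Nnode = length(ord_internal))
  class(phy) <- "phylo"
  stats::reorder(phy, "cladewise")
}

# All trees obtained by attaching `tip` onto each edge of `edges`
# (rooted binary edge-list); returns list of edge matrices.
tip_insertions <- function(edges, tip, counter) {
  lapply(seq_len(nrow(edges)), function(e) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    w <- paste0("#", counter, "_", e)
    rbind(edges[-e, , drop = FALSE],
          matrix(c(u, w, w, v, w, tip), ncol = 2L, byrow = TRUE))
  })
}

#' Maximum-parsimony tree search (random addition + close-neighbor
#' interchange)
#'
#' For each replicate a starting tree is built by stepwise addition of
#' the taxa in random order (each new taxon tried on every edge, the
#' best-scoring placement kept), then improved by hill-climbing over
#' close-neighbor-interchange rearrangements (nearest-neighbor
#' interchanges at search level 1) until no rearrangement lowers the
#' Fitch score. Equally best topologies across replicates are all
#' retained.
#'
#' @param aln A [marker_alignment()] with at least 4 records.
#' @param n_random_addition Number of random-addition replicates.
#' @param cni_level Rearrangement radius; level 1 = plain NNI.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return List of class `mp_result`: `trees` (list of distinct
#'   best `phylo` topologies, unrooted), `score` (best Fitch score),
#'   `replicate_scores`.
#' @export
mp_search <- function(aln, n_random_addition = 10L, cni_level = 1L,
                      seed = 1L) {
  stopifnot(length(aln$seqs) >= 4L)
  if (cni_level != 1L)
    warning("only cni_level = 1 (NNI radius) is implemented; using 1")
  labels <- aln$taxa$accession
  pat <- site_patterns(encode_fitch(aln))
  set.seed(seed)
  best_score <- Inf
  best_trees <- list()
  best_keys <- character(0)
  rep_scores <- numeric(n_random_addition)
  for (r in seq_len(n_random_addition)) {
    ord <- sample(labels)
    # rooted binary start on first two taxa
    edges <- matrix(c("R", ord[1L], "R", ord[2L]), ncol = 2L, byrow = TRUE)
    counter <- 0L
    for (k in 3L:length(ord)) {
      counter <- counter + 1L
      cand <- tip_insertions(edges, ord[k], counter)
      scores <- vapply(cand, function(ed) fitch_score(rep_to_phylo(ed), pat),
                       0)
      edges <- cand[[which.min(scores)]]
    }
    tree <- rep_to_phylo(edges)
    score <- fitch_score(tree, pat)
    repeat {
      nbrs <- phangorn::nni(ape::unroot(tree))
      nscores <- vapply(nbrs, function(tr) fitch_score(tr, pat), 0)
      if (min(nscores) < score) {
        score <- min(nscores)
        tree <- nbrs[[which.min(nscores)]]
      } else break
    }
    rep_scores[r] <- score
    key <- topology_key(tree)
    if (score < best_score - 1e-9) {
      best_score <- score
      best_trees <- list(ape::unroot(tree))
      best_keys <- key
    } else if (abs(score - best_score) < 1e-9 && !(key %in% best_keys)) {
      best_trees <- c(best_trees, list(ape::unroot(tree)))
      best_keys <- c(best_keys, key)
    }
  }
  structure(list(trees = best_trees, score = best_score,
                 replicate_scores = rep_scores),
            class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat("<mp_result> best score ", x$score, ", ", length(x$trees),
      " distinct best topolog", if (length(x$trees) == 1L) "y" else "ies",
      " over ", length(x$replicate_scores), " replicates\n", sep = "")
  invisible(x)
}

# Canonical unrooted-topology key: sorted branch bipartitions.
topology_key <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(p) {
    side <- sort(attr(parts, "labels")[p])
    other <- setdiff(labs, side)
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  }, "")
  paste(sort(unique(keys)), collapse = ";")
}

#' Root an MP tree at its midpoint using parsimony branch lengths
#'
#' MP topologies carry no branch lengths; lengths are assigned as
#' per-branch parsimony changes (ACCTRAN) and the tree midpoint-rooted
#' so species monophyly can be counted on a rooted tree.
#'
#' @param tree Unrooted `phylo` from [mp_search()].
#' @param aln The alignment used in the search.
#' @return Rooted `phylo` with branch lengths.
#' @export
root_mp_tree <- function(tree, aln) {
  pd <- as_phyDat(aln)
  tr <- phangorn::acctran(ape::unroot(tree), pd)
  phangorn::midpoint(tr)
}

# marker_alignment -> phangorn phyDat (for acctran/oracle use)
as_phyDat <- function(aln) {
  mat <- do.call(rbind, strsplit(chartr("U", "T", tolower(aln$seqs)), ""))
  rownames(mat) <- aln$taxa$accession
  phangorn::phyDat(mat, type = "DNA")
}
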