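#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration: repeatedly merge the two clusters at
#' minimal mean inter-cluster distance; the new node's height is half
#' that distance, so root-to-tip path lengths are equal (ultrametric).
#' Ties (within 1e-12) are broken by the lexicographically smallest
#' pair of cluster indices in order of first appearance, which makes
#' the result deterministic.
#'
#' @param dm A `pairdist` from [pairwise_matrix()], or a symmetric
#'   numeric matrix with dimnames.
#' @return A rooted ultrametric tree of class `phylo` (ape).
#' @export
upgma <- function(dm) {
  m <- if (inherits(dm, "pairdist")) dm$d else as.matrix(dm)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(m)))
  if (anyNA(m[upper.tri(m)])) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    stop("distance matrix has missing entries: ",
         paste(paste(labels[bad[, 1L]], labels[bad[, 2L]], sep = "--"),
               collapse = ", "))
  }
  agg <- upgma_merge(m)
  hc <- structure(list(merge = agg$merge, height = agg$height,
                       order = seq_along(labels), labels = labels,
                       method = "average"),
                  class = "hclust")
  ape::as.phylo(hc)  # halves heights: node height = d/2
}

# Core agglomeration; returns hclust-style merge matrix and heights
# (heights on the distance scale, i.e. twice the node height).
upgma_merge <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: negatives are tips
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  work <- m
  diag(work) <- Inf
  for (step in seq_len(n - 1L)) {
    sub <- work[active, active, drop = FALSE]
    dmin <- min(sub)
    # lexicographically smallest (i, j) among ties, i < j in active order
    hit <- which(sub <= dmin + 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L])[1L], ]
    i <- active[hit[1L]]; j <- active[hit[2L]]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- work[i, j]
    # average-linkage update into slot i
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      newd <- (size[i] * work[i, others] + size[j] * work[j, others]) /
        (size[i] + size[j])
      work[i, others] <- newd
      work[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merge, height = height)
}

#' Test whether a rooted tree is ultrametric
#' @param tree A `phylo` with branch lengths.
#' @param tol Tolerance on root-to-tip path differences.
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(depths)) <= tol
}
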