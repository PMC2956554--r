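# Independent oracles and tiny fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths.

# Build a marker_alignment from bare sequences with auto species labels:
# species given as e.g. c("sp1","sp1","sp2") parallel to seqs.
tiny_alignment <- function(seqs, species, marker = "test-marker",
                           genus = "Gen") {
  n <- length(seqs)
  marker_alignment(
    marker,
    data.frame(accession = sprintf("ACC%03d", seq_len(n)),
               genus = genus, species = species,
               ecotype = as.character(seq_len(n) + 100L),
               stringsAsFactors = FALSE),
    seqs
  )
}

# Random ungapped alignment (uniform letters), optionally with gaps and
# ambiguity codes sprinkled in.
random_seqs <- function(n, len, gap_frac = 0, ambig_frac = 0) {
  vapply(seq_len(n), function(i) {
    ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    k <- round(gap_frac * len)
    if (k > 0) ch[sample.int(len, k)] <- "-"
    k2 <- round(ambig_frac * len)
    if (k2 > 0) ch[sample.int(len, k2)] <- sample(c("N", "R", "Y"), k2,
                                                  replace = TRUE)
    paste(ch, collapse = "")
  }, "")
}

# Brute-force per-column scan: p-distance and site-pair counts computed
# with character comparison only.
oracle_site_scan <- function(x, y) {
  cx <- strsplit(toupper(x), "")[[1L]]
  cy <- strsplit(toupper(y), "")[[1L]]
  cx[cx == "U"] <- "T"; cy[cy == "U"] <- "T"
  ok <- cx %in% c("A", "C", "G", "T") & cy %in% c("A", "C", "G", "T")
  cx <- cx[ok]; cy <- cy[ok]
  ts <- 0L; tv <- 0L
  for (i in seq_along(cx)) {
    if (cx[i] == cy[i]) next
    pair <- sort(c(cx[i], cy[i]))
    if (identical(pair, c("A", "G")) || identical(pair, c("C", "T")))
      ts <- ts + 1L
    else tv <- tv + 1L
  }
  list(n_valid = length(cx), n_transitions = ts, n_transversions = tv,
       p = if (length(cx)) (ts + tv) / length(cx) else NA_real_)
}

# Exhaustive Fitch oracle: minimum changes per site by enumerating all
# internal-node state assignments of a rooted binary tree.
oracle_parsimony <- function(tree, seqs_named) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    tree <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1L],
                      resolve.root = TRUE)
  n_tip <- length(tree$tip.label)
  internals <- (n_tip + 1L):(n_tip + tree$Nnode)
  chars <- do.call(rbind, strsplit(toupper(seqs_named[tree$tip.label]), ""))
  bases <- c("A", "C", "G", "T")
  total <- 0L
  grid <- as.matrix(expand.grid(rep(list(bases), length(internals)),
                                stringsAsFactors = FALSE))
  for (site in seq_len(ncol(chars))) {
    tip_states <- chars[, site]
    missing_tip <- !(tip_states %in% bases)
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      assign_state <- c(tip_states, grid[g, ])
      changes <- 0L
      for (e in seq_len(nrow(tree$edge))) {
        a <- assign_state[tree$edge[e, 1L]]
        b <- assign_state[tree$edge[e, 2L]]
        bi <- tree$edge[e, 2L]
        if (bi <= n_tip && missing_tip[bi]) next  # missing tips free
        if (a != b) changes <- changes + 1L
      }
      if (changes < best) best <- changes
      if (best == 0L) break
    }
    total <- total + best
  }
  total
}

# Sort-and-count threshold oracle: smallest observed value v with
# >= pct% of values strictly below it; falls back to the maximum.
oracle_threshold <- function(values, pct = 95) {
  v <- sort(values)
  n <- length(v)
  need <- pct / 100 * n
  for (x in unique(v)) if (sum(v < x) >= need) return(x)
  max(v)
}

# Exact two-sided Mann-Whitney p by full enumeration of group
# assignments (small n only).
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[idx], nrow = n1))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Small, fast simulation config for classifier/tree tests.
small_config <- function(seed, n_species = 4L, ecotypes = 2L, len = 400L,
                         inter = 0.08, intra = 0.004, ...) {
  sim_config(n_species = n_species, ecotypes_per_species = ecotypes,
             marker_length = len, inter_divergence = inter,
             intra_divergence = intra, seed = seed, ...)
}
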