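#' Per-species mean intraspecific distances
#'
#' For every species with at least two ecotypes, the mean of all
#' conspecific pairwise distances. Averaging within species first
#' removes the bias introduced by unbalanced sampling across species.
#'
#' @param dm A `pairdist` from [pairwise_matrix()].
#' @return Named numeric vector (one value per multi-ecotype species);
#'   species whose within-species pairs are all missing are skipped
#'   with a warning.
#' @export
intraspecific_values <- function(dm) {
  sp <- paste(dm$taxa$genus, dm$taxa$species)
  multi <- names(which(table(sp) >= 2L))
  out <- numeric(0)
  for (s in multi) {
    idx <- which(sp == s)
    vals <- dm$d[idx, idx][upper.tri(diag(length(idx)))]
    if (all(is.na(vals))) {
      warning("all within-species pairs missing for ", s, "; skipped")
      next
    }
    out[s] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' Pooled intraspecific pairwise distances
#'
#' Every conspecific ecotype-pair distance (non-missing), pooled across
#' species. This is the list from which the identification threshold
#' and the barcoding-gap distribution are computed.
#'
#' @param dm A `pairdist`.
#' @return Numeric vector of distances.
#' @export
intraspecific_pairs <- function(dm) {
  idx <- intra_pair_index(dm)
  v <- dm$d[idx]
  v[!is.na(v)]
}

#' Interspecific pairwise distances
#'
#' @param dm A `pairdist`.
#' @param mode `"all_pairs"` (every between-species ecotype pair) or
#'   `"species_means"` (mean per unordered species pair, pooled).
#' @return Numeric vector of interspecific distances (missing pairs
#'   dropped).
#' @export
interspecific_values <- function(dm, mode = c("all_pairs", "species_means")) {
  mode <- match.arg(mode)
  sp <- paste(dm$taxa$genus, dm$taxa$species)
  idx <- inter_pair_index(dm)
  v <- dm$d[idx]
  keep <- !is.na(v)
  if (mode == "all_pairs") return(v[keep])
  pair_key <- apply(cbind(sp[idx[, 1L]], sp[idx[, 2L]]), 1L,
                    function(r) paste(sort(r), collapse = " vs "))
  as.numeric(tapply(v[keep], pair_key[keep], mean))
}

#' Mean interspecific substitution count
#'
#' Average number of observed substitutions (transitions plus
#' transversions) over interspecific pairs, the "average substitution
#' sites" figure used to compare markers of different length.
#'
#' @param dm A `pairdist`.
#' @param mode Pairing mode as in [interspecific_values()].
#' @return Mean substitution count (real).
#' @export
mean_interspecific_substitutions <- function(dm,
                                             mode = c("all_pairs",
                                                      "species_means")) {
  mode <- match.arg(mode)
  sp <- paste(dm$taxa$genus, dm$taxa$species)
  idx <- inter_pair_index(dm)
  v <- as.numeric(dm$subs[idx])
  if (mode == "all_pairs") return(mean(v))
  pair_key <- apply(cbind(sp[idx[, 1L]], sp[idx[, 2L]]), 1L,
                    function(r) paste(sort(r), collapse = " vs "))
  mean(tapply(v, pair_key, mean))
}

#' Mann-Whitney U and Mood's median test for the barcoding gap
#'
#' Tests whether intraspecific distances are located below
#' interspecific ones. The median test dichotomizes both samples at the
#' grand median and applies a chi-square test (Fisher's exact test when
#' any expected cell count is below 5).
#'
#' @param intra,inter Numeric vectors of pairwise distances.
#' @return List with `mwu_p` and `median_test_p` (two-sided).
#' @export
barcoding_gap_tests <- function(intra, inter) {
  if (!length(intra) || !length(inter)) stop("both samples must be nonempty")
  pooled <- c(intra, inter)
  if (length(unique(pooled)) == 1L) {
    warning("all pooled values identical; p = 1 by convention")
    return(list(mwu_p = 1, median_test_p = 1))
  }
  mwu <- suppressWarnings(
    stats::wilcox.test(intra, inter, alternative = "two.sided")
  )$p.value
  m <- stats::median(pooled)
  tab <- rbind(intra = c(sum(intra > m), sum(intra <= m)),
               inter = c(sum(inter > m), sum(inter <= m)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  med_p <- if (any(expected < 5)) {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  }
  list(mwu_p = mwu, median_test_p = med_p)
}

#' Histogram of intra- vs inter-specific distances (barcoding gap)
#'
#' Bins both distributions over shared edges and attaches the gap
#' tests, mirroring the relative-distribution figures used to visualize
#' marker separation.
#'
#' @param intra,inter Numeric distance vectors.
#' @param bin_width Bin width on the distance axis.
#' @return List of class `gap_distribution`: `bin_edges`,
#'   `intra_counts`, `inter_counts`, `mwu_p`, `median_test_p`.
#' @export
gap_histogram <- function(intra, inter, bin_width = 0.005) {
  if (!length(intra) || !length(inter)) stop("both samples must be nonempty")
  stopifnot(bin_width > 0)
  top <- max(intra, inter)
  edges <- seq(0, (floor(top / bin_width) + 1L) * bin_width, by = bin_width)
  cut_counts <- function(v)
    as.integer(table(cut(v, edges, include.lowest = TRUE, right = FALSE)))
  tests <- barcoding_gap_tests(intra, inter)
  structure(list(bin_edges = edges,
                 intra_counts = cut_counts(intra),
                 inter_counts = cut_counts(inter),
                 mwu_p = tests$mwu_p, median_test_p = tests$median_test_p),
            class = "gap_distribution")
}

#' Wilcoxon signed-rank comparison of two markers' divergences
#'
#' Orders markers by variability: the same species (or species pairs)
#' measured under two markers give paired samples; a signed-rank test
#' asks whether one marker is systematically more divergent.
#'
#' @param values_a,values_b Paired numeric vectors (same entities under
#'   marker A and marker B).
#' @return List with two-sided `p`, the signed-rank statistic `V`, and
#'   `direction` (`"B > A"`, `"A > B"` or `"none"` by median paired
#'   difference).
#' @export
marker_rank_test <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  diffs <- values_b - values_a
  if (all(diffs == 0))
    return(list(p = 1, V = 0, direction = "none"))
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = TRUE,
                       alternative = "two.sided")
  )
  md <- stats::median(diffs)
  list(p = wt$p.value, V = unname(wt$statistic),
       direction = if (md > 0) "B > A" else if (md < 0) "A > B" else "none")
}

#' Divergence summary for one marker (distance-table analog)
#'
#' @param aln A [marker_alignment()].
#' @param min_overlap Minimum pairwise overlap (default per marker).
#' @param inter_mode Pairing mode for interspecific values.
#' @param sd_as `"sd"` (population standard deviation of the value
#'   list) or `"se"` (standard error of the mean).
#' @return One-row data frame: marker, aligned length, mean
#'   interspecific substitutions, mean +/- spread of inter- and
#'   intra-specific K2P and p-distances, and the number of
#'   multi-ecotype species used.
#' @export
divergence_summary <- function(aln, min_overlap = NULL,
                               inter_mode = "all_pairs", sd_as = c("sd", "se")) {
  sd_as <- match.arg(sd_as)
  spread <- function(v) {
    if (length(v) < 2L) return(NA_real_)
    s <- stats::sd(v) * sqrt((length(v) - 1) / length(v))
    if (sd_as == "se") s / sqrt(length(v)) else s
  }
  dk <- pairwise_matrix(aln, "K2P", min_overlap)
  dp <- pairwise_matrix(aln, "p", min_overlap)
  inter_k <- interspecific_values(dk, inter_mode)
  inter_p <- interspecific_values(dp, inter_mode)
  intra_k <- intraspecific_values(dk)
  intra_p <- intraspecific_values(dp)
  data.frame(
    marker = aln$marker,
    aligned_length = aln$alignment_length,
    n_records = length(aln$seqs),
    n_species_multi = length(intra_k),
    mean_inter_subs = mean_interspecific_substitutions(dk, inter_mode),
    mean_inter_k2p = mean(inter_k), sd_inter_k2p = spread(inter_k),
    mean_intra_k2p = mean(intra_k), sd_intra_k2p = spread(intra_k),
    mean_inter_p = mean(inter_p), sd_inter_p = spread(inter_p),
    mean_intra_p = mean(intra_p), sd_intra_p = spread(intra_p),
    stringsAsFactors = FALSE
  )
}
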