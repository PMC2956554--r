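# Integer coding: A=1, C=2, G=3, T=4 (U folded into T); gaps, N and
# IUPAC ambiguity codes code 0 and are excluded from every comparison.
encode_residues <- function(x) {
  ch <- strsplit(chartr("U", "T", toupper(x)), "")[[1L]]
  code <- match(ch, c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  code
}

encode_alignment <- function(aln) {
  m <- vapply(aln$seqs, encode_residues,
              integer(aln$alignment_length), USE.NAMES = FALSE)
  # vapply drops to a vector for single-column alignments
  m <- if (is.matrix(m)) t(m) else matrix(m, ncol = 1L)
  rownames(m) <- aln$taxa$accession
  m
}

#' Classify aligned site pairs into transitions and transversions
#'
#' Columns where either row carries a gap, `N` or an IUPAC ambiguity
#' code are excluded (indel suppression / pairwise deletion). Among the
#' remaining columns, A<->G and C<->T differences are transitions, all
#' other differences transversions.
#'
#' @param x,y Aligned residue strings of equal length (or their integer
#'   encodings).
#' @return List with `n_valid`, `n_transitions`, `n_transversions`, and
#'   the proportions `P` and `Q` (NaN when `n_valid` is 0).
#' @export
classify_site_pairs <- function(x, y) {
  if (is.character(x)) x <- encode_residues(x)
  if (is.character(y)) y <- encode_residues(y)
  if (length(x) != length(y)) stop("rows differ in length")
  valid <- x > 0L & y > 0L
  xi <- x[valid]; yi <- y[valid]
  diff <- xi != yi
  # purine A(1)<->G(3) and pyrimidine C(2)<->T(4) pairs: same parity
  ts <- diff & ((xi %% 2L) == (yi %% 2L))
  n_valid <- length(xi)
  n_ts <- sum(ts)
  n_tv <- sum(diff) - n_ts
  list(n_valid = n_valid, n_transitions = n_ts, n_transversions = n_tv,
       P = n_ts / n_valid, Q = n_tv / n_valid)
}

#' Uncorrected p-distance from site-pair counts
#'
#' @param counts Output of [classify_site_pairs()].
#' @return Proportion of differing sites among valid sites; `NA` when no
#'   sites could be compared.
#' @export
p_distance <- function(counts) {
  if (counts$n_valid == 0L) return(NA_real_)
  (counts$n_transitions + counts$n_transversions) / counts$n_valid
}

#' Kimura 2-parameter distance from site-pair counts
#'
#' Implements `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` where `P`
#' and `Q` are the transition and transversion proportions. Saturated
#' pairs (log argument non-positive) yield `NA` with attribute
#' `saturated = TRUE`.
#'
#' @param counts Output of [classify_site_pairs()].
#' @return The K2P distance, or a flagged `NA` sentinel.
#' @export
k2p_distance <- function(counts) {
  if (counts$n_valid == 0L) return(NA_real_)
  a <- 1 - 2 * counts$P - counts$Q
  b <- 1 - 2 * counts$Q
  if (a <= 0 || b <= 0) return(structure(NA_real_, saturated = TRUE))
  -0.5 * log(a * sqrt(b))
}

#' Default minimum pairwise overlap for a marker
#'
#' Two sequences are only compared when they share at least 300
#' ungapped, unambiguous columns, relaxed to 230 for the short and
#' indel-rich psbK-psbI spacer.
#'
#' @param marker Marker name.
#' @return Minimum overlap in bp.
#' @export
default_min_overlap <- function(marker) {
  if (identical(marker, "psbK-psbI")) 230L else 300L
}

#' Pairwise distance matrix for a marker alignment
#'
#' Computes all unordered pairs under pairwise deletion: columns with a
#' gap or ambiguity code in either member of a pair are excluded for
#' that pair only. Pairs whose remaining overlap falls below
#' `min_overlap` are flagged missing (`NA`), as are saturated K2P
#' pairs.
#'
#' @param aln A [marker_alignment()].
#' @param model `"K2P"` or `"p"`.
#' @param min_overlap Minimum shared valid columns per pair; default
#'   from [default_min_overlap()] for the alignment's marker.
#' @return An object of class `pairdist`: list with `model`, `taxa`,
#'   `labels`, and symmetric matrices `d` (distances), `overlap`
#'   (valid-site counts), `subs` (substitution counts) and `saturated`
#'   (logical).
#' @export
pairwise_matrix <- function(aln, model = c("K2P", "p"), min_overlap = NULL) {
  model <- match.arg(model)
  if (length(aln$seqs) < 2L) stop("need at least 2 records")
  if (is.null(min_overlap)) min_overlap <- default_min_overlap(aln$marker)
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  labels <- aln$taxa$accession
  if (anyDuplicated(labels))
    stop("duplicated accession ids: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  overlap <- matrix(0L, n, n, dimnames = list(labels, labels))
  subs <- matrix(0L, n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    xi <- enc[i, ]
    for (j in (i + 1L):n) {
      cnt <- classify_site_pairs(xi, enc[j, ])
      overlap[i, j] <- overlap[j, i] <- cnt$n_valid
      subs[i, j] <- subs[j, i] <- cnt$n_transitions + cnt$n_transversions
      if (cnt$n_valid < min_overlap) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        dij <- if (model == "K2P") k2p_distance(cnt) else p_distance(cnt)
        if (isTRUE(attr(dij, "saturated"))) sat[i, j] <- sat[j, i] <- TRUE
        d[i, j] <- d[j, i] <- as.numeric(dij)
      }
    }
  }
  structure(list(model = model, taxa = aln$taxa, labels = labels,
                 marker = aln$marker, min_overlap = min_overlap,
                 d = d, overlap = overlap, subs = subs, saturated = sat),
            class = "pairdist")
}

#' @export
print.pairdist <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat("<pairdist> ", x$model, " distances, ", length(x$labels), " taxa (",
      x$marker, "); ", sum(is.na(off)), " missing of ", length(off),
      " pairs\n", sep = "")
  invisible(x)
}

#' Export a distance matrix as long-format TSV or PHYLIP square matrix
#'
#' @param dm A `pairdist` from [pairwise_matrix()].
#' @param path Output file.
#' @param format `"tsv"` (long: taxon_i, taxon_j, model, d, overlap,
#'   subs) or `"phylip"` (square matrix; missing entries written as -1).
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ut <- which(upper.tri(dm$d), arr.ind = TRUE)
    out <- data.frame(taxon_i = dm$labels[ut[, 1L]],
                      taxon_j = dm$labels[ut[, 2L]],
                      model = dm$model,
                      d = dm$d[ut], overlap = dm$overlap[ut],
                      subs = dm$subs[ut])
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- dm$d
    m[is.na(m)] <- -1
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(formatC(dm$labels[i], width = -10),
                       paste(sprintf("%.8f", m[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

# Distances restricted to pairs in one species / across species
intra_pair_index <- function(dm) {
  sp <- paste(dm$taxa$genus, dm$taxa$species)
  ut <- which(upper.tri(dm$d), arr.ind = TRUE)
  ut[sp[ut[, 1L]] == sp[ut[, 2L]], , drop = FALSE]
}

inter_pair_index <- function(dm) {
  sp <- paste(dm$taxa$genus, dm$taxa$species)
  ut <- which(upper.tri(dm$d), arr.ind = TRUE)
  ut[sp[ut[, 1L]] != sp[ut[, 2L]], , drop = FALSE]
}
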