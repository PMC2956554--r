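IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
DNA_ALPHABET <- c("A", "C", "G", "T", "U", IUPAC_AMBIG, "-")

#' Construct a marker alignment
#'
#' A `marker_alignment` bundles the aligned sequences of one barcoding
#' marker with per-record taxon labels (accession, genus, species,
#' ecotype). It is the unit of all downstream computation: distance
#' matrices, divergence summaries, identification reports and trees are
#' all derived from it.
#'
#' @param marker Marker name, e.g. `"atpF-atpH"`.
#' @param taxa Data frame with columns `accession`, `genus`, `species`,
#'   `ecotype` (one row per record, in alignment order).
#' @param seqs Character vector of aligned sequences (equal length,
#'   gaps as `-`), same length and order as `taxa` rows.
#' @return An object of class `marker_alignment` with fields `marker`,
#'   `taxa`, `seqs` and `alignment_length`.
#' @export
marker_alignment <- function(marker, taxa, seqs) {
  stopifnot(is.character(marker), length(marker) == 1L)
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  required <- c("accession", "genus", "species", "ecotype")
  missing_cols <- setdiff(required, names(taxa))
  if (length(missing_cols))
    stop("taxon table lacks columns: ", paste(missing_cols, collapse = ", "))
  seqs <- toupper(as.character(seqs))
  if (length(seqs) != nrow(taxa))
    stop("number of sequences (", length(seqs), ") does not match taxon rows (",
         nrow(taxa), ")")
  if (length(seqs) == 0L) stop("alignment is empty")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- taxa$accession[which(lens != lens[1L])[1L]]
    stop("not aligned: record '", bad, "' has length ", lens[lens != lens[1L]][1L],
         " but expected ", lens[1L])
  }
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  bad_letters <- setdiff(letters_used, DNA_ALPHABET)
  if (length(bad_letters))
    stop("illegal residue characters: ", paste(bad_letters, collapse = ", "))
  structure(
    list(marker = marker, taxa = taxa, seqs = seqs,
         alignment_length = lens[1L]),
    class = "marker_alignment"
  )
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("<marker_alignment> ", x$marker, ": ", length(x$seqs), " records x ",
      x$alignment_length, " columns, ",
      length(unique(x$taxa$species)), " species\n", sep = "")
  invisible(x)
}

#' Read one marker's aligned FASTA with its taxon table
#'
#' FASTA headers follow the convention
#' `accession|Genus_species|ecotypeID|marker`; only the leading
#' accession token is required, and the taxon table is authoritative for
#' genus/species/ecotype on any conflict.
#'
#' @param path Aligned FASTA file (gaps as `-`).
#' @param taxon_table TSV with header
#'   `accession\tgenus\tspecies\tecotype\torigin` (origin optional).
#' @param marker Marker name to attach to the alignment.
#' @return A [marker_alignment()].
#' @export
read_marker_fasta <- function(path, taxon_table, marker) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  acc <- vapply(strsplit(names(ss), "|", fixed = TRUE), `[`, "", 1L)
  acc <- trimws(vapply(strsplit(acc, "[ \t]"), `[`, "", 1L))
  tab <- utils::read.delim(taxon_table, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("accession", "genus", "species", "ecotype")
  if (!all(required %in% names(tab)))
    stop("taxon table must have columns ", paste(required, collapse = ", "))
  idx <- match(acc, tab$accession)
  if (anyNA(idx))
    stop("accession(s) not found in taxon table: ",
         paste(acc[is.na(idx)], collapse = ", "))
  marker_alignment(marker, tab[idx, required], as.character(ss))
}

#' Write a marker alignment as aligned FASTA
#'
#' Headers use the `accession|Genus_species|ecotypeID|marker` convention
#' so that [read_marker_fasta()] round-trips.
#'
#' @param aln A [marker_alignment()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_marker_fasta <- function(aln, path) {
  headers <- paste(aln$taxa$accession,
                   paste(aln$taxa$genus, aln$taxa$species, sep = "_"),
                   aln$taxa$ecotype, aln$marker, sep = "|")
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write the taxon table of an alignment or dataset as TSV
#' @param taxa Data frame with accession/genus/species/ecotype columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(taxa, path) {
  utils::write.table(taxa, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trim terminal runs of ambiguous nucleotides from a raw read
#'
#' Sanger reads carry unreliable calls at both ends; this removes the
#' maximal leading and trailing contiguous run of non-ACGT(U)
#' characters, capped at `max_trim` positions per end (about the 30 bp
#' typically discarded). Interior ambiguity codes are preserved.
#'
#' @param x Ungapped read (character scalar).
#' @param max_trim Maximum residues removable per end.
#' @return The trimmed read; may be empty (with a warning).
#' @export
trim_ambiguous_ends <- function(x, max_trim = 30L) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  if (grepl("-", x, fixed = TRUE)) stop("expected an ungapped raw read")
  ch <- strsplit(x, "")[[1L]]
  ok <- ch %in% c("A", "C", "G", "T", "U")
  n <- length(ch)
  lead <- 0L
  while (lead < min(max_trim, n) && !ok[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < min(max_trim, n - lead) && !ok[n - trail]) trail <- trail + 1L
  out <- substr(x, lead + 1L, n - trail)
  if (!nzchar(out)) warning("read entirely trimmed away")
  out
}

#' Reverse-complement a DNA string
#' @param x DNA string (IUPAC codes allowed).
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' In-silico PCR: extract the amplicon delimited by a primer pair
#'
#' The forward primer is matched on the given strand and the reverse
#' primer as its reverse complement downstream; if that orientation
#' yields no product both roles are retried on the reverse strand. The
#' amplicon runs from the 5' end of the forward site to the 5' end of
#' the reverse site on the opposite strand, primers included.
#'
#' @param template Gap-free DNA string.
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param max_mismatches Mismatches tolerated per primer site.
#' @return The amplicon as a character scalar; its `nchar()` is the
#'   product size in bp.
#' @export
insilico_pcr <- function(template, forward, reverse, max_mismatches = 0L) {
  stopifnot(!grepl("-", template, fixed = TRUE))
  tmpl <- Biostrings::DNAString(toupper(template))
  find_amplicon <- function(subject) {
    f <- Biostrings::matchPattern(toupper(forward), subject,
                                  max.mismatch = max_mismatches)
    r <- Biostrings::matchPattern(revcomp(toupper(reverse)), subject,
                                  max.mismatch = max_mismatches)
    list(f = f, r = r)
  }
  hits <- find_amplicon(tmpl)
  nf <- length(hits$f); nr <- length(hits$r)
  if (nf != 1L || nr != 1L) {
    hits2 <- find_amplicon(Biostrings::reverseComplement(tmpl))
    if (length(hits2$f) == 1L && length(hits2$r) == 1L) {
      tmpl <- Biostrings::reverseComplement(tmpl)
      hits <- hits2
    } else {
      stop("primer site resolution failed: forward hits = ", nf,
           ", reverse hits = ", nr, " (forward strand); reverse strand: ",
           length(hits2$f), "/", length(hits2$r))
    }
  }
  fs <- Biostrings::start(hits$f)
  re <- Biostrings::end(hits$r)
  if (re <= fs) stop("reverse primer site lies upstream of forward site")
  as.character(Biostrings::subseq(tmpl, fs, re))
}

#' Optimal annealing temperature from primer and product melting points
#'
#' Combines the two melting temperatures (defined at 50 mM monovalent
#' ion, 200 nM nucleic acid) linearly:
#' `Ta = 0.3 * Tm(primer) + 0.7 * Tm(product) - 14.9`.
#'
#' @param tm_primer,tm_product Melting temperatures in degrees Celsius.
#' @return Optimal annealing temperature in degrees Celsius.
#' @export
optimal_annealing_temp <- function(tm_primer, tm_product) {
  stopifnot(is.finite(tm_primer), is.finite(tm_product))
  0.3 * tm_primer + 0.7 * tm_product - 14.9
}

#' Concatenate two marker alignments over their shared taxa
#'
#' Records are matched on (genus, species, ecotype); taxa present in
#' only one marker are dropped and listed in the `dropped` attribute.
#' Used to evaluate combined two-marker barcodes.
#'
#' @param a,b [marker_alignment()] objects.
#' @return A `marker_alignment` named `"<a>+<b>"` whose rows are the
#'   per-taxon concatenations; attribute `dropped` is a character vector
#'   of excluded taxon keys.
#' @export
concatenate_markers <- function(a, b) {
  key <- function(aln) paste(aln$taxa$genus, aln$taxa$species,
                             aln$taxa$ecotype, sep = "|")
  ka <- key(a); kb <- key(b)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stop("no taxa shared between markers")
  ia <- match(shared, ka); ib <- match(shared, kb)
  out <- marker_alignment(
    paste(a$marker, b$marker, sep = "+"),
    a$taxa[ia, , drop = FALSE],
    paste0(a$seqs[ia], b$seqs[ib])
  )
  attr(out, "dropped") <- setdiff(union(ka, kb), shared)
  out
}

#' Read a primer table (TSV)
#'
#' Expected columns: `marker`, `forward`, `reverse`, and optionally
#' `amplicon_bp` and `ta_optimum`.
#'
#' @param path TSV file.
#' @return Data frame of primer pairs.
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("marker", "forward", "reverse") %in% names(tab)))
    stop("primer table must have columns marker, forward, reverse")
  if (any(grepl("-", c(tab$forward, tab$reverse), fixed = TRUE)))
    stop("primers must be gap-free")
  tab
}
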