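#' Configuration for a full marker-evaluation run
#'
#' @param alignments Named list of [marker_alignment()] objects (names
#'   = marker names), or a named character vector of aligned FASTA
#'   paths (then `taxon_table` must be given).
#' @param taxon_table Path to the taxon TSV when `alignments` are file
#'   paths.
#' @param min_overlap Named list/vector of per-marker overrides;
#'   markers not listed use [default_min_overlap()].
#' @param percentile Intraspecific-threshold percentile.
#' @param combine_with Marker to pair with every other marker for the
#'   combined-barcode evaluation (`NULL` disables; ignored if absent
#'   from the data).
#' @param bootstrap Bootstrap replicates for the UPGMA tree (0 = no
#'   supports; bootstrapping every marker is expensive).
#' @param run_mp Whether to run the maximum-parsimony search and score
#'   its monophyly as well.
#' @param mp_random_additions Random-addition replicates for the MP
#'   search.
#' @param completeness_threshold Fraction of expected records below
#'   which a marker is flagged "low completeness".
#' @param total_records Expected number of records per marker (for
#'   completeness accounting); defaults to the largest marker.
#' @param seed Seed governing MP search and bootstrap.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(alignments, taxon_table = NULL,
                            min_overlap = list(), percentile = 95,
                            combine_with = "atpF-atpH",
                            bootstrap = 0L, run_mp = FALSE,
                            mp_random_additions = 10L,
                            completeness_threshold = 0.9,
                            total_records = NULL, seed = 1L) {
  if (is.character(alignments)) {
    if (is.null(taxon_table)) stop("taxon_table required with file paths")
    if (is.null(names(alignments))) stop("alignment paths must be named")
    missing_files <- alignments[!file.exists(alignments)]
    if (length(missing_files))
      stop("missing files: ", paste(missing_files, collapse = ", "))
    alignments <- Map(function(p, m) read_marker_fasta(p, taxon_table, m),
                      alignments, names(alignments))
  }
  stopifnot(length(alignments) >= 1L,
            all(vapply(alignments, inherits, TRUE, "marker_alignment")))
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, `[[`, "", "marker")
  structure(list(alignments = alignments, min_overlap = min_overlap,
                 percentile = percentile, combine_with = combine_with,
                 bootstrap = as.integer(bootstrap), run_mp = run_mp,
                 mp_random_additions = as.integer(mp_random_additions),
                 completeness_threshold = completeness_threshold,
                 total_records = total_records, seed = as.integer(seed)),
            class = "pipeline_config")
}

marker_overlap <- function(config, marker) {
  ov <- config$min_overlap[[marker]]
  if (is.null(ov)) default_min_overlap(marker) else ov
}

#' Run the full per-marker evaluation pipeline
#'
#' For every marker: completeness accounting (records present, ungapped
#' length range), divergence summary with barcoding-gap tests,
#' best-close-match identification, and UPGMA (optionally MP) monophyly
#' scoring; then the identification step is repeated for each
#' combination of `combine_with` with the remaining markers.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `evaluation_report` with data-frame fields
#'   `completeness`, `divergence`, `identification`, `monophyly`, plus
#'   `trees` (per-marker UPGMA `phylo`), `gap_tests`, and a `log` of
#'   drops and flags.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  markers <- names(config$alignments)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  n_expected <- config$total_records %||%
    max(vapply(config$alignments, function(a) length(a$seqs), 0L))

  completeness <- do.call(rbind, lapply(markers, function(m) {
    aln <- config$alignments[[m]]
    ungapped <- nchar(gsub("-", "", aln$seqs, fixed = TRUE))
    frac <- length(aln$seqs) / n_expected
    low <- frac < config$completeness_threshold
    if (low) note("marker ", m, ": low completeness (",
                  round(100 * frac, 1), "% of ", n_expected, " records)")
    data.frame(marker = m, n_records = length(aln$seqs),
               n_expected = n_expected,
               pct_present = 100 * frac,
               min_ungapped = min(ungapped), max_ungapped = max(ungapped),
               aligned_length = aln$alignment_length,
               low_completeness = low, stringsAsFactors = FALSE)
  }))

  divergence <- NULL; gap_tests <- list(); trees <- list()
  monophyly <- NULL; identification <- NULL
  for (m in markers) {
    aln <- config$alignments[[m]]
    ov <- marker_overlap(config, m)
    divergence <- rbind(divergence, divergence_summary(aln, ov))
    dk <- pairwise_matrix(aln, "K2P", ov)
    dp <- pairwise_matrix(aln, "p", ov)
    gt <- barcoding_gap_tests(intraspecific_pairs(dp),
                              interspecific_values(dp))
    gap_tests[[m]] <- gt
    if (any(is.na(dk$d[upper.tri(dk$d)]))) {
      note("marker ", m, ": ", sum(is.na(dk$d[upper.tri(dk$d)])),
           " pair(s) missing (overlap < ", ov, " or saturated); ",
           "tree built on available records only")
      keep <- stats::complete.cases(dk$d)
      dk$d <- dk$d[keep, keep]; dk$taxa <- dk$taxa[keep, , drop = FALSE]
      dk$labels <- dk$labels[keep]
    }
    tree <- if (config$bootstrap > 0L) {
      bootstrap_support(aln, "UPGMA", config$bootstrap, seed = config$seed,
                        min_overlap = ov)
    } else upgma(dk)
    trees[[m]] <- tree
    mono_u <- monophyly_report(tree, aln$taxa, "UPGMA")
    monophyly <- rbind(monophyly, data.frame(
      marker = m, method = "UPGMA",
      n_multi_species = mono_u$n_multi_species,
      n_monophyletic = mono_u$n_monophyletic,
      mean_support = mono_u$mean_support, stringsAsFactors = FALSE))
    if (config$run_mp) {
      mp <- mp_search(aln, config$mp_random_additions, seed = config$seed)
      mono_m <- monophyly_report(root_mp_tree(mp$trees[[1L]], aln),
                                 aln$taxa, "MP")
      monophyly <- rbind(monophyly, data.frame(
        marker = m, method = "MP",
        n_multi_species = mono_m$n_multi_species,
        n_monophyletic = mono_m$n_monophyletic,
        mean_support = mono_m$mean_support, stringsAsFactors = FALSE))
    }
    idr <- evaluate_marker(aln, ov, config$percentile)
    identification <- rbind(identification, id_report_row(idr, flagged = FALSE))
  }

  cw <- config$combine_with
  if (!is.null(cw) && cw %in% markers) {
    for (m in setdiff(markers, cw)) {
      comb <- concatenate_markers(config$alignments[[m]],
                                  config$alignments[[cw]])
      if (length(attr(comb, "dropped")))
        note("combination ", comb$marker, ": dropped ",
             length(attr(comb, "dropped")), " unshared taxa")
      ov <- marker_overlap(config, m)
      flag <- isTRUE(completeness$low_completeness[completeness$marker == m])
      if (flag) note("combination ", comb$marker,
                     ": flagged (low-completeness component)")
      idr <- evaluate_marker(comb, ov, config$percentile)
      identification <- rbind(identification, id_report_row(idr, flag))
    }
  }
  structure(list(completeness = completeness, divergence = divergence,
                 gap_tests = gap_tests, identification = identification,
                 monophyly = monophyly, trees = trees, log = log_lines),
            class = "evaluation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

id_report_row <- function(idr, flagged) {
  data.frame(marker = idr$marker, n_queries = idr$n_queries,
             correct = idr$counts[["correct"]],
             ambiguous = idr$counts[["ambiguous"]],
             incorrect = idr$counts[["incorrect"]],
             no_match = idr$counts[["no_match"]],
             pct_correct = idr$percent[["correct"]],
             pct_ambiguous = idr$percent[["ambiguous"]],
             pct_incorrect = idr$percent[["incorrect"]],
             pct_no_match = idr$percent[["no_match"]],
             threshold_percent = idr$threshold_percent,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", nrow(x$completeness), " marker(s)\n", sep = "")
  cat("-- divergence --\n")
  print(x$divergence[, c("marker", "mean_inter_k2p", "mean_intra_k2p")],
        row.names = FALSE)
  cat("-- identification --\n")
  print(x$identification[, c("marker", "n_queries", "pct_correct",
                             "threshold_percent")], row.names = FALSE)
  cat("-- monophyly --\n")
  print(x$monophyly, row.names = FALSE)
  if (length(x$log)) cat("log:\n", paste(" *", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Render an evaluation report to TSV and JSON files
#'
#' Writes one TSV per result table (completeness, divergence,
#' identification, monophyly; percentages rounded to 2 decimals) and a
#' single full-precision JSON bundle.
#'
#' @param report An `evaluation_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
render_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round_pct <- function(df) {
    num <- vapply(df, is.numeric, TRUE) & grepl("pct|percent", names(df))
    df[num] <- lapply(df[num], round, 2)
    df
  }
  paths <- list()
  for (tab in c("completeness", "divergence", "identification", "monophyly")) {
    p <- file.path(dir, paste0(tab, ".tsv"))
    utils::write.table(round_pct(report[[tab]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[[tab]] <- p
  }
  pj <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(completeness = report$completeness, divergence = report$divergence,
         gap_tests = report$gap_tests, identification = report$identification,
         monophyly = report$monophyly, log = report$log),
    pj, auto_unbox = TRUE, digits = NA, na = "null")
  paths$json <- pj
  for (m in names(report$trees)) {
    p <- file.path(dir, paste0("upgma_", gsub("[^A-Za-z0-9.-]", "_", m),
                               ".nwk"))
    write_newick(report$trees[[m]], p)
    paths[[paste0("tree_", m)]] <- p
  }
  invisible(paths)
}
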