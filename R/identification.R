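#' Intraspecific distance threshold for best-close-match
#'
#' The threshold is the smallest observed value `v` such that at least
#' the given percentage of all pooled intraspecific pairwise distances
#' lie strictly below `v`; when no observed value qualifies (e.g. a
#' degenerate all-equal list) the maximum is returned.
#'
#' @param dm A `pairdist` built with the `"p"` model, or a numeric
#'   vector of intraspecific distances.
#' @param percentile Percentage of intraspecific distances required to
#'   fall below the threshold (default 95).
#' @return The threshold distance (proportion, not percent).
#' @export
intraspecific_threshold <- function(dm, percentile = 95) {
  v <- if (inherits(dm, "pairdist")) intraspecific_pairs(dm) else
    dm[!is.na(dm)]
  if (!length(v)) stop("no intraspecific pairwise distances available")
  v <- sort(v)
  n <- length(v)
  need <- percentile / 100 * n
  below <- cumsum(c(0, rle(v)$lengths))   # strictly-below counts per
  uniq <- unique(v)                       # distinct observed value
  hit <- which(below[seq_along(uniq)] >= need)
  if (length(hit)) uniq[hit[1L]] else v[n]
}

match_category <- function(query_species, nearest_species, tie_tol = 1e-12) {
  if (length(nearest_species) > 1L) "ambiguous"
  else if (identical(nearest_species, query_species)) "correct"
  else "incorrect"
}

#' Best-match species assignment for one query
#'
#' The query is assigned the species of its nearest reference by
#' uncorrected p-distance; equidistant nearest references (within
#' `tie_tol`) of different species make the call ambiguous.
#'
#' @param d Named numeric vector of query-to-reference distances
#'   (query excluded; `NA` = pair not comparable).
#' @param ref_species Character vector of reference species labels,
#'   parallel to `d`.
#' @param query_species The query's labeled species.
#' @param tie_tol Distances within this of the minimum count as tied.
#' @return List: `predicted_species` (vector if ambiguous), `category`
#'   (`correct`/`ambiguous`/`incorrect`), `nearest_distance`.
#' @export
best_match <- function(d, ref_species, query_species, tie_tol = 1e-12) {
  keep <- !is.na(d)
  if (!any(keep)) stop("no comparable references for query")
  d <- d[keep]; ref_species <- ref_species[keep]
  dmin <- min(d)
  nearest <- unique(ref_species[d <= dmin + tie_tol])
  list(predicted_species = nearest,
       category = match_category(query_species, nearest, tie_tol),
       nearest_distance = dmin)
}

#' Best-close-match species assignment for one query
#'
#' As [best_match()], but only references within the intraspecific
#' threshold are eligible; a query with no reference inside the
#' threshold is reported as `no_match`.
#'
#' @inheritParams best_match
#' @param threshold Distance threshold from [intraspecific_threshold()].
#' @param strict If `TRUE` eligibility uses `d < threshold` instead of
#'   `d <= threshold`.
#' @return List as in [best_match()] plus `threshold_used`; category
#'   may additionally be `no_match`.
#' @export
best_close_match <- function(d, ref_species, query_species, threshold,
                             tie_tol = 1e-12, strict = FALSE) {
  keep <- !is.na(d)
  if (!any(keep)) stop("no comparable references for query")
  d <- d[keep]; ref_species <- ref_species[keep]
  eligible <- if (strict) d < threshold else d <= threshold
  if (!any(eligible)) {
    return(list(predicted_species = NA_character_, category = "no_match",
                nearest_distance = min(d), threshold_used = threshold))
  }
  out <- best_match(d[eligible], ref_species[eligible], query_species, tie_tol)
  out$threshold_used <- threshold
  out
}

#' Evaluate a marker by leave-one-out best-close-match identification
#'
#' Every ecotype of a species with at least two sampled ecotypes is
#' queried in turn against all remaining records (singleton species
#' contribute references but no queries, so they can still attract
#' incorrect calls). Distances are uncorrected p-distances with indels
#' suppressed; the threshold is the `percentile`-th percentile of
#' pooled intraspecific distances on the same matrix.
#'
#' @param aln A [marker_alignment()] (possibly a concatenation from
#'   [concatenate_markers()]).
#' @param min_overlap Minimum pairwise overlap in bp (default per
#'   marker).
#' @param percentile Threshold percentile (default 95).
#' @param tie_tol,strict Passed to [best_close_match()].
#' @return Object of class `id_report`: list with `marker`,
#'   `n_queries`, `counts` and `percent` per category (correct,
#'   ambiguous, incorrect, no_match), `threshold_percent`, and the
#'   per-query `outcomes` data frame.
#' @export
evaluate_marker <- function(aln, min_overlap = NULL, percentile = 95,
                            tie_tol = 1e-12, strict = FALSE) {
  dm <- pairwise_matrix(aln, "p", min_overlap)
  sp <- paste(dm$taxa$genus, dm$taxa$species)
  multi <- names(which(table(sp) >= 2L))
  queries <- which(sp %in% multi)
  threshold <- intraspecific_threshold(dm, percentile)
  rows <- lapply(queries, function(q) {
    res <- best_close_match(dm$d[q, -q], sp[-q], sp[q], threshold,
                            tie_tol = tie_tol, strict = strict)
    data.frame(accession = dm$labels[q], species = sp[q],
               predicted = paste(res$predicted_species, collapse = ";"),
               category = res$category,
               nearest_distance = res$nearest_distance,
               stringsAsFactors = FALSE)
  })
  outcomes <- do.call(rbind, rows)
  cats <- c("correct", "ambiguous", "incorrect", "no_match")
  counts <- vapply(cats, function(k) sum(outcomes$category == k), 0L)
  structure(list(marker = aln$marker,
                 n_queries = length(queries),
                 counts = counts,
                 percent = 100 * counts / length(queries),
                 threshold_percent = 100 * threshold,
                 outcomes = outcomes),
            class = "id_report")
}

#' @export
print.id_report <- function(x, ...) {
  cat("<id_report> ", x$marker, ": ", x$n_queries, " queries, threshold ",
      sprintf("%.2f%%", x$threshold_percent), "\n", sep = "")
  for (k in names(x$counts))
    cat(sprintf("  %-9s %3d (%.2f%%)\n", k, x$counts[[k]], x$percent[[k]]))
  invisible(x)
}
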