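#' Thresholds for the ortholog-assignment cascade
#'
#' @param e_strict Strict genomic BLASTN E-value cutoff (default 1e-10).
#' @param e_primary Primary genomic cutoff used for the conserved/absent
#'   decision (default 1e-6).
#' @param e_est_fallbacks Ordered relaxed cutoffs for the transcript/CDS
#'   fallback searches (default 1e-30, 1e-20, 1e-5); only the most permissive
#'   matters for the conserved-by-fallback call, the full cascade is kept for
#'   tally reporting.
#' @param hsp_merge_window Max bp between HSP midpoints on one subject for
#'   them to count as a single locus (default 50 kb).
#' @return A `cascade_thresholds` list.
#' @export
cascade_thresholds <- function(e_strict = 1e-10, e_primary = 1e-6,
                               e_est_fallbacks = c(1e-30, 1e-20, 1e-5),
                               hsp_merge_window = 5e4) {
  stopifnot(e_strict <= e_primary, all(diff(e_est_fallbacks) > 0),
            hsp_merge_window > 0)
  structure(list(e_strict = e_strict, e_primary = e_primary,
                 e_est_fallbacks = e_est_fallbacks,
                 hsp_merge_window = hsp_merge_window),
            class = "cascade_thresholds")
}

#' Collapse the HSPs of one query into candidate loci
#'
#' BLAST reports a gene-scale match as several HSPs; HSPs on the same
#' subject whose midpoints lie within `hsp_merge_window` of the growing
#' locus span collapse into one locus, positioned at the midpoint of the
#' merged span. "A single hit at a single position" is then "exactly one
#' merged locus".
#'
#' @param hits A `hit_table` subset in which all rows share one `query_id`.
#' @param hsp_merge_window Merge window, bp.
#' @return A tibble (`subject_id`, `position`, `best_e_value`, `n_hsps`)
#'   sorted by `best_e_value`; empty input gives an empty tibble.
#' @examples
#' \dontrun{merge_hsps(hits[hits$query_id == "m0001", ], 5e4)}
#' @export
merge_hsps <- function(hits, hsp_merge_window = 5e4) {
  empty <- tibble::tibble(subject_id = character(), position = numeric(),
                          best_e_value = numeric(), n_hsps = integer())
  if (nrow(hits) == 0L) return(empty)
  stopifnot(length(unique(hits$query_id)) == 1L)
  lo <- pmin(hits$s_start, hits$s_end)
  hi <- pmax(hits$s_start, hits$s_end)
  d <- tibble::tibble(subject_id = hits$subject_id, lo = lo, hi = hi,
                      mid = (lo + hi) / 2, e = hits$e_value)
  loci <- dplyr::bind_rows(lapply(split(d, d$subject_id), function(s) {
    s <- s[order(s$mid), ]
    grp <- integer(nrow(s))
    grp[1L] <- 1L
    span_lo <- s$lo[1L]; span_hi <- s$hi[1L]
    for (i in seq_len(nrow(s))[-1L]) {
      if (s$mid[i] - (span_lo + span_hi) / 2 <= hsp_merge_window) {
        grp[i] <- grp[i - 1L]
        span_lo <- min(span_lo, s$lo[i]); span_hi <- max(span_hi, s$hi[i])
      } else {
        grp[i] <- grp[i - 1L] + 1L
        span_lo <- s$lo[i]; span_hi <- s$hi[i]
      }
    }
    dplyr::bind_rows(lapply(split(s, grp), function(g) {
      tibble::tibble(subject_id = g$subject_id[1L],
                     position = (min(g$lo) + max(g$hi)) / 2,
                     best_e_value = min(g$e), n_hsps = nrow(g))
    }))
  }))
  loci[order(loci$best_e_value, loci$subject_id, loci$position), ]
}

ortholog_statuses <- c("single_locus", "multi_locus", "chrom_unknown_position",
                       "unplaced_contig", "absent_primary_conserved_fallback",
                       "absent")

#' Assign orthology status to every query by the E-value cascade
#'
#' Hits at or below `e_primary` are merged per query into loci
#' ([merge_hsps()]). A query with exactly one locus is a putative single-locus
#' ortholog and carries a target position; with several loci (including
#' equal-E-value ties on different subjects) it is `multi_locus` and excluded
#' from synteny. Single loci landing on subjects listed as unplaced contigs or
#' as chromosome-known/position-unknown segments are set aside under their own
#' statuses. Queries with no primary hit are `absent`, unless a fallback
#' (EST/CDS) hit at or below the most permissive fallback cutoff rescues them
#' as `absent_primary_conserved_fallback` — bookkeeping only, never synteny
#' input.
#'
#' @param hits A `hit_table` of genomic hits.
#' @param thresholds A `cascade_thresholds`.
#' @param queries Character vector of all query ids (markers with no hit at
#'   all are tallied `absent`); defaults to the queries present in `hits`.
#' @param unplaced_subjects Subject ids that are unanchored contigs.
#' @param position_unknown_subjects Subject ids assigned to a chromosome but
#'   without a position.
#' @param fallback_hits Optional `hit_table` from the transcript/CDS
#'   searches.
#' @return An `ortholog_assignments` tibble (`marker_id`, `status`,
#'   `target_chromosome`, `target_bp`, `best_e_value`, `n_loci`) with a
#'   `tally` attribute (named integer counts per status, summing to the
#'   number of queries); see [assignment_tally()].
#' @export
assign_orthologs <- function(hits, thresholds = cascade_thresholds(),
                             queries = NULL, unplaced_subjects = character(0),
                             position_unknown_subjects = character(0),
                             fallback_hits = NULL) {
  queries <- sort(unique(c(queries, hits$query_id)))
  strong <- hits[hits$e_value <= thresholds$e_primary, ]
  fb_ok <- character(0L)
  if (!is.null(fallback_hits) && nrow(fallback_hits) > 0L) {
    fb_cut <- max(thresholds$e_est_fallbacks)
    fb_ok <- unique(fallback_hits$query_id[fallback_hits$e_value <= fb_cut])
  }
  rows <- lapply(queries, function(q) {
    h <- strong[strong$query_id == q, ]
    if (nrow(h) == 0L) {
      status <- if (q %in% fb_ok) "absent_primary_conserved_fallback" else "absent"
      return(tibble::tibble(marker_id = q, status = status,
                            target_chromosome = NA_character_,
                            target_bp = NA_real_, best_e_value = NA_real_,
                            n_loci = 0L))
    }
    loci <- merge_hsps(h, thresholds$hsp_merge_window)
    if (nrow(loci) > 1L) {
      return(tibble::tibble(marker_id = q, status = "multi_locus",
                            target_chromosome = NA_character_,
                            target_bp = NA_real_,
                            best_e_value = loci$best_e_value[1L],
                            n_loci = nrow(loci)))
    }
    status <- if (loci$subject_id %in% unplaced_subjects) "unplaced_contig"
              else if (loci$subject_id %in% position_unknown_subjects) "chrom_unknown_position"
              else "single_locus"
    tibble::tibble(marker_id = q, status = status,
                   target_chromosome = if (status == "single_locus") loci$subject_id else NA_character_,
                   target_bp = if (status == "single_locus") loci$position else NA_real_,
                   best_e_value = loci$best_e_value, n_loci = 1L)
  })
  out <- dplyr::bind_rows(rows)
  tal <- table(factor(out$status, levels = ortholog_statuses))
  structure(out, tally = stats::setNames(as.integer(tal), names(tal)),
            class = c("ortholog_assignments", class(out)))
}

#' Status tally of an assignment table
#'
#' @param assignments An `ortholog_assignments` tibble.
#' @return Named integer vector over all six statuses; sums to the number of
#'   queries.
#' @export
assignment_tally <- function(assignments) attr(assignments, "tally")

#' Write assignments as TSV and the tally as JSON
#'
#' @param assignments An `ortholog_assignments` tibble.
#' @param path Output TSV path.
#' @param tally_path Optional JSON path for the status tally.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path, tally_path = NULL) {
  df <- as.data.frame(assignments)[order(assignments$marker_id), ]
  df$best_e_value <- format(df$best_e_value, trim = TRUE, digits = 3)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tally_path)) {
    jsonlite::write_json(as.list(assignment_tally(assignments)), tally_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
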