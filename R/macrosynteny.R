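#' Derive the physical chaining gap from a gene-count window
#'
#' The maximum physical distance allowed between consecutive syntenic
#' markers is set so that the window holds about `gene_window` genes at the
#' target genome's mean gene density: `gene_window * genome_size_bp /
#' n_genes`. With the grapevine figures (475 Mb, 30,434 predicted genes) a
#' 200-gene window gives about 3.1 Mb, i.e. the operational 3.2 Mb setting.
#'
#' @param genome_size_bp Target genome size, bp (> 0).
#' @param n_genes Predicted gene count (> 0).
#' @param gene_window Genes a window should span (default 200).
#' @return Gap threshold in bp.
#' @examples
#' derive_physical_threshold(475e6, 30434, 200)
#' @export
derive_physical_threshold <- function(genome_size_bp, n_genes, gene_window = 200) {
  stopifnot(genome_size_bp > 0, gene_window > 0)
  if (n_genes <= 0) stop("n_genes must be positive", call. = FALSE)
  gene_window * genome_size_bp / n_genes
}

#' Genes contained in a physical window (inverse of the threshold rule)
#'
#' @param window_bp Window size, bp.
#' @inheritParams derive_physical_threshold
#' @return Expected gene count in the window.
#' @examples
#' genes_in_window(3.2e6, 475e6, 30434) # ~205, i.e. about 200 genes
#' @export
genes_in_window <- function(window_bp, genome_size_bp, n_genes) {
  stopifnot(window_bp >= 0, genome_size_bp > 0, n_genes >= 0)
  window_bp * n_genes / genome_size_bp
}

#' Derive the genetic chaining gap as a fraction of total map length
#'
#' Returns `map_fraction * map_length_cM` unrounded; whether to floor to an
#' integer cM (e.g. 14.63 used as 14) is an explicit policy of
#' [synteny_thresholds()], never silent.
#'
#' @param map_length_cM Total genetic map length, cM.
#' @param map_fraction Fraction of the map (default 0.01).
#' @return Gap threshold in cM, unrounded.
#' @examples
#' derive_genetic_threshold(1463, 0.01) # 14.63 -> floored to 14 by policy
#' @export
derive_genetic_threshold <- function(map_length_cM, map_fraction = 0.01) {
  stopifnot(map_length_cM > 0, map_fraction >= 0)
  map_fraction * map_length_cM
}

#' Chaining thresholds for conserved syntenic segments
#'
#' Defaults follow the comparative-mapping setting this package
#' operationalizes: at least 3 markers per segment, at most 3.2 Mb between
#' consecutive markers on the physical target and at most 12 cM (about 1
#' percent of a ~1350 cM map) on the genetic query. For a 1463 cM map the 1
#' percent rule gives 14.63, floored to 14 under `floor_to_int`.
#'
#' @param min_markers Minimum markers per block (>= 2).
#' @param max_gap_target_bp Max physical gap between consecutive chained
#'   markers, bp (used when the target is a physical genome).
#' @param max_gap_query_cM Max genetic gap on the query map, cM. If `NULL`,
#'   derived as `query_map_length_cM * map_fraction` when a map length is
#'   supplied, else the 12 cM default applies.
#' @param query_map_length_cM Optional total map length used for derivation.
#' @param map_fraction Fraction for the derivation rule (default 0.01).
#' @param floor_to_int Floor a derived cM threshold to an integer (default
#'   TRUE, recorded in the result).
#' @param max_gap_target_cM Genetic gap for the target side in map-vs-map
#'   comparisons (each map keeps its own threshold on its own axis).
#' @return A `synteny_thresholds` list.
#' @export
synteny_thresholds <- function(min_markers = 3, max_gap_target_bp = 3.2e6,
                               max_gap_query_cM = NULL,
                               query_map_length_cM = NULL, map_fraction = 0.01,
                               floor_to_int = TRUE, max_gap_target_cM = NULL) {
  if (is.null(max_gap_query_cM)) {
    if (!is.null(query_map_length_cM)) {
      raw <- derive_genetic_threshold(query_map_length_cM, map_fraction)
      max_gap_query_cM <- if (floor_to_int) floor(raw) else raw
    } else {
      max_gap_query_cM <- 12
    }
  }
  stopifnot(min_markers >= 2, max_gap_target_bp > 0, max_gap_query_cM > 0)
  structure(list(min_markers = min_markers,
                 max_gap_target_bp = max_gap_target_bp,
                 max_gap_query_cM = max_gap_query_cM,
                 max_gap_target_cM = max_gap_target_cM,
                 map_fraction = map_fraction, floor_to_int = floor_to_int),
            class = "synteny_thresholds")
}

# Greedy left-to-right chaining of one (query LG, target chromosome) marker
# set, sorted by query position (ties by marker id). A marker extends the
# open chain iff both gap constraints to the previous chained marker hold;
# a violation closes the chain and opens a new one. Chains are therefore
# maximal runs of consecutive markers with all adjacent gaps valid.
chain_pair <- function(d, max_gap_q, max_gap_t) {
  d <- d[order(d$query_cM, d$marker_id), ]
  n <- nrow(d)
  if (n == 0L) return(list())
  breaks <- which(diff(d$query_cM) > max_gap_q |
                  abs(diff(d$target_pos)) > max_gap_t)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  lapply(seq_along(starts), function(i) d[starts[i]:ends[i], ])
}

#' Detect conserved syntenic segments between a genetic map and a genome
#'
#' Single-locus assigned markers are grouped by (query linkage group, target
#' chromosome) and chained greedily in query order: consecutive chained
#' markers must lie within `max_gap_query_cM` on the map and within
#' `max_gap_target_bp` on the target (absolute distance — orientation-free,
#' so inverted segments chain). Chains with at least `min_markers` markers
#' become blocks. Query-map markers falling inside a block's query span
#' without being members (orthologs elsewhere, multi-locus, or absent) are
#' counted per block as interspersed non-syntenic markers; they do not reset
#' gaps.
#'
#' @param assignments An `ortholog_assignments` tibble; only `single_locus`
#'   rows are chained.
#' @param query_map A `genetic_map` giving each marker its (LG, cM) position.
#'   Markers assigned but absent from the map are skipped with a warning.
#' @param thresholds A `synteny_thresholds`.
#' @return A `synteny_blocks` tibble: one row per block with `query_lg`,
#'   `target_chromosome`, `n_syntenic`, `n_interspersed`, spans on both
#'   coordinate systems, and a `members` list-column of
#'   (`marker_id`, `query_cM`, `target_pos`) tibbles ordered by query
#'   position.
#' @export
detect_css <- function(assignments, query_map, thresholds = synteny_thresholds()) {
  single <- assignments[assignments$status == "single_locus", ]
  missing <- setdiff(single$marker_id, query_map$marker_id)
  if (length(missing) > 0L) {
    warning(length(missing), " single-locus marker(s) without a query map ",
            "placement were skipped (e.g. '", missing[1L], "')", call. = FALSE)
  }
  idx <- match(single$marker_id, query_map$marker_id)
  keep <- !is.na(idx)
  pairs <- tibble::tibble(marker_id = single$marker_id[keep],
                          query_lg = query_map$linkage_group[idx[keep]],
                          query_cM = query_map$position_cM[idx[keep]],
                          target_chromosome = single$target_chromosome[keep],
                          target_pos = single$target_bp[keep])
  blocks <- chain_blocks(pairs, thresholds, thresholds$max_gap_target_bp)
  add_interspersed(blocks, query_map, assignments)
}

chain_blocks <- function(pairs, thresholds, max_gap_t) {
  empty <- tibble::tibble(query_lg = character(), target_chromosome = character(),
                          n_syntenic = integer(), n_interspersed = integer(),
                          query_start = numeric(), query_end = numeric(),
                          span_query = numeric(), target_start = numeric(),
                          target_end = numeric(), span_target = numeric(),
                          members = list())
  if (nrow(pairs) == 0L) return(structure(empty, class = c("synteny_blocks", class(empty))))
  groups <- split(pairs, paste(pairs$query_lg, pairs$target_chromosome, sep = "\r"))
  groups <- groups[order(names(groups))]
  rows <- list()
  for (g in groups) {
    chains <- chain_pair(g, thresholds$max_gap_query_cM, max_gap_t)
    for (ch in chains) {
      if (nrow(ch) < thresholds$min_markers) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        query_lg = ch$query_lg[1L],
        target_chromosome = ch$target_chromosome[1L],
        n_syntenic = nrow(ch), n_interspersed = 0L,
        query_start = min(ch$query_cM), query_end = max(ch$query_cM),
        span_query = max(ch$query_cM) - min(ch$query_cM),
        target_start = min(ch$target_pos), target_end = max(ch$target_pos),
        span_target = max(ch$target_pos) - min(ch$target_pos),
        members = list(ch[, c("marker_id", "query_cM", "target_pos")])
      )
    }
  }
  out <- if (length(rows) > 0L) dplyr::bind_rows(rows) else empty
  out <- out[order(out$query_lg, out$query_start, out$target_chromosome), ]
  structure(out, class = c("synteny_blocks", setdiff(class(out), "synteny_blocks")))
}

add_interspersed <- function(blocks, query_map, assignments) {
  if (nrow(blocks) == 0L) return(blocks)
  mapped <- intersect(query_map$marker_id, assignments$marker_id)
  blocks$n_interspersed <- vapply(seq_len(nrow(blocks)), function(i) {
    in_span <- query_map$linkage_group == blocks$query_lg[i] &
      query_map$position_cM >= blocks$query_start[i] &
      query_map$position_cM <= blocks$query_end[i] &
      query_map$marker_id %in% mapped
    sum(in_span & !(query_map$marker_id %in% blocks$members[[i]]$marker_id))
  }, integer(1L))
  blocks
}

#' Detect syntenic blocks between two genetic maps
#'
#' Map-versus-map variant of [detect_css()] for comparisons where both
#' genomes are observed as genetic maps: shared markers are chained with a
#' cM gap constraint on each axis, each map keeping its own threshold
#' (`max_gap_query_cM` for `map_a`, `max_gap_target_cM` for `map_b`).
#'
#' @param map_a,map_b `genetic_map`s sharing marker ids.
#' @param thresholds A `synteny_thresholds` with `max_gap_target_cM` set.
#' @return A `synteny_blocks` tibble; target coordinates are cM on `map_b`.
#' @export
detect_css_maps <- function(map_a, map_b, thresholds = synteny_thresholds(
                              max_gap_query_cM = 12, max_gap_target_cM = 14)) {
  stopifnot(!is.null(thresholds$max_gap_target_cM))
  shared <- intersect(map_a$marker_id, map_b$marker_id)
  ia <- match(shared, map_a$marker_id)
  ib <- match(shared, map_b$marker_id)
  pairs <- tibble::tibble(marker_id = shared,
                          query_lg = map_a$linkage_group[ia],
                          query_cM = map_a$position_cM[ia],
                          target_chromosome = map_b$linkage_group[ib],
                          target_pos = map_b$position_cM[ib])
  chain_blocks(pairs, thresholds, thresholds$max_gap_target_cM)
}

#' Summarize a set of syntenic blocks
#'
#' Computes the Table-1-style descriptive statistics of one pairwise
#' comparison: marker and block counts, mean/max block spans on both
#' coordinate systems, mean/max syntenic markers per block, mean distance
#' between adjacent syntenic markers (pooled over all consecutive member
#' pairs of all blocks), and mean interspersed non-syntenic markers per
#' block.
#'
#' @param blocks A `synteny_blocks` tibble.
#' @param assignments Optional `ortholog_assignments`; supplies
#'   `n_orthologous_markers` (single-locus count). When absent, the number of
#'   distinct chained markers is reported.
#' @return A `block_summary` list of named scalars; an empty block set gives
#'   zeros with `n_css = 0`.
#' @export
summarize_blocks <- function(blocks, assignments = NULL) {
  n_orth <- if (!is.null(assignments)) {
    sum(assignments$status == "single_locus")
  } else if (nrow(blocks) > 0L) {
    length(unique(unlist(lapply(blocks$members, `[[`, "marker_id"))))
  } else 0L
  if (nrow(blocks) == 0L) {
    return(structure(list(n_orthologous_markers = n_orth, n_css = 0L,
                          n_markers_in_blocks = 0L,
                          mean_span_query = 0, max_span_query = 0,
                          mean_span_target = 0, max_span_target = 0,
                          mean_markers_per_block = 0, max_markers_per_block = 0L,
                          mean_adjacent_gap_query = 0, mean_adjacent_gap_target = 0,
                          mean_interspersed = 0),
                     class = "block_summary"))
  }
  gaps_q <- unlist(lapply(blocks$members, function(m) diff(m$query_cM)))
  gaps_t <- unlist(lapply(blocks$members, function(m) abs(diff(m$target_pos))))
  structure(list(
    n_orthologous_markers = n_orth,
    n_css = nrow(blocks),
    n_markers_in_blocks = sum(blocks$n_syntenic),
    mean_span_query = mean(blocks$span_query),
    max_span_query = max(blocks$span_query),
    mean_span_target = mean(blocks$span_target),
    max_span_target = max(blocks$span_target),
    mean_markers_per_block = mean(blocks$n_syntenic),
    max_markers_per_block = max(blocks$n_syntenic),
    mean_adjacent_gap_query = mean(gaps_q),
    mean_adjacent_gap_target = mean(gaps_t),
    mean_interspersed = mean(blocks$n_interspersed)
  ), class = "block_summary")
}

#' @export
print.block_summary <- function(x, ...) {
  cat("Syntenic block summary\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]], digits = 4)))
  invisible(x)
}

interval_overlap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

#' Triangulate two pairwise block sets on their shared reference genome
#'
#' Given blocks from comparisons A-vs-B and C-vs-B (both targeting genome
#' B), reports for every block pair on the same reference chromosome the
#' overlap of their target intervals (bp, continuous-length semantics) and
#' the Jaccard index, plus per-chromosome coverage: the fraction of each
#' reference chromosome covered by the union of block target spans from
#' either comparison. Chromosomes with zero coverage are flagged.
#'
#' @param blocks_ab,blocks_cb `synteny_blocks` targeting the same genome.
#' @param ref_lengths Named numeric vector of reference chromosome lengths,
#'   bp.
#' @return A list with `overlaps` (tibble: chromosome, block indices, the
#'   two intervals, `overlap_bp`, `jaccard`) and `coverage` (tibble:
#'   `chromosome`, `covered_bp`, `length_bp`, `fraction`, `uncovered`
#'   flag).
#' @export
project_multiway <- function(blocks_ab, blocks_cb, ref_lengths) {
  ov <- list()
  if (nrow(blocks_ab) > 0L && nrow(blocks_cb) > 0L) {
    for (i in seq_len(nrow(blocks_ab))) {
      for (j in seq_len(nrow(blocks_cb))) {
        if (blocks_ab$target_chromosome[i] != blocks_cb$target_chromosome[j]) next
        o <- interval_overlap(blocks_ab$target_start[i], blocks_ab$target_end[i],
                              blocks_cb$target_start[j], blocks_cb$target_end[j])
        un <- max(blocks_ab$target_end[i], blocks_cb$target_end[j]) -
          min(blocks_ab$target_start[i], blocks_cb$target_start[j])
        ov[[length(ov) + 1L]] <- tibble::tibble(
          chromosome = blocks_ab$target_chromosome[i],
          block_ab = i, block_cb = j,
          ab_start = blocks_ab$target_start[i], ab_end = blocks_ab$target_end[i],
          cb_start = blocks_cb$target_start[j], cb_end = blocks_cb$target_end[j],
          overlap_bp = o, jaccard = if (un > 0) o / un else 0)
      }
    }
  }
  overlaps <- if (length(ov) > 0L) dplyr::bind_rows(ov) else
    tibble::tibble(chromosome = character(), block_ab = integer(),
                   block_cb = integer(), ab_start = numeric(), ab_end = numeric(),
                   cb_start = numeric(), cb_end = numeric(),
                   overlap_bp = numeric(), jaccard = numeric())
  spans <- dplyr::bind_rows(
    blocks_ab[, c("target_chromosome", "target_start", "target_end")],
    blocks_cb[, c("target_chromosome", "target_start", "target_end")])
  coverage <- dplyr::bind_rows(lapply(names(ref_lengths), function(chrom) {
    s <- spans[spans$target_chromosome == chrom, ]
    cov <- 0
    if (nrow(s) > 0L) {
      s <- s[order(s$target_start), ]
      cur_s <- s$target_start[1L]; cur_e <- s$target_end[1L]
      for (k in seq_len(nrow(s))[-1L]) {
        if (s$target_start[k] <= cur_e) cur_e <- max(cur_e, s$target_end[k])
        else { cov <- cov + (cur_e - cur_s); cur_s <- s$target_start[k]; cur_e <- s$target_end[k] }
      }
      cov <- cov + (cur_e - cur_s)
    }
    tibble::tibble(chromosome = chrom, covered_bp = cov,
                   length_bp = unname(ref_lengths[chrom]),
                   fraction = cov / unname(ref_lengths[chrom]),
                   uncovered = cov == 0)
  }))
  list(overlaps = overlaps, coverage = coverage)
}
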