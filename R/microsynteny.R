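#' Construct an annotated gene segment
#'
#' The microsynteny input: an ordered, oriented, family-labelled gene list
#' for one genomic segment (a BAC clone or a genome slice). Family labels
#' are inputs, typically carried in a GFF3 attribute; genes without a family
#' are automatically lineage-specific in any comparison.
#'
#' @param genes Data frame with columns `gene_id`, `family` (character or
#'   `NA`), `orientation` (`"+"`/`"-"`), and optionally `order_index`
#'   (defaults to file order).
#' @param segment_id,species Identifying strings.
#' @return An `annotated_segment` tibble.
#' @export
annotated_segment <- function(genes, segment_id = "segment", species = NA_character_) {
  genes <- tibble::as_tibble(genes)
  if (!"order_index" %in% names(genes)) genes$order_index <- seq_len(nrow(genes))
  genes <- genes[order(genes$order_index),
                 c("gene_id", "family", "orientation", "order_index")]
  stopifnot(!anyDuplicated(genes$gene_id),
            all(genes$orientation %in% c("+", "-")),
            !is.unsorted(genes$order_index, strictly = TRUE))
  structure(genes, segment_id = segment_id, species = species,
            class = c("annotated_segment", class(genes)))
}

#' Read an annotated segment from GFF3
#'
#' Genes are ordered by start coordinate; the family label is read from a
#' configurable attribute key (absent attribute -> no family, i.e.
#' lineage-specific).
#'
#' @param path GFF3 file.
#' @param feature_kind GFF3 `type` to keep (default `"gene"`).
#' @param family_attr Attribute key holding the family label (default
#'   `"family"`).
#' @param segment_id,species Identifying strings (default: file name).
#' @return An `annotated_segment`.
#' @export
read_segment_gff3 <- function(path, feature_kind = "gene", family_attr = "family",
                              segment_id = NULL, species = NA_character_) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[as.character(gr$type) %in% feature_kind]
  gr <- gr[order(GenomicRanges::start(gr))]
  fam <- if (family_attr %in% names(GenomicRanges::mcols(gr))) {
    as.character(GenomicRanges::mcols(gr)[[family_attr]])
  } else rep(NA_character_, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  annotated_segment(
    tibble::tibble(gene_id = as.character(gr$ID), family = fam,
                   orientation = strand, order_index = seq_along(gr)),
    segment_id = segment_id %||% sub("\\.[^.]*$", "", basename(path)),
    species = species)
}

#' Reverse a segment and flip gene orientations
#'
#' The other physical reading of the same segment.
#'
#' @param seg An `annotated_segment`.
#' @return The reversed `annotated_segment`.
#' @export
reverse_and_flip <- function(seg) {
  annotated_segment(
    tibble::tibble(gene_id = rev(seg$gene_id), family = rev(seg$family),
                   orientation = ifelse(rev(seg$orientation) == "+", "-", "+"),
                   order_index = seq_len(nrow(seg))),
    segment_id = attr(seg, "segment_id"), species = attr(seg, "species"))
}

# leftmost-in-A maximum-length common subsequence over family labels;
# returns a 2-column matrix of (index in a, index in b)
lcs_backbone <- function(fa, fb) {
  m <- length(fa); n <- length(fb)
  # L[i+1, j+1] = LCS length of suffixes a[i..m], b[j..n]
  L <- matrix(0L, m + 1L, n + 1L)
  if (m == 0L || n == 0L) return(matrix(integer(0), 0L, 2L))
  for (i in m:1) {
    for (j in n:1) {
      L[i, j] <- if (!is.na(fa[i]) && !is.na(fb[j]) && fa[i] == fb[j]) {
        1L + L[i + 1L, j + 1L]
      } else {
        max(L[i + 1L, j], L[i, j + 1L])
      }
    }
  }
  pairs <- matrix(integer(0), 0L, 2L)
  i <- 1L; j <- 1L
  while (i <= m && j <= n) {
    if (!is.na(fa[i]) && !is.na(fb[j]) && fa[i] == fb[j] &&
        1L + L[i + 1L, j + 1L] == L[i, j]) {
      pairs <- rbind(pairs, c(i, j))
      i <- i + 1L; j <- j + 1L
    } else if (L[i + 1L, j] >= L[i, j + 1L]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  pairs
}

classify_reading <- function(segA, segB) {
  pairs <- lcs_backbone(segA$family, segB$family)
  n_match <- nrow(pairs)
  if (n_match > 0L) {
    same_orient <- segA$orientation[pairs[, 1L]] == segB$orientation[pairs[, 2L]]
    # consensus relative orientation is the majority over matched pairs;
    # exact ties default to the same-orientation reading
    consensus_same <- mean(same_orient) >= 0.5
    same <- same_orient == consensus_same
  } else {
    same <- logical(0)
  }
  list(pairs = pairs, n_match = n_match, same = same)
}

count_side <- function(seg, matched_idx) {
  un <- setdiff(seq_len(nrow(seg)), matched_idx)
  matched_fams <- seg$family[matched_idx]
  dup <- sum(!is.na(seg$family[un]) & seg$family[un] %in% matched_fams)
  list(duplicated = dup, specific = length(un) - dup, unmatched_idx = un,
       dup_idx = un[!is.na(seg$family[un]) & seg$family[un] %in% matched_fams])
}

#' Align two annotated segments and classify every gene
#'
#' The collinear backbone is a longest common subsequence of family labels
#' over gene order (deterministically the leftmost backbone in segment A;
#' one match per family occurrence). Matched pairs whose relative
#' orientation equals the backbone's consensus relative orientation are
#' `same_order_and_orientation`, the rest `inverted`. Unmatched genes whose
#' family does occur in the backbone are tandem `duplicated` copies;
#' remaining unmatched genes (including all genes without a family label)
#' are lineage-specific. With `allow_reverse_reading` the alignment is also
#' tried against the reversed-and-flipped B segment and the reading with the
#' larger backbone is reported (ties keep the forward reading).
#'
#' @param segA,segB `annotated_segment`s.
#' @param allow_reverse_reading Also try segment B reversed (default TRUE).
#' @return A `microsynteny_report` list: counts `matched_families`,
#'   `same_order_and_orientation`, `inverted`, `duplicated` (with per-side
#'   `duplicated_a`/`duplicated_b`), `a_specific`, `b_specific`; `reading`
#'   (`"forward"` or `"reverse"`); and `pairs`, a tibble of
#'   (`gene_a`, `gene_b`, `class`) covering every gene of both segments
#'   exactly once (unpaired genes carry `NA` on the other side).
#' @examples
#' a <- annotated_segment(data.frame(gene_id = c("a1", "a2", "a3"),
#'                                   family = c("f1", "f2", "f3"),
#'                                   orientation = c("+", "+", "+")))
#' b <- annotated_segment(data.frame(gene_id = c("b1", "b2", "b3"),
#'                                   family = c("f1", "f2", "f3"),
#'                                   orientation = c("+", "-", "+")))
#' align_segments(a, b)$inverted
#' @export
align_segments <- function(segA, segB, allow_reverse_reading = TRUE) {
  fwd <- classify_reading(segA, segB)
  reading <- "forward"
  segB_used <- segB
  if (allow_reverse_reading) {
    segB_rev <- reverse_and_flip(segB)
    rev_ <- classify_reading(segA, segB_rev)
    if (rev_$n_match > fwd$n_match) {
      fwd <- rev_; segB_used <- segB_rev; reading <- "reverse"
    }
  }
  pairs <- fwd$pairs
  ca <- count_side(segA, pairs[, 1L])
  cb <- count_side(segB_used, pairs[, 2L])
  pair_rows <- list()
  if (fwd$n_match > 0L) {
    pair_rows[[1L]] <- tibble::tibble(
      gene_a = segA$gene_id[pairs[, 1L]],
      gene_b = segB_used$gene_id[pairs[, 2L]],
      class = ifelse(fwd$same, "same_order_and_orientation", "inverted"))
  }
  side_rows <- function(seg, cs, col) {
    out <- list()
    if (length(cs$dup_idx) > 0L) {
      out[[1L]] <- tibble::tibble(gene = seg$gene_id[cs$dup_idx], class = "duplicated")
    }
    spec_idx <- setdiff(cs$unmatched_idx, cs$dup_idx)
    if (length(spec_idx) > 0L) {
      out[[2L]] <- tibble::tibble(gene = seg$gene_id[spec_idx],
                                  class = paste0(col, "_specific"))
    }
    dplyr::bind_rows(out)
  }
  ra <- side_rows(segA, ca, "a")
  rb <- side_rows(segB_used, cb, "b")
  if (!is.null(ra) && nrow(ra) > 0L) {
    pair_rows[[length(pair_rows) + 1L]] <-
      tibble::tibble(gene_a = ra$gene, gene_b = NA_character_, class = ra$class)
  }
  if (!is.null(rb) && nrow(rb) > 0L) {
    pair_rows[[length(pair_rows) + 1L]] <-
      tibble::tibble(gene_a = NA_character_, gene_b = rb$gene, class = rb$class)
  }
  pairs_tbl <- if (length(pair_rows) > 0L) dplyr::bind_rows(pair_rows) else
    tibble::tibble(gene_a = character(), gene_b = character(), class = character())
  structure(list(
    segment_a = attr(segA, "segment_id"), segment_b = attr(segB, "segment_id"),
    matched_families = fwd$n_match,
    same_order_and_orientation = sum(fwd$same),
    inverted = sum(!fwd$same),
    duplicated = ca$duplicated + cb$duplicated,
    duplicated_a = ca$duplicated, duplicated_b = cb$duplicated,
    a_specific = ca$specific, b_specific = cb$specific,
    reading = reading, pairs = pairs_tbl
  ), class = "microsynteny_report")
}

#' @export
print.microsynteny_report <- function(x, ...) {
  cat(sprintf("Microsynteny %s vs %s (%s reading)\n", x$segment_a, x$segment_b,
              x$reading))
  cat(sprintf("  matched %d (same order+orientation %d, inverted %d), ",
              x$matched_families, x$same_order_and_orientation, x$inverted))
  cat(sprintf("duplicated %d, specific %d/%d\n", x$duplicated, x$a_specific,
              x$b_specific))
  invisible(x)
}

#' Restrict a segment to an order-index window
#'
#' @param seg An `annotated_segment`.
#' @param bounds Length-2 integer interval of order indices (inclusive).
#' @return The restricted `annotated_segment`.
#' @export
window_segment <- function(seg, bounds) {
  keep <- seg$order_index >= bounds[1L] & seg$order_index <= bounds[2L]
  annotated_segment(
    tibble::tibble(gene_id = seg$gene_id[keep], family = seg$family[keep],
                   orientation = seg$orientation[keep],
                   order_index = seq_len(sum(keep))),
    segment_id = attr(seg, "segment_id"), species = attr(seg, "species"))
}

#' Re-align two segments restricted to overlapping windows
#'
#' Recomputes the full classification on the restricted gene lists (the
#' region where several species' sequenced segments overlap). Matched
#' counts can never exceed the unrestricted report's.
#'
#' @param segA,segB `annotated_segment`s.
#' @param boundsA,boundsB Order-index intervals (inclusive).
#' @param allow_reverse_reading Passed to [align_segments()].
#' @return A `microsynteny_report` for the windowed comparison.
#' @export
overlap_window <- function(segA, segB, boundsA, boundsB,
                           allow_reverse_reading = TRUE) {
  align_segments(window_segment(segA, boundsA), window_segment(segB, boundsB),
                 allow_reverse_reading = allow_reverse_reading)
}

#' All-pairs microsynteny reports for a set of segments
#'
#' @param segments Named list of `annotated_segment`s (>= 2).
#' @param allow_reverse_reading Passed to [align_segments()].
#' @return A list with `matched`, a symmetric matrix of matched-family
#'   counts (diagonal = self-identity), and `reports`, a tibble of one row
#'   per unordered pair with a `report` list-column.
#' @export
multi_segment_matrix <- function(segments, allow_reverse_reading = TRUE) {
  stopifnot(length(segments) >= 2L, !is.null(names(segments)))
  nm <- names(segments)
  mat <- matrix(NA_integer_, length(nm), length(nm), dimnames = list(nm, nm))
  rows <- list()
  for (i in seq_along(nm)) {
    for (j in i:length(nm)) {
      rep_ <- align_segments(segments[[i]], segments[[j]],
                             allow_reverse_reading = allow_reverse_reading)
      mat[i, j] <- mat[j, i] <- rep_$matched_families
      if (j > i) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          segment_a = nm[i], segment_b = nm[j],
          matched = rep_$matched_families,
          same_order_and_orientation = rep_$same_order_and_orientation,
          inverted = rep_$inverted, duplicated = rep_$duplicated,
          a_specific = rep_$a_specific, b_specific = rep_$b_specific,
          report = list(rep_))
      }
    }
  }
  list(matched = mat, reports = dplyr::bind_rows(rows))
}

#' Group genes into families from a similarity matrix (fixture helper)
#'
#' Single-linkage grouping of genes whose pairwise similarity meets a
#' cutoff; intended for building small test fixtures, not for sequence-level
#' family inference (families are normally an input).
#'
#' @param sim Symmetric numeric matrix with gene ids as dimnames.
#' @param cutoff Minimum similarity joining two genes into one family.
#' @return Named character vector mapping gene id to family label.
#' @export
families_from_similarity <- function(sim, cutoff) {
  stopifnot(is.matrix(sim), !is.null(rownames(sim)))
  ids <- rownames(sim)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && sim[i, j] >= cutoff) parent[max(find(i), find(j))] <- min(find(i), find(j))
    }
  }
  roots <- vapply(seq_along(ids), find, 0L)
  stats::setNames(sprintf("fam%02d", match(roots, unique(roots))), ids)
}
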