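# Independent oracles used to check the package's algorithms by brute force.

# All maximal contiguous windows (in query-sorted order) in which every
# consecutive marker pair satisfies both gap constraints, keeping windows
# with at least `min_markers` markers. Enumerates every window and filters
# non-maximal ones — independent of the package's greedy chaining.
oracle_chains <- function(df, max_gap_q, max_gap_t, min_markers) {
  df <- df[order(df$query_cM, df$marker_id), ]
  n <- nrow(df)
  ok_pair <- function(i, j) {
    df$query_cM[j] - df$query_cM[i] <= max_gap_q &&
      abs(df$target_pos[j] - df$target_pos[i]) <= max_gap_t
  }
  valid <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      valid[i, j] <- if (j == i) TRUE else
        valid[i, j - 1L] && ok_pair(j - 1L, j)
    }
  }
  wins <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!valid[i, j]) next
      left_ext <- i > 1L && valid[i - 1L, j]
      right_ext <- j < n && valid[i, j + 1L]
      if (!left_ext && !right_ext && (j - i + 1L) >= min_markers) {
        wins[[length(wins) + 1L]] <- df$marker_id[i:j]
      }
    }
  }
  wins
}

# Memoized recursive longest-common-subsequence length over family labels
# (NA labels never match).
oracle_lcs <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > length(a) || j > length(b)) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (!is.na(a[i]) && !is.na(b[j]) && a[i] == b[j]) {
      1L + rec(i + 1L, j + 1L)
    } else {
      max(rec(i + 1L, j), rec(i, j + 1L))
    }
    memo[[key]] <- res
    res
  }
  rec(1L, 1L)
}

ordered_ids <- function(g) {
  d <- g[!g$is_paralog, ]
  d <- d[order(match(d$chromosome, attr(g, "chrom_order")), d$pos_bp), ]
  split(d$marker_id, factor(d$chromosome, levels = attr(g, "chrom_order")),
        drop = TRUE)
}

# Minimum number of parts in a partition of the shared markers where every
# part is a run in the all-shared ancestral order, sits on one chromosome in
# each descendant, and is a run among its own chromosome-pair group's
# markers in each descendant. Parts are ancestral runs, so the optimum
# decomposes into an interval-partition DP per ancestral chromosome.
oracle_true_block_count <- function(anc, ga, gb) {
  shared <- intersect(ga$marker_id[!ga$is_paralog], gb$marker_id[!gb$is_paralog])
  oa <- ordered_ids(ga); ob <- ordered_ids(gb); oanc <- ordered_ids(anc)
  chrom_of <- function(ord) {
    stats::setNames(rep(names(ord), lengths(ord)), unlist(ord, use.names = FALSE))
  }
  chromA <- chrom_of(oa)[shared]
  chromB <- chrom_of(ob)[shared]
  grp <- stats::setNames(paste(chromA, chromB), shared)
  seqA <- unlist(oa, use.names = FALSE); seqA <- seqA[seqA %in% shared]
  seqB <- unlist(ob, use.names = FALSE); seqB <- seqB[seqB %in% shared]
  is_run_in <- function(p, seq_all) {
    gseq <- seq_all[grp[seq_all] == grp[p[1L]]]
    idx <- match(p, gseq)
    !anyNA(idx) && max(idx) - min(idx) + 1L == length(p)
  }
  part_valid <- function(p) {
    length(unique(chromA[p])) == 1L && length(unique(chromB[p])) == 1L &&
      is_run_in(p, seqA) && is_run_in(p, seqB)
  }
  total <- 0L
  for (S in oanc) {
    S <- S[S %in% shared]
    n <- length(S)
    if (n == 0L) next
    best <- c(0L, rep(.Machine$integer.max, n))
    for (j in seq_len(n)) {
      for (i in seq_len(j)) {
        if (best[i] < .Machine$integer.max && part_valid(S[i:j])) {
          best[j + 1L] <- min(best[j + 1L], best[i] + 1L)
        }
      }
    }
    total <- total + best[n + 1L]
  }
  total
}

# deterministic hand-built genome for truth tests: markers at fixed 100 kb
# spacing, in the given per-chromosome order
mk_genome <- function(chrom_list, lineage = "X") {
  rows <- lapply(names(chrom_list), function(ch) {
    ids <- chrom_list[[ch]]
    tibble::tibble(feature_id = ids, marker_id = ids, chromosome = ch,
                   pos_bp = 1e5 * seq_along(ids), is_paralog = FALSE)
  })
  g <- dplyr::bind_rows(rows)
  structure(g, chrom_order = names(chrom_list),
            class = c("marker_genome", class(g)))
}

# minimal assignments table accepted by detect_css
mk_assignments <- function(marker_id, chrom, bp) {
  tibble::tibble(marker_id = marker_id, status = "single_locus",
                 target_chromosome = chrom, target_bp = bp,
                 best_e_value = 1e-30, n_loci = 1L)
}

mk_map <- function(marker_id, lg, cM, name = "test") {
  genetic_map(tibble::tibble(marker_id = marker_id, linkage_group = lg,
                             position_cM = cM), map_name = name)
}

mk_segment <- function(families, orientations = NULL, id = "seg") {
  n <- length(families)
  if (is.null(orientations)) orientations <- rep("+", n)
  annotated_segment(tibble::tibble(
    gene_id = sprintf("%s_g%02d", id, seq_len(n)),
    family = families, orientation = orientations,
    order_index = seq_len(n)), segment_id = id)
}

# one BLAST outfmt-6 row with controllable fields
mk_hit <- function(query, subject, sstart, send, evalue) {
  tibble::tibble(query_id = query, subject_id = subject, pct_identity = 98,
                 aln_length = abs(send - sstart) + 1, mismatches = 0,
                 gap_opens = 0, q_start = 1, q_end = 500,
                 s_start = sstart, s_end = send, e_value = evalue,
                 bit_score = 500)
}

mk_hit_table <- function(...) {
  tab <- dplyr::bind_rows(...)
  structure(tab, class = c("hit_table", class(tab)))
}
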