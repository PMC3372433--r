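#' @title Genome-rearrangement simulator
#' @description Generates ground-truthed synthetic inputs for the pipeline:
#'   an ancestral marker genome evolved along independent lineages by
#'   inversions, reciprocal translocations, fusions and fissions, with marker
#'   loss and paralog noise, observed either as a genetic map (cM) or as a
#'   physical genome (bp), together with a noisy BLAST-style hit table and the
#'   true orthology/block structure for recovery scoring.
#' @name synthetic_data
NULL

# Run code under a fixed seed without touching the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

marker_genome <- function(df, chrom_order = unique(df$chromosome)) {
  df <- tibble::as_tibble(df)[, c("feature_id", "marker_id", "chromosome",
                                  "pos_bp", "is_paralog")]
  structure(df, chrom_order = chrom_order,
            class = c("marker_genome", class(df)))
}

# ordered marker ids per chromosome (paralogs excluded), as a named list
chrom_orders <- function(genome, include_paralogs = FALSE) {
  df <- genome[order(match(genome$chromosome, attr(genome, "chrom_order")),
                     genome$pos_bp), ]
  if (!include_paralogs) df <- df[!df$is_paralog, ]
  split(df$marker_id, factor(df$chromosome, levels = attr(genome, "chrom_order")),
        drop = TRUE)
}

draw_gaps <- function(n, mean_gap_bp) pmax(1L, round(stats::rexp(n, 1 / mean_gap_bp)))

# turn per-chromosome ordered marker id lists into a marker_genome with
# freshly drawn exponential inter-marker spacings
place_markers <- function(chrom_list, mean_gap_bp, paralog_of = character(0)) {
  rows <- lapply(names(chrom_list), function(chrom) {
    ids <- chrom_list[[chrom]]
    if (length(ids) == 0L) return(NULL)
    tibble::tibble(feature_id = ids,
                   marker_id = sub("_p[0-9]+$", "", ids),
                   chromosome = chrom,
                   pos_bp = cumsum(draw_gaps(length(ids), mean_gap_bp)),
                   is_paralog = ids %in% paralog_of)
  })
  marker_genome(dplyr::bind_rows(rows), chrom_order = names(chrom_list))
}

#' Simulate an ancestral marker genome
#'
#' Markers are points on chromosomes; inter-marker gaps are i.i.d.
#' exponential with mean `mean_gap_bp`, emulating a dense set of mapped
#' single-copy gene markers.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param markers_per_chromosome Markers on each chromosome (>= 1).
#' @param mean_gap_bp Mean physical gap between adjacent markers, bp.
#' @param seed Integer seed; the same call with the same seed reproduces the
#'   genome exactly.
#' @return A `marker_genome` tibble (`feature_id`, `marker_id`, `chromosome`,
#'   `pos_bp`, `is_paralog`) with a `chrom_order` attribute.
#' @examples
#' anc <- simulate_ancestor(2, 5, 5e5, seed = 1)
#' table(anc$chromosome)
#' @export
simulate_ancestor <- function(n_chromosomes, markers_per_chromosome,
                              mean_gap_bp = 5e5, seed) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1, mean_gap_bp > 0)
  n <- n_chromosomes * markers_per_chromosome
  ids <- sprintf("m%04d", seq_len(n))
  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  chrom_list <- split(ids, rep(chroms, each = markers_per_chromosome))
  g <- with_seed(seed, place_markers(chrom_list[chroms], mean_gap_bp))
  attr(g, "mean_gap_bp") <- mean_gap_bp
  g
}

# --- rearrangement events on per-chromosome ordered marker lists ----------

apply_inversion <- function(cl) {
  ok <- names(cl)[lengths(cl) >= 2L]
  if (length(ok) == 0L) return(list(cl = cl, detail = NA_character_))
  chrom <- sample(ok, 1L)
  n <- length(cl[[chrom]])
  ij <- sort(sample.int(n, 2L))
  cl[[chrom]][ij[1L]:ij[2L]] <- rev(cl[[chrom]][ij[1L]:ij[2L]])
  list(cl = cl, detail = sprintf("%s:%d-%d", chrom, ij[1L], ij[2L]))
}

apply_translocation <- function(cl) {
  ok <- names(cl)[lengths(cl) >= 2L]
  if (length(ok) < 2L) return(list(cl = cl, detail = NA_character_))
  ch <- sample(ok, 2L)
  n1 <- length(cl[[ch[1L]]]); n2 <- length(cl[[ch[2L]]])
  b1 <- sample.int(n1 - 1L, 1L); b2 <- sample.int(n2 - 1L, 1L)
  head1 <- cl[[ch[1L]]][seq_len(b1)]; tail1 <- cl[[ch[1L]]][-seq_len(b1)]
  head2 <- cl[[ch[2L]]][seq_len(b2)]; tail2 <- cl[[ch[2L]]][-seq_len(b2)]
  cl[[ch[1L]]] <- c(head1, tail2)
  cl[[ch[2L]]] <- c(head2, tail1)
  list(cl = cl, detail = sprintf("%s:%d<->%s:%d", ch[1L], b1, ch[2L], b2))
}

apply_fusion <- function(cl) {
  if (length(cl) < 2L) return(list(cl = cl, detail = NA_character_))
  ch <- sample(names(cl), 2L)
  cl[[ch[1L]]] <- c(cl[[ch[1L]]], cl[[ch[2L]]])
  cl[[ch[2L]]] <- NULL
  list(cl = cl, detail = sprintf("%s+%s", ch[1L], ch[2L]))
}

apply_fission <- function(cl) {
  ok <- names(cl)[lengths(cl) >= 2L]
  if (length(ok) == 0L) return(list(cl = cl, detail = NA_character_))
  chrom <- sample(ok, 1L)
  n <- length(cl[[chrom]])
  b <- sample.int(n - 1L, 1L)
  new_name <- paste0(chrom, "f")
  while (new_name %in% names(cl)) new_name <- paste0(new_name, "f")
  cl[[new_name]] <- cl[[chrom]][-seq_len(b)]
  cl[[chrom]] <- cl[[chrom]][seq_len(b)]
  list(cl = cl, detail = sprintf("%s:%d", chrom, b))
}

evolve_lineage <- function(chrom_list, n_events, kind_weights, marker_loss_rate,
                           paralog_rate, mean_gap_bp, lineage) {
  kinds <- names(kind_weights)
  log <- tibble::tibble(lineage = character(), kind = character(),
                        detail = character())
  if (n_events > 0L) {
    drawn <- sample(kinds, n_events, replace = TRUE, prob = kind_weights)
    for (kind in drawn) {
      res <- switch(kind,
                    inversion = apply_inversion(chrom_list),
                    translocation = apply_translocation(chrom_list),
                    fusion = apply_fusion(chrom_list),
                    fission = apply_fission(chrom_list),
                    stop("unknown event kind: ", kind))
      chrom_list <- res$cl
      if (!is.na(res$detail)) {
        log <- dplyr::bind_rows(log, tibble::tibble(lineage = lineage,
                                                    kind = kind,
                                                    detail = res$detail))
      }
    }
  }
  all_ids <- unlist(chrom_list, use.names = FALSE)
  lost <- all_ids[stats::runif(length(all_ids)) < marker_loss_rate]
  chrom_list <- lapply(chrom_list, function(ids) setdiff(ids, lost))
  chrom_list <- chrom_list[lengths(chrom_list) > 0L]
  # paralog copies are extra physical features inserted at random positions;
  # they never appear on genetic maps (map loci are the true marker loci)
  surv <- unlist(chrom_list, use.names = FALSE)
  par_src <- surv[stats::runif(length(surv)) < paralog_rate]
  par_ids <- character(0L)
  for (m in par_src) {
    pid <- paste0(m, "_p1")
    chrom <- sample(names(chrom_list), 1L)
    at <- sample.int(length(chrom_list[[chrom]]) + 1L, 1L)
    chrom_list[[chrom]] <- append(chrom_list[[chrom]], pid, after = at - 1L)
    par_ids <- c(par_ids, pid)
  }
  # stable lineage-local chromosome names, in current order
  names(chrom_list) <- sprintf("%s_chr%02d", lineage, seq_along(chrom_list))
  genome <- place_markers(chrom_list, mean_gap_bp, paralog_of = par_ids)
  attr(genome, "mean_gap_bp") <- mean_gap_bp
  list(genome = genome, lost = lost,
       paralogs = tibble::tibble(lineage = rep(lineage, length(par_ids)),
                                 marker_id = sub("_p[0-9]+$", "", par_ids),
                                 feature_id = par_ids),
       events = log)
}

#' Evolve two descendant genomes from a common ancestor
#'
#' Each lineage independently accumulates `n_events_per_lineage` large-scale
#' rearrangements (kinds drawn with `kind_weights`; breakpoints always fall
#' between markers), then loses each marker with probability
#' `marker_loss_rate` and gains a paralogous physical copy of each surviving
#' marker with probability `paralog_rate`. Physical spacings are redrawn per
#' descendant. The returned truth set records the one-to-one orthology, the
#' losses and paralogs per lineage, the event log, and the true conserved
#' blocks: the coarsest partition of shared markers into parts whose marker
#' set is contiguous on a single chromosome in both descendants (so an
#' inversion does not split a block, while a reciprocal translocation adds
#' exactly two).
#'
#' @param ancestor A `marker_genome` from [simulate_ancestor()].
#' @param n_events_per_lineage Rearrangement count per lineage; a length-2
#'   vector gives each lineage its own count.
#' @param kind_weights Named sampling weights over
#'   `inversion`, `translocation`, `fusion`, `fission`.
#' @param marker_loss_rate,paralog_rate Per-marker probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @param lineages Two lineage name prefixes for descendant chromosomes.
#' @return A list with elements `descendant_a`, `descendant_b`
#'   (`marker_genome`s) and `truth` (a `truth_set` list: `pairs`, `lost_a`,
#'   `lost_b`, `paralogs`, `events`, `true_blocks`).
#' @examples
#' anc <- simulate_ancestor(2, 8, seed = 1)
#' sim <- evolve(anc, n_events_per_lineage = 1, marker_loss_rate = 0,
#'               paralog_rate = 0, seed = 2)
#' table(sim$truth$true_blocks$block_id)
#' @export
evolve <- function(ancestor, n_events_per_lineage = 8,
                   kind_weights = c(inversion = 0.4, translocation = 0.4,
                                    fusion = 0.1, fission = 0.1),
                   marker_loss_rate = 0.1, paralog_rate = 0.05, seed,
                   lineages = c("A", "B")) {
  stopifnot(marker_loss_rate >= 0, marker_loss_rate <= 1,
            paralog_rate >= 0, paralog_rate <= 1, length(lineages) == 2L)
  mean_gap_bp <- attr(ancestor, "mean_gap_bp") %||% 5e5
  n_ev <- rep(n_events_per_lineage, length.out = 2L)
  with_seed(seed, {
    base <- chrom_orders(ancestor)
    la <- evolve_lineage(base, n_ev[1L], kind_weights,
                         marker_loss_rate, paralog_rate, mean_gap_bp, lineages[1L])
    lb <- evolve_lineage(base, n_ev[2L], kind_weights,
                         marker_loss_rate, paralog_rate, mean_gap_bp, lineages[2L])
    truth <- make_truth(ancestor, la, lb)
    list(descendant_a = la$genome, descendant_b = lb$genome, truth = truth)
  })
}

make_truth <- function(ancestor, la, lb) {
  shared <- intersect(la$genome$marker_id[!la$genome$is_paralog],
                      lb$genome$marker_id[!lb$genome$is_paralog])
  blocks <- true_blocks(ancestor, la$genome, lb$genome, shared)
  structure(list(
    pairs = tibble::tibble(marker_id = blocks$marker_id,
                           feature_id = blocks$marker_id),
    lost_a = la$lost, lost_b = lb$lost,
    paralogs = dplyr::bind_rows(la$paralogs, lb$paralogs),
    events = dplyr::bind_rows(la$events, lb$events),
    true_blocks = blocks
  ), class = "truth_set")
}

# Coarsest partition of `shared` markers into maximal conserved ancestral
# segments: each part must be (i) a set-run in the all-shared ancestral
# marker order — so segments glued convergently in both lineages still count
# as separate blocks, (ii) on a single chromosome in each descendant, and
# (iii) a set-run among the markers of its own (chromosome-in-A x
# chromosome-in-B) group in each descendant — markers of other groups may
# intersperse it (they are exactly the interspersed non-syntenic markers the
# chaining rule tolerates) without splitting it. Fixpoint refinement over
# the three order systems; every split is forced, so the result is the
# unique coarsest such partition.
true_blocks <- function(ancestor, genome_a, genome_b, shared) {
  chrom_of <- lapply(list(genome_a, genome_b), function(g) {
    df <- g[!g$is_paralog & g$marker_id %in% shared, ]
    stats::setNames(df$chromosome, df$marker_id)
  })
  group <- stats::setNames(paste(chrom_of[[1L]][shared], chrom_of[[2L]][shared]),
                           shared)
  anc_seqs <- lapply(chrom_orders(ancestor), function(ids) ids[ids %in% shared])
  group_seqs <- lapply(list(genome_a, genome_b), function(g) {
    full <- unlist(chrom_orders(g), use.names = FALSE)
    lapply(split(shared, group), function(ids_g) full[full %in% ids_g])
  })
  seqs <- c(anc_seqs, group_seqs[[1L]], group_seqs[[2L]])
  names(seqs) <- sprintf("s%03d", seq_along(seqs))
  part <- group
  repeat {
    n_before <- length(unique(part))
    for (sn in names(seqs)) {
      ids <- seqs[[sn]]
      if (length(ids) == 0L) next
      labs <- part[ids]
      runs <- cumsum(c(TRUE, labs[-1L] != labs[-length(labs)]))
      part[ids] <- paste(labs, sn, runs)
    }
    if (length(unique(part)) == n_before) break
  }
  # order blocks and members along descendant A
  ord_a <- unlist(chrom_orders(genome_a), use.names = FALSE)
  ord_a <- ord_a[ord_a %in% shared]
  part <- part[ord_a]
  tibble::tibble(marker_id = ord_a,
                 block_id = as.integer(factor(part, levels = unique(part))))
}

#' Project a descendant genome onto a genetic map
#'
#' Marker bp positions are converted to cM with a locally varying
#' recombination rate: each inter-marker physical gap gets its own rate drawn
#' from a normal distribution (truncated away from zero), so the jitter is
#' rank-preserving — marker order on the map always equals physical order.
#' Paralog copies are physical-only features and are not placed on the map.
#'
#' @param descendant A `marker_genome`.
#' @param cM_per_Mb_mean Mean recombination rate, cM per Mb (> 0).
#' @param cM_per_Mb_sd Rate standard deviation; 0 gives exact linearity.
#' @param seed Integer seed.
#' @param map_name Name for the resulting map.
#' @return A `genetic_map`; linkage groups are the descendant's chromosomes.
#' @export
project_genetic <- function(descendant, cM_per_Mb_mean = 2, cM_per_Mb_sd = 0.5,
                            seed, map_name = "simulated") {
  stopifnot(cM_per_Mb_mean > 0, cM_per_Mb_sd >= 0)
  with_seed(seed, {
    df <- descendant[!descendant$is_paralog, ]
    df <- df[order(match(df$chromosome, attr(descendant, "chrom_order")), df$pos_bp), ]
    rows <- lapply(split(df, factor(df$chromosome, levels = unique(df$chromosome))),
                   function(d) {
      gaps_mb <- diff(c(0, d$pos_bp)) / 1e6
      rates <- stats::rnorm(length(gaps_mb), cM_per_Mb_mean, cM_per_Mb_sd)
      rates <- pmax(rates, 0.05 * cM_per_Mb_mean)
      d$position_cM <- round(cumsum(gaps_mb * rates), 2)
      d
    })
    df <- dplyr::bind_rows(rows)
    genetic_map(tibble::tibble(marker_id = df$marker_id,
                               linkage_group = df$chromosome,
                               position_cM = df$position_cM),
                map_name = map_name)
  })
}

#' Physical placement table of a simulated genome
#'
#' Each marker (and paralog copy) becomes a 500 bp feature starting at its
#' point position, suitable for the BED/GFF3 writers and for supplying the
#' subject universe to the orthology cascade.
#'
#' @param genome A `marker_genome`.
#' @return A `physical_placement` tibble.
#' @export
as_physical_table <- function(genome) {
  physical_table(tibble::tibble(feature_id = genome$feature_id,
                                chromosome = genome$chromosome,
                                start = genome$pos_bp,
                                end = genome$pos_bp + 499L,
                                strand = "+"))
}

#' Emit a BLAST-style hit table for simulated orthologs
#'
#' Every surviving ortholog pair yields one strong hit at its true position
#' on the target genome (E-values drawn as `10^U(log10_evalue_range)`, below
#' the strict 1e-10 cutoff by default). Paralog copies on the target yield an
#' additional comparable hit for their source marker, and
#' `n_spurious_multihit` further markers receive a second hit at a random
#' position, so the single-locus exclusion is exercised. Markers lost on the
#' target yield no rows.
#'
#' @param truth A `truth_set` from [evolve()].
#' @param target A `marker_genome`, the lineage observed as a physical genome.
#' @param query_map Optional `genetic_map` for the query lineage; only
#'   markers on the map emit hits (default: all truth pairs).
#' @param log10_evalue_range Length-2 numeric, log10 E-value range for true
#'   hits.
#' @param n_spurious_multihit Count of extra markers given a second,
#'   spurious locus.
#' @param seed Integer seed.
#' @return A `hit_table`.
#' @export
emit_hits <- function(truth, target, query_map = NULL,
                      log10_evalue_range = c(-50, -20),
                      n_spurious_multihit = 0, seed) {
  with_seed(seed, {
    queries <- truth$pairs$marker_id
    if (!is.null(query_map)) queries <- intersect(queries, query_map$marker_id)
    feats <- target[target$marker_id %in% queries, ]
    feats <- feats[order(feats$feature_id), ]
    hit_row <- function(q, chrom, pos, lo = log10_evalue_range) {
      fwd <- stats::runif(1) < 0.5
      tibble::tibble(query_id = q, subject_id = chrom,
                     pct_identity = round(stats::runif(1, 85, 100), 2),
                     aln_length = 500, mismatches = 0, gap_opens = 0,
                     q_start = 1, q_end = 500,
                     s_start = if (fwd) pos - 249 else pos + 250,
                     s_end = if (fwd) pos + 250 else pos - 249,
                     e_value = 10^stats::runif(1, lo[1L], lo[2L]),
                     bit_score = round(stats::runif(1, 200, 900), 1))
    }
    rows <- lapply(seq_len(nrow(feats)), function(i) {
      hit_row(feats$marker_id[i], feats$chromosome[i], feats$pos_bp[i])
    })
    if (n_spurious_multihit > 0) {
      multi_free <- setdiff(queries, truth$paralogs$marker_id)
      picked <- sample(multi_free, min(n_spurious_multihit, length(multi_free)))
      chroms <- attr(target, "chrom_order")
      extra <- lapply(picked, function(q) {
        hit_row(q, sample(chroms, 1L),
                round(stats::runif(1, 1e6, max(target$pos_bp))),
                lo = c(-15, -8))
      })
      rows <- c(rows, extra)
    }
    tab <- dplyr::bind_rows(rows)
    tab <- tab[order(tab$query_id, tab$e_value), ]
    hit_table(tab)
  })
}

#' Emit EST/CDS fallback hits for markers absent from the target genome
#'
#' Models the relaxed-threshold transcript searches used to rescue markers
#' with no genomic hit: a fraction of the markers lost on the target lineage
#' get a hit against an unplaced transcript subject, with E-values passing
#' the most permissive fallback cutoff. These feed only the
#' conserved-by-fallback bookkeeping, never synteny.
#'
#' @param truth A `truth_set`.
#' @param fraction Fraction of target-lost markers rescued.
#' @param log10_evalue_range log10 E-value range of fallback hits.
#' @param seed Integer seed.
#' @return A `hit_table` (possibly empty).
#' @export
emit_fallback_hits <- function(truth, fraction = 0.5,
                               log10_evalue_range = c(-20, -6), seed) {
  with_seed(seed, {
    lost <- sort(truth$lost_b)
    picked <- lost[stats::runif(length(lost)) < fraction]
    if (length(picked) == 0L) {
      return(read_hit_table(tempfile_empty()))
    }
    tab <- dplyr::bind_rows(lapply(seq_along(picked), function(i) {
      tibble::tibble(query_id = picked[i],
                     subject_id = sprintf("EST_%04d", i),
                     pct_identity = round(stats::runif(1, 80, 98), 2),
                     aln_length = 300, mismatches = 5, gap_opens = 1,
                     q_start = 1, q_end = 300, s_start = 1, s_end = 300,
                     e_value = 10^stats::runif(1, log10_evalue_range[1L],
                                               log10_evalue_range[2L]),
                     bit_score = round(stats::runif(1, 50, 300), 1))
    }))
    hit_table(tab)
  })
}

tempfile_empty <- function() {
  tf <- tempfile(fileext = ".tsv")
  file.create(tf)
  tf
}

#' Score detected blocks against the simulator truth
#'
#' Measures how well detected conserved syntenic segments recover the
#' implanted block structure. Truth pairs are consecutive pairs of markers
#' within a true block, ordered along the query lineage and restricted to
#' markers in `eligible` (typically the single-locus assigned markers, so the
#' score isolates the chaining stage from the orthology cascade). A pair is
#' recovered when both markers sit in the same detected block; a false merge
#' is a detected block containing markers from more than one true block.
#'
#' @param blocks A `synteny_blocks` tibble from [detect_css()].
#' @param truth A `truth_set`.
#' @param eligible Character vector of markers eligible for chaining;
#'   defaults to all shared markers.
#' @return A list: `n_truth_pairs`, `n_recovered`, `pair_coverage`,
#'   `n_false_merges`, `n_blocks`.
#' @export
score_block_recovery <- function(blocks, truth, eligible = NULL) {
  tb <- truth$true_blocks
  if (!is.null(eligible)) tb <- tb[tb$marker_id %in% eligible, ]
  membership <- if (nrow(blocks) > 0L) {
    stats::setNames(rep(seq_len(nrow(blocks)),
                        vapply(blocks$members, nrow, 0L)),
                    unlist(lapply(blocks$members, `[[`, "marker_id")))
  } else stats::setNames(integer(0), character(0))
  pairs <- do.call(rbind, lapply(split(tb$marker_id, tb$block_id), function(ids) {
    if (length(ids) < 2L) return(NULL)
    cbind(ids[-length(ids)], ids[-1L])
  }))
  n_pairs <- if (is.null(pairs)) 0L else nrow(pairs)
  recovered <- if (n_pairs == 0L) 0L else {
    b1 <- membership[pairs[, 1L]]; b2 <- membership[pairs[, 2L]]
    sum(!is.na(b1) & !is.na(b2) & b1 == b2)
  }
  truth_of <- stats::setNames(truth$true_blocks$block_id, truth$true_blocks$marker_id)
  merges <- if (nrow(blocks) == 0L) 0L else {
    sum(vapply(blocks$members, function(m) {
      length(unique(stats::na.omit(truth_of[m$marker_id]))) > 1L
    }, logical(1L)))
  }
  list(n_truth_pairs = n_pairs, n_recovered = as.integer(recovered),
       pair_coverage = if (n_pairs == 0L) NA_real_ else recovered / n_pairs,
       n_false_merges = as.integer(merges), n_blocks = nrow(blocks))
}

#' Evolve three descendant genomes for triangulation studies
#'
#' Runs three independent lineages from one ancestor and builds pairwise
#' truth sets against the reference lineage `B`, matching the design where
#' two genetic maps (A, C) are both compared to one sequenced genome (B).
#'
#' @inheritParams evolve
#' @param lineages Three lineage name prefixes.
#' @return A list `descendant_a`, `descendant_b`, `descendant_c`,
#'   `truth_ab`, `truth_cb`.
#' @export
simulate_trio <- function(ancestor, n_events_per_lineage = 8,
                          kind_weights = c(inversion = 0.4, translocation = 0.4,
                                           fusion = 0.1, fission = 0.1),
                          marker_loss_rate = 0.1, paralog_rate = 0.05, seed,
                          lineages = c("A", "B", "C")) {
  mean_gap_bp <- attr(ancestor, "mean_gap_bp") %||% 5e5
  with_seed(seed, {
    base <- chrom_orders(ancestor)
    ls <- lapply(lineages, function(ln) {
      evolve_lineage(base, n_events_per_lineage, kind_weights,
                     marker_loss_rate, paralog_rate, mean_gap_bp, ln)
    })
    list(descendant_a = ls[[1L]]$genome, descendant_b = ls[[2L]]$genome,
         descendant_c = ls[[3L]]$genome,
         truth_ab = make_truth(ancestor, ls[[1L]], ls[[2L]]),
         truth_cb = make_truth(ancestor, ls[[3L]], ls[[2L]]))
  })
}
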