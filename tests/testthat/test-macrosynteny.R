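test_that("gap thresholds derive from gene density and map fraction", {
  expect_equal(derive_physical_threshold(1e6, 1000, 1), 1000)
  expect_equal(derive_physical_threshold(1e6, 1000, 10),
               2 * derive_physical_threshold(1e6, 1000, 5))
  expect_error(derive_physical_threshold(1e6, 0, 200), "n_genes")
  # the reference setting: 200 genes at grapevine density is about 3.1 Mb
  expect_equal(derive_physical_threshold(475e6, 30434, 200), 3121509,
               tolerance = 1)

  expect_equal(derive_genetic_threshold(1463, 0.01), 14.63)
  expect_equal(derive_genetic_threshold(100, 0), 0)
  thr <- synteny_thresholds(query_map_length_cM = 1463)
  expect_equal(thr$max_gap_query_cM, 14)
  thr2 <- synteny_thresholds(query_map_length_cM = 1463, floor_to_int = FALSE)
  expect_equal(thr2$max_gap_query_cM, 14.63)
  expect_error(synteny_thresholds(min_markers = 1))
})

test_that("chaining honors both gap constraints and the minimum block size", {
  qm <- mk_map(c("m1", "m2", "m3"), "A", c(0, 5, 10))
  a <- mk_assignments(c("m1", "m2", "m3"), "chr1", c(1.0e6, 1.5e6, 2.0e6))
  b <- detect_css(a, qm)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_syntenic, 3L)
  expect_equal(b$span_query, 10)
  expect_equal(b$span_target, 1e6)

  a2 <- mk_assignments(c("m1", "m2", "m3"), "chr1", c(1.0e6, 40e6, 2.0e6))
  expect_equal(nrow(detect_css(a2, qm)), 0L)

  # a single query gap above threshold splits 12 markers into two blocks of 6
  cm <- c(0, 2, 4, 6, 8, 10, 23, 25, 27, 29, 31, 33)
  ids <- sprintf("m%02d", 1:12)
  qm3 <- mk_map(ids, "A", cm)
  a3 <- mk_assignments(ids, "chr1", 1e6 + seq_len(12) * 5e5)
  b3 <- detect_css(a3, qm3)
  expect_equal(nrow(b3), 2L)
  expect_equal(b3$n_syntenic, c(6L, 6L))
  oracle <- oracle_chains(
    tibble::tibble(marker_id = ids, query_cM = cm,
                   target_pos = 1e6 + seq_len(12) * 5e5),
    12, 3.2e6, 3)
  expect_equal(lapply(seq_len(nrow(b3)), function(i) b3$members[[i]]$marker_id),
               oracle)
})

test_that("greedy chaining equals exhaustive maximal-valid-chain enumeration", {
  set.seed(977)
  for (rep in 1:100) {
    n <- sample(2:15, 1)
    min_m <- sample(2:4, 1)
    cm <- sort(round(runif(n, 0, 60), 2))
    bp <- round(runif(n, 0, 3e7))
    ids <- sprintf("m%02d", seq_len(n))
    thr <- synteny_thresholds(min_markers = min_m, max_gap_target_bp = 3.2e6,
                              max_gap_query_cM = 12)
    b <- detect_css(mk_assignments(ids, "chr1", bp), mk_map(ids, "A", cm), thr)
    got <- lapply(seq_len(nrow(b)), function(i) b$members[[i]]$marker_id)
    want <- oracle_chains(tibble::tibble(marker_id = ids, query_cM = cm,
                                         target_pos = bp), 12, 3.2e6, min_m)
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("no marker lands in two blocks and thresholds act monotonically", {
  set.seed(31)
  n <- 60
  ids <- sprintf("m%02d", 1:n)
  cm <- sort(round(runif(n, 0, 120), 2))
  bp <- round(runif(n, 0, 4e7))
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  qm <- mk_map(ids, rep(c("A", "B"), each = n / 2), cm)
  a <- mk_assignments(ids, chrom, bp)

  chained <- function(thr) sum(detect_css(a, qm, thr)$n_syntenic)
  base <- synteny_thresholds(min_markers = 2, max_gap_target_bp = 2e6,
                             max_gap_query_cM = 6)
  b <- detect_css(a, qm, base)
  members <- unlist(lapply(b$members, `[[`, "marker_id"))
  expect_equal(anyDuplicated(members), 0L)
  expect_lte(sum(b$n_syntenic), sum(a$status == "single_locus"))

  wider_t <- synteny_thresholds(min_markers = 2, max_gap_target_bp = 8e6,
                                max_gap_query_cM = 6)
  wider_q <- synteny_thresholds(min_markers = 2, max_gap_target_bp = 2e6,
                                max_gap_query_cM = 20)
  expect_gte(chained(wider_t), chained(base))
  expect_gte(chained(wider_q), chained(base))
  for (mm in 2:5) {
    more <- synteny_thresholds(min_markers = mm, max_gap_target_bp = 2e6,
                               max_gap_query_cM = 6)
    if (mm > 2) expect_lte(nrow(detect_css(a, qm, more)), prev_nb)
    prev_nb <- nrow(detect_css(a, qm, more))
  }
})

test_that("reversing a chromosome's physical coordinates leaves blocks unchanged", {
  set.seed(47)
  n <- 30
  ids <- sprintf("m%02d", 1:n)
  cm <- sort(round(runif(n, 0, 80), 2))
  bp <- round(runif(n, 1, 3e7))
  qm <- mk_map(ids, "A", cm)
  b1 <- detect_css(mk_assignments(ids, "chr1", bp), qm)
  b2 <- detect_css(mk_assignments(ids, "chr1", 3e7 - bp), qm)
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(lapply(b1$members, function(m) m$marker_id),
               lapply(b2$members, function(m) m$marker_id))
})

test_that("interspersed non-syntenic markers are counted but do not break chains", {
  ids <- c("m1", "m2", "mx", "m3")
  qm <- mk_map(ids, "A", c(0, 4, 6, 8))
  a <- dplyr::bind_rows(
    mk_assignments(c("m1", "m2", "m3"), "chr1", c(1e6, 1.5e6, 2e6)),
    mk_assignments("mx", "chr7", 9e6))
  b <- detect_css(a, qm)
  expect_equal(nrow(b), 1L) # mx alone cannot reach min_markers
  chr1 <- b[b$target_chromosome == "chr1", ]
  expect_equal(chr1$n_syntenic, 3L)
  expect_equal(chr1$n_interspersed, 1L)
})

test_that("map-versus-map mode applies each map's own gap threshold", {
  shared <- sprintf("m%d", 1:6)
  ma <- mk_map(shared, "G", c(0, 5, 10, 30, 35, 40), name = "a")
  mb <- mk_map(shared, "T2", c(0, 6, 12, 40, 46, 52), name = "b")
  thr <- synteny_thresholds(min_markers = 3, max_gap_query_cM = 12,
                            max_gap_target_cM = 14)
  b <- detect_css_maps(ma, mb, thr)
  expect_equal(nrow(b), 2L) # split by the 20 cM / 28 cM gap on both maps
  expect_equal(b$n_syntenic, c(3L, 3L))
  # a gap legal on the query but not on the target still splits
  mb2 <- mk_map(shared, "T2", c(0, 6, 12, 27, 33, 39), name = "b2")
  ma2 <- mk_map(shared, "G", c(0, 5, 10, 15, 20, 25), name = "a2")
  expect_equal(nrow(detect_css_maps(ma2, mb2, thr)), 2L)
})

test_that("block summaries aggregate counts, spans and pooled gaps", {
  ids <- sprintf("m%d", 1:8)
  qm <- mk_map(ids, c(rep("A", 3), rep("B", 5)),
               c(0, 4, 8, 0, 2, 4, 6, 8))
  a <- mk_assignments(ids, c(rep("c1", 3), rep("c2", 5)),
                      c(1e6, 1.5e6, 2e6, 5e6, 5.4e6, 5.8e6, 6.2e6, 6.6e6))
  b <- detect_css(a, qm)
  s <- summarize_blocks(b, a)
  expect_equal(s$n_css, 2L)
  expect_equal(s$n_orthologous_markers, 8L)
  expect_equal(s$mean_markers_per_block, 4)
  expect_equal(s$max_markers_per_block, 5L)
  expect_equal(s$mean_adjacent_gap_query, mean(c(4, 4, 2, 2, 2, 2)))
  expect_equal(s$mean_adjacent_gap_target,
               mean(c(5e5, 5e5, 4e5, 4e5, 4e5, 4e5)))
  s0 <- summarize_blocks(b[0, ])
  expect_equal(s0$n_css, 0L)
  expect_equal(s0$mean_markers_per_block, 0)
})

test_that("summary agrees with an oracle recount on simulated data", {
  anc <- simulate_ancestor(3, 12, seed = 81)
  sim <- evolve(anc, n_events_per_lineage = 2, marker_loss_rate = 0.1,
                paralog_rate = 0, seed = 82)
  qmap <- project_genetic(sim$descendant_a, seed = 83)
  hits <- emit_hits(sim$truth, sim$descendant_b, query_map = qmap, seed = 84)
  a <- assign_orthologs(hits, queries = qmap$marker_id)
  b <- detect_css(a, qmap)
  s <- summarize_blocks(b, a)
  # recount blocks per (LG, chromosome) with the exhaustive oracle
  single <- a[a$status == "single_locus", ]
  idx <- match(single$marker_id, qmap$marker_id)
  d <- tibble::tibble(marker_id = single$marker_id,
                      lg = qmap$linkage_group[idx],
                      query_cM = qmap$position_cM[idx],
                      chrom = single$target_chromosome,
                      target_pos = single$target_bp)
  wins <- unlist(lapply(split(d, paste(d$lg, d$chrom)), function(g) {
    oracle_chains(g, 12, 3.2e6, 3)
  }), recursive = FALSE)
  expect_equal(s$n_css, length(wins))
  expect_equal(s$n_markers_in_blocks, sum(lengths(wins)))
  expect_equal(s$max_markers_per_block, max(lengths(wins)))
})

test_that("triangulation reports interval overlaps, Jaccard and reference coverage", {
  mk_blocks <- function(chrom, qlg, s, e) {
    tibble::tibble(query_lg = qlg, target_chromosome = chrom,
                   n_syntenic = 3L, n_interspersed = 0L,
                   query_start = 0, query_end = 10, span_query = 10,
                   target_start = s, target_end = e, span_target = e - s,
                   members = list(tibble::tibble(marker_id = c("x", "y", "z"),
                                                 query_cM = c(0, 5, 10),
                                                 target_pos = c(s, (s + e) / 2, e))))
  }
  ab <- mk_blocks("chr4", "A", 1e6, 5e6)
  cb <- mk_blocks("chr4", "T1", 3e6, 8e6)
  mw <- project_multiway(ab, cb, c(chr4 = 10e6, chr5 = 10e6))
  expect_equal(mw$overlaps$overlap_bp, 2e6)
  expect_equal(mw$overlaps$jaccard, 2 / 7)
  expect_equal(mw$coverage$fraction[mw$coverage$chromosome == "chr4"], 0.7)
  expect_true(mw$coverage$uncovered[mw$coverage$chromosome == "chr5"])

  cb2 <- mk_blocks("chr4", "T1", 6e6, 8e6)
  mw2 <- project_multiway(ab, cb2, c(chr4 = 10e6))
  expect_equal(mw2$overlaps$overlap_bp, 0)
})

test_that("a segment retained in both descendants triangulates onto one reference interval", {
  anc <- simulate_ancestor(2, 12, seed = 91)
  trio <- simulate_trio(anc, n_events_per_lineage = 0, marker_loss_rate = 0,
                        paralog_rate = 0, seed = 92)
  detect_for <- function(desc, truth, seed) {
    qmap <- project_genetic(desc, seed = seed)
    hits <- emit_hits(truth, trio$descendant_b, query_map = qmap, seed = seed + 1)
    detect_css(assign_orthologs(hits, queries = qmap$marker_id), qmap)
  }
  b_ab <- detect_for(trio$descendant_a, trio$truth_ab, 93)
  b_cb <- detect_for(trio$descendant_c, trio$truth_cb, 95)
  lens <- tapply(trio$descendant_b$pos_bp, trio$descendant_b$chromosome, max)
  mw <- project_multiway(b_ab, b_cb, lens)
  # with no rearrangement both pairwise blocks tile the same chromosomes
  expect_equal(nrow(mw$overlaps), 2L)
  expect_true(all(mw$overlaps$jaccard > 0.9))
  expect_true(all(!mw$coverage$uncovered))
})
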