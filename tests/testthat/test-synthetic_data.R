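test_that("ancestor simulation is sized correctly and seed-reproducible", {
  anc <- simulate_ancestor(2, 5, 1e5, seed = 1)
  expect_equal(nrow(anc), 10L)
  expect_equal(as.integer(table(anc$chromosome)[c("chr01", "chr02")]), c(5L, 5L))
  expect_true(all(diff(anc$pos_bp[anc$chromosome == "chr01"]) > 0))
  anc2 <- simulate_ancestor(2, 5, 1e5, seed = 1)
  expect_identical(as.data.frame(anc), as.data.frame(anc2))
  expect_false(identical(as.data.frame(anc),
                         as.data.frame(simulate_ancestor(2, 5, 1e5, seed = 2))))
  expect_error(simulate_ancestor(0, 5, 1e5, seed = 1))
})

test_that("zero events and zero loss give identity orthology and whole-chromosome blocks", {
  anc <- simulate_ancestor(3, 8, seed = 3)
  sim <- evolve(anc, n_events_per_lineage = 0, marker_loss_rate = 0,
                paralog_rate = 0, seed = 4)
  expect_equal(nrow(sim$truth$pairs), 24L)
  expect_equal(sim$truth$pairs$marker_id, sim$truth$pairs$feature_id)
  expect_equal(max(sim$truth$true_blocks$block_id), 3L)
  per_block <- table(sim$truth$true_blocks$block_id)
  expect_equal(unname(as.integer(per_block)), rep(8L, 3L))
})

test_that("marker accounting balances losses and paralogs per lineage", {
  anc <- simulate_ancestor(4, 12, seed = 11)
  sim <- evolve(anc, n_events_per_lineage = 5, marker_loss_rate = 0.2,
                paralog_rate = 0.1, seed = 12)
  for (side in c("a", "b")) {
    g <- sim[[paste0("descendant_", side)]]
    lost <- sim$truth[[paste0("lost_", side)]]
    n_par <- sum(g$is_paralog)
    expect_equal(nrow(g), nrow(anc) - length(lost) + n_par)
    expect_setequal(g$marker_id[!g$is_paralog], setdiff(anc$marker_id, lost))
  }
  # shared markers are those surviving in both lineages
  expect_setequal(sim$truth$pairs$marker_id,
                  setdiff(anc$marker_id, c(sim$truth$lost_a, sim$truth$lost_b)))
})

test_that("an inversion keeps one proximity block; one translocation adds exactly two", {
  anc <- simulate_ancestor(1, 10, seed = 5)
  sim <- evolve(anc, n_events_per_lineage = c(1, 0),
                kind_weights = c(inversion = 1),
                marker_loss_rate = 0, paralog_rate = 0, seed = 6)
  expect_equal(nrow(sim$truth$events), 1L)
  expect_equal(max(sim$truth$true_blocks$block_id), 1L)

  anc2 <- simulate_ancestor(2, 10, seed = 5)
  for (s in c(6, 7, 8)) {
    sim2 <- evolve(anc2, n_events_per_lineage = c(1, 0),
                   kind_weights = c(translocation = 1),
                   marker_loss_rate = 0, paralog_rate = 0, seed = s)
    expect_equal(nrow(sim2$truth$events), 1L)
    expect_equal(max(sim2$truth$true_blocks$block_id), 4L)
  }
})

test_that("true-block count matches the independent minimum-parts oracle", {
  for (s in 1:25) {
    anc <- simulate_ancestor(3, 5, seed = s)
    sim <- evolve(anc, n_events_per_lineage = s %% 4,
                  marker_loss_rate = 0.1, paralog_rate = 0.05, seed = s + 100)
    expect_equal(max(sim$truth$true_blocks$block_id),
                 oracle_true_block_count(anc, sim$descendant_a, sim$descendant_b),
                 info = paste("seed", s))
  }
})

test_that("genetic projection is linear at sd 0 and rank-preserving under jitter", {
  g <- mk_genome(list(chr1 = c("m1", "m2")))
  g$pos_bp <- c(1e6, 2e6)
  qm <- project_genetic(g, cM_per_Mb_mean = 2, cM_per_Mb_sd = 0, seed = 1)
  expect_equal(qm$position_cM, c(2, 4))

  anc <- simulate_ancestor(2, 20, seed = 8)
  qm2 <- project_genetic(anc, cM_per_Mb_mean = 2, cM_per_Mb_sd = 0.5, seed = 9)
  for (lg in unique(qm2$linkage_group)) {
    d <- qm2[qm2$linkage_group == lg, ]
    phys <- anc[match(d$marker_id, anc$marker_id), ]
    expect_equal(order(d$position_cM), order(phys$pos_bp))
  }
  expect_identical(as.data.frame(qm2),
                   as.data.frame(project_genetic(anc, 2, 0.5, seed = 9)))
})

test_that("emitted hits are strong, seed-stable, and plant multi-locus queries", {
  anc <- simulate_ancestor(2, 10, seed = 21)
  sim <- evolve(anc, n_events_per_lineage = 2, marker_loss_rate = 0.1,
                paralog_rate = 0, seed = 22)
  hits <- emit_hits(sim$truth, sim$descendant_b, seed = 23)
  expect_true(all(hits$e_value <= 1e-10))
  expect_setequal(unique(hits$query_id), sim$truth$pairs$marker_id)
  expect_identical(as.data.frame(hits),
                   as.data.frame(emit_hits(sim$truth, sim$descendant_b, seed = 23)))

  hits2 <- emit_hits(sim$truth, sim$descendant_b, n_spurious_multihit = 3, seed = 24)
  a <- assign_orthologs(hits2)
  expect_equal(assignment_tally(a)[["multi_locus"]], 3L)
})

test_that("noise-free hits let the cascade recover truth orthology exactly", {
  anc <- simulate_ancestor(3, 10, seed = 31)
  sim <- evolve(anc, n_events_per_lineage = 3, marker_loss_rate = 0.15,
                paralog_rate = 0, seed = 32)
  qmap <- project_genetic(sim$descendant_a, seed = 33)
  hits <- emit_hits(sim$truth, sim$descendant_b, query_map = qmap, seed = 34)
  a <- assign_orthologs(hits, queries = qmap$marker_id)
  single <- a$marker_id[a$status == "single_locus"]
  expect_setequal(single, intersect(sim$truth$pairs$marker_id, qmap$marker_id))
  # markers on the map but lost on the target are absent
  expect_setequal(a$marker_id[a$status == "absent"],
                  intersect(qmap$marker_id, sim$truth$lost_b))
})

test_that("fallback hits rescue target-lost markers as conserved-by-fallback", {
  anc <- simulate_ancestor(2, 15, seed = 41)
  sim <- evolve(anc, n_events_per_lineage = 1, marker_loss_rate = 0.3,
                paralog_rate = 0, seed = 42)
  hits <- emit_hits(sim$truth, sim$descendant_b, seed = 43)
  fb <- emit_fallback_hits(sim$truth, fraction = 1, seed = 44)
  a <- assign_orthologs(hits, queries = setdiff(anc$marker_id, sim$truth$lost_a),
                        fallback_hits = fb)
  tal <- assignment_tally(a)
  expect_equal(tal[["absent_primary_conserved_fallback"]],
               length(setdiff(sim$truth$lost_b, sim$truth$lost_a)))
  expect_equal(tal[["absent"]], 0L)
})

test_that("three-lineage simulation yields consistent pairwise truths", {
  anc <- simulate_ancestor(3, 10, seed = 51)
  trio <- simulate_trio(anc, n_events_per_lineage = 2, marker_loss_rate = 0.1,
                        paralog_rate = 0, seed = 52)
  expect_setequal(
    trio$truth_ab$pairs$marker_id,
    intersect(trio$descendant_a$marker_id, trio$descendant_b$marker_id))
  expect_setequal(
    trio$truth_cb$pairs$marker_id,
    intersect(trio$descendant_c$marker_id, trio$descendant_b$marker_id))
})
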