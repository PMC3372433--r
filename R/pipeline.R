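#' Validate a pipeline run configuration
#'
#' Collects every problem at once rather than stopping at the first. A
#' configuration has a mandatory `seed` whenever any comparison simulates
#' its inputs, an `output_dir`, and a named `comparisons` map in which each
#' comparison carries exactly one of a `simulation` block or an `inputs`
#' block, plus optional `cascade` and `synteny` threshold overrides.
#'
#' @param config A list (parsed YAML) or a path to a YAML file.
#' @return Character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$output_dir)) add("missing field: output_dir")
  comps <- config$comparisons
  if (is.null(comps) || length(comps) == 0L) {
    add("missing field: comparisons")
    comps <- list()
  }
  if (is.null(names(comps)) || any(!nzchar(names(comps)))) {
    add("comparisons must be named")
  }
  any_sim <- FALSE
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    has_sim <- !is.null(cmp$simulation)
    has_inp <- !is.null(cmp$inputs)
    if (has_sim == has_inp) {
      add(sprintf("comparison '%s': exactly one of {inputs, simulation} required", nm))
    }
    any_sim <- any_sim || has_sim
    if (has_inp) {
      for (f in c("genetic_map", "hits")) {
        p <- cmp$inputs[[f]]
        if (is.null(p)) add(sprintf("comparison '%s': inputs.%s missing", nm, f))
        else if (!file.exists(p)) add(sprintf("comparison '%s': inputs.%s not found: %s", nm, f, p))
      }
    }
    syn <- cmp$synteny
    for (f in c("min_markers", "max_gap_target_bp", "max_gap_query_cM")) {
      v <- syn[[f]]
      if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
        add(sprintf("comparison '%s': synteny.%s must be positive", nm, f))
      }
    }
  }
  if (any_sim && is.null(config$seed)) add("seed is mandatory when simulating")
  if (!is.null(config$seed) && (!is.numeric(config$seed) ||
                                config$seed != round(config$seed))) {
    add("seed must be an integer")
  }
  errs
}

config_thresholds <- function(cmp) {
  syn <- cmp$synteny %||% list()
  do.call(synteny_thresholds, syn[intersect(names(syn),
    names(formals(synteny_thresholds)))])
}

config_cascade <- function(config) {
  casc <- config$cascade %||% list()
  do.call(cascade_thresholds, casc[intersect(names(casc),
    names(formals(cascade_thresholds)))])
}

#' Run the comparative-mapping pipeline from one configuration
#'
#' Orchestrates, per comparison: input simulation (or loading), the
#' orthology cascade, CSS detection, block summarizing, and — for simulated
#' three-lineage comparisons — triangulation on the shared reference. Each
#' stage appends machine-parsable `KEY=value` tally lines to `run.log`, and
#' all outputs are deterministic functions of the configured seed. On any
#' stage failure, partial outputs of the run are removed and the error names
#' the failing stage.
#'
#' @param config A list (parsed YAML) or a path to a YAML file.
#' @param output_dir Overrides `config$output_dir`.
#' @param quiet Suppress progress messages (default TRUE).
#' @return Invisibly, the output directory, with attribute `results`: a
#'   named list per comparison (assignments, blocks, summary, and recovery
#'   scores or triangulation where applicable).
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_run_config(config)
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  out <- output_dir %||% config$output_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  file.create(log_path)
  log_line <- function(...) {
    line <- paste0(...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  results <- list()
  stage <- "setup"
  tryCatch({
    for (nm in names(config$comparisons)) {
      cmp <- config$comparisons[[nm]]
      cdir <- file.path(out, nm)
      dir.create(cdir, showWarnings = FALSE)
      log_line("COMPARISON=", nm)
      stage <- paste0(nm, "/inputs")
      thr <- config_thresholds(cmp)
      casc <- config_cascade(config)
      sim <- NULL
      if (!is.null(cmp$simulation)) {
        s <- cmp$simulation
        seed <- as.integer(config$seed)
        anc <- simulate_ancestor(s$n_chromosomes %||% 3,
                                 s$markers_per_chromosome %||% 20,
                                 s$mean_gap_bp %||% 5e5, seed = seed)
        sim <- evolve(anc,
                      n_events_per_lineage = s$n_events_per_lineage %||% 8,
                      marker_loss_rate = s$marker_loss_rate %||% 0.1,
                      paralog_rate = s$paralog_rate %||% 0.05,
                      seed = seed + 1L)
        qmap <- project_genetic(sim$descendant_a,
                                cM_per_Mb_mean = s$cM_per_Mb_mean %||% 2,
                                cM_per_Mb_sd = s$cM_per_Mb_sd %||% 0.5,
                                seed = seed + 2L, map_name = nm)
        hits <- emit_hits(sim$truth, sim$descendant_b, query_map = qmap,
                          n_spurious_multihit = s$n_spurious_multihit %||% 0,
                          seed = seed + 3L)
        write_genetic_map(qmap, file.path(cdir, "genetic_map.tsv"))
        write_physical_bed(as_physical_table(sim$descendant_b),
                           file.path(cdir, "target_features.bed"))
        write_hit_table(hits, file.path(cdir, "hits.tsv"))
        log_line("MARKERS_ANCESTOR=", nrow(anc))
        log_line("MARKERS_ON_MAP=", nrow(qmap))
      } else {
        qmap <- read_genetic_map(cmp$inputs$genetic_map)
        hits <- read_hit_table(cmp$inputs$hits)
        log_line("MARKERS_ON_MAP=", nrow(qmap))
      }
      stage <- paste0(nm, "/assign")
      unpl <- cmp$inputs$unplaced_subjects %||% character(0)
      assignments <- assign_orthologs(hits, casc, queries = qmap$marker_id,
                                      unplaced_subjects = unpl)
      write_assignments(assignments, file.path(cdir, "assignments.tsv"),
                        tally_path = file.path(cdir, "tally.json"))
      tal <- assignment_tally(assignments)
      for (k in names(tal)) log_line("TALLY_", toupper(k), "=", tal[[k]])
      stage <- paste0(nm, "/detect")
      blocks <- detect_css(assignments, qmap, thr)
      write_block_report(blocks, file.path(cdir, "block_report.tsv"),
                         thresholds = thr)
      write_links(blocks, file.path(cdir, "links.txt"))
      log_line("N_CSS=", nrow(blocks))
      stage <- paste0(nm, "/summarize")
      summ <- summarize_blocks(blocks, assignments)
      jsonlite::write_json(unclass(summ), file.path(cdir, "summary.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      log_line("MARKERS_IN_BLOCKS=", summ$n_markers_in_blocks)
      res <- list(assignments = assignments, blocks = blocks, summary = summ)
      if (!is.null(sim)) {
        stage <- paste0(nm, "/recovery")
        rec <- score_block_recovery(blocks, sim$truth,
                                    eligible = assignments$marker_id[
                                      assignments$status == "single_locus"])
        jsonlite::write_json(rec, file.path(cdir, "recovery.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        log_line("RECOVERY_PAIR_COVERAGE=", format(rec$pair_coverage, digits = 4))
        log_line("RECOVERY_FALSE_MERGES=", rec$n_false_merges)
        res$truth <- sim$truth
        res$recovery <- rec
      }
      results[[nm]] <- res
    }
    stage <- "triangulate"
    tri <- config$triangulation
    if (!is.null(tri)) {
      stopifnot(all(c("comparison_ab", "comparison_cb") %in% names(tri)))
      ba <- results[[tri$comparison_ab]]$blocks
      bc <- results[[tri$comparison_cb]]$blocks
      chroms <- unique(c(ba$target_chromosome, bc$target_chromosome))
      ref_lengths <- tri$ref_lengths %||%
        stats::setNames(vapply(chroms, function(ch) {
          max(c(ba$target_end[ba$target_chromosome == ch],
                bc$target_end[bc$target_chromosome == ch]))
        }, 0), chroms)
      mw <- project_multiway(ba, bc, unlist(ref_lengths))
      utils::write.table(as.data.frame(mw$overlaps),
                         file.path(out, "triangulation_overlaps.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(as.data.frame(mw$coverage),
                         file.path(out, "triangulation_coverage.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_line("TRIANGULATION_OVERLAPS=", nrow(mw$overlaps))
      results$triangulation <- mw
    }
  }, error = function(e) {
    if (created) unlink(out, recursive = TRUE)
    else unlink(file.path(out, c("run.log", names(config$comparisons),
                                 "triangulation_overlaps.tsv",
                                 "triangulation_coverage.tsv")), recursive = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(structure(out, results = results))
}

#' Path to the bundled demonstration configuration
#'
#' A small fully simulated run (3 chromosomes, 60 markers, seed 42) used by
#' the examples and the determinism tests.
#'
#' @return Path to a YAML file shipped with the package.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "synmapr", mustWork = TRUE)
}
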