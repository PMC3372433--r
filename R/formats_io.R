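#' Read a genetic map from a tab-separated file
#'
#' The expected dialect is a TSV with a header line
#' `marker<TAB>linkage_group<TAB>cM`. Positions are centiMorgans, stored as
#' printed (no rescaling). Linkage-group order is preserved as first
#' encountered in the file.
#'
#' @param path Path to the TSV file.
#' @param map_name Name recorded on the returned map; defaults to the file
#'   name without extension.
#' @return A `genetic_map`: a tibble with columns `marker_id`,
#'   `linkage_group`, `position_cM`, with attributes `map_name` and
#'   `lg_lengths` (named numeric, max position per linkage group).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("marker\tlinkage_group\tcM", "m1\tA\t0", "m2\tA\t5.5"), tf)
#' gm <- read_genetic_map(tf)
#' lg_lengths(gm)
#' @export
read_genetic_map <- function(path, map_name = NULL) {
  stopifnot(file.exists(path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("marker", "linkage_group", "cM")
  if (!all(required %in% names(tab))) {
    stop("genetic map header must declare columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("no markers in genetic map file '", path, "'", call. = FALSE)
  pos <- suppressWarnings(as.numeric(tab$cM))
  bad <- which(is.na(pos) | !is.finite(pos))
  if (length(bad) > 0L) {
    # +1 for the header line
    stop("non-numeric cM position at line ", bad[1L] + 1L, " of '", path, "'",
         call. = FALSE)
  }
  if (any(pos < 0)) stop("negative cM position in '", path, "'", call. = FALSE)
  dup <- tab$marker[duplicated(tab$marker)]
  if (length(dup) > 0L) {
    stop("duplicate marker id in genetic map: '", dup[1L], "'", call. = FALSE)
  }
  genetic_map(
    tibble::tibble(marker_id = tab$marker,
                   linkage_group = tab$linkage_group,
                   position_cM = pos),
    map_name = map_name %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' Construct a genetic map object from a data frame
#'
#' @param df Data frame with columns `marker_id`, `linkage_group`,
#'   `position_cM`.
#' @param map_name Character scalar naming the map.
#' @return A `genetic_map` tibble (see [read_genetic_map()]).
#' @export
genetic_map <- function(df, map_name = "map") {
  df <- tibble::as_tibble(df)[, c("marker_id", "linkage_group", "position_cM")]
  stopifnot(!anyDuplicated(df$marker_id), all(is.finite(df$position_cM)),
            all(df$position_cM >= 0))
  lgs <- unique(df$linkage_group)
  lens <- vapply(lgs, function(lg) max(df$position_cM[df$linkage_group == lg]), 0)
  names(lens) <- lgs
  structure(df, map_name = map_name, lg_lengths = lens,
            class = c("genetic_map", class(df)))
}

#' Per-linkage-group map lengths (cM)
#'
#' @param map A `genetic_map`.
#' @return Named numeric vector, max marker position per linkage group.
#' @export
lg_lengths <- function(map) attr(map, "lg_lengths")

#' Total genetic map length (cM)
#'
#' Sum of per-linkage-group lengths; the quantity the 1 percent rule for the
#' query-side gap threshold is applied to.
#'
#' @param map A `genetic_map`.
#' @return Numeric scalar, cM.
#' @export
map_length <- function(map) sum(lg_lengths(map))

#' Write a genetic map to the package TSV dialect
#'
#' @param map A `genetic_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  df <- data.frame(marker = map$marker_id, linkage_group = map$linkage_group,
                   cM = format(map$position_cM, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

physical_table <- function(df) {
  df <- tibble::as_tibble(df)[, c("feature_id", "chromosome", "start", "end", "strand")]
  stopifnot(all(df$start <= df$end), all(df$start >= 0), !anyDuplicated(df$feature_id))
  structure(df, class = c("physical_placement", class(df)))
}

#' Read physical placements from a BED file
#'
#' BED is 0-based half-open; coordinates are converted on read to the
#' internal 1-based closed convention (GFF3-style), so a BED line
#' `chr1 99 200` becomes the internal interval 100..200. Strand symbols
#' other than `+`/`-` are recorded as `*` (unknown).
#'
#' @param path Path to a BED6 (or BED4+) file.
#' @return A `physical_placement` tibble with columns `feature_id`,
#'   `chromosome`, `start`, `end`, `strand` (1-based, closed).
#' @export
read_physical_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  ids <- if (!is.null(gr$name)) as.character(gr$name) else paste0("feat", seq_along(gr))
  physical_table(tibble::tibble(
    feature_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ))
}

#' Read physical placements from a GFF3 file
#'
#' GFF3 is already 1-based closed, matching the internal convention.
#' Feature ids are taken from the `ID` attribute, falling back to `Name`.
#'
#' @param path Path to a GFF3 file.
#' @param feature_kind GFF3 `type` to keep (e.g. `"gene"`); `NULL` keeps all.
#' @return A `physical_placement` tibble (see [read_physical_bed()]).
#' @export
read_physical_gff3 <- function(path, feature_kind = "gene") {
  gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (!is.null(feature_kind)) gr <- gr[as.character(gr$type) %in% feature_kind]
  ids <- as.character(gr$ID)
  if (!is.null(gr$Name)) ids[is.na(ids)] <- as.character(gr$Name)[is.na(ids)]
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("feat", which(is.na(ids)))
  physical_table(tibble::tibble(
    feature_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ))
}

#' Write physical placements as BED6
#'
#' Internal 1-based closed intervals are converted back to BED's 0-based
#' half-open convention, so read/write round trips are exact.
#'
#' @param placements A `physical_placement` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_physical_bed <- function(placements, path) {
  df <- data.frame(chrom = placements$chromosome,
                   start = placements$start - 1L,
                   end = placements$end,
                   name = placements$feature_id,
                   score = 0L,
                   strand = ifelse(placements$strand %in% c("+", "-"),
                                   placements$strand, "."))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
              "gap_opens", "q_start", "q_end", "s_start", "s_end", "e_value",
              "bit_score")

hit_table <- function(df) {
  df <- tibble::as_tibble(df)[, hit_cols]
  stopifnot(all(df$e_value >= 0))
  structure(df, class = c("hit_table", class(df)))
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Expects the standard 12 tab-separated columns
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Subject start/end orientation encodes the hit strand.
#'
#' @param path Path to a BLAST outfmt-6 file.
#' @return A `hit_table` tibble with typed columns; E-values in scientific
#'   notation are parsed numerically.
#' @export
read_hit_table <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(hit_table(tibble::as_tibble(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10L)), hit_cols))))
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop("expected 12 tab-separated columns, found ", nf[bad[1L]],
         " at line ", bad[1L], " of '", path, "'", call. = FALSE)
  }
  tab <- readr::read_tsv(I(lines), col_names = hit_cols,
                         col_types = "ccnnnnnnnnnn", progress = FALSE)
  hit_table(tab)
}

#' Write a hit table as BLAST outfmt 6
#'
#' @param hits A `hit_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  df <- as.data.frame(hits)
  df$e_value <- format(df$e_value, trim = TRUE, scientific = TRUE, digits = 3)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a syntenic block report
#'
#' One TSV row per block, sorted by query linkage group then query start, so
#' identical inputs produce byte-identical files. Threshold settings are
#' recorded in `# key=value` header comments for provenance.
#'
#' @param blocks A `synteny_blocks` tibble from [detect_css()].
#' @param path Output path.
#' @param thresholds Optional `synteny_thresholds` echoed in the header.
#' @return `path`, invisibly.
#' @export
write_block_report <- function(blocks, path, thresholds = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(thresholds)) {
    for (k in names(thresholds)) {
      writeLines(sprintf("# %s=%s", k, format(thresholds[[k]], scientific = FALSE)), con)
    }
  }
  cols <- c("block_id", "query_lg", "target_chromosome", "n_syntenic",
            "n_interspersed", "query_start", "query_end", "span_query",
            "target_start", "target_end", "span_target", "members")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(blocks) > 0L) {
    ord <- order(blocks$query_lg, blocks$query_start, blocks$target_chromosome)
    b <- blocks[ord, ]
    rows <- vapply(seq_len(nrow(b)), function(i) {
      m <- b$members[[i]]
      paste(c(sprintf("block%03d", i), b$query_lg[i], b$target_chromosome[i],
              b$n_syntenic[i], b$n_interspersed[i],
              format(c(b$query_start[i], b$query_end[i], b$span_query[i]),
                     trim = TRUE, scientific = FALSE),
              format(c(b$target_start[i], b$target_end[i], b$span_target[i]),
                     trim = TRUE, scientific = FALSE),
              paste(m$marker_id, collapse = ",")),
            collapse = "\t")
    }, character(1L))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Write blocks as a Circos-style link file
#'
#' Six whitespace-separated columns per link:
#' `query_lg q_start q_end target_chrom t_start t_end`. The query interval is
#' in cM multiplied by `cm_scale` (so genetic and physical coordinates can
#' share one plotting unit); the target interval is in bp.
#'
#' @param blocks A `synteny_blocks` tibble.
#' @param path Output path.
#' @param cm_scale Multiplier applied to cM coordinates (default 1e6, i.e.
#'   1 cM is drawn as 1 Mb).
#' @return `path`, invisibly.
#' @export
write_links <- function(blocks, path, cm_scale = 1e6) {
  lines <- character(0L)
  if (nrow(blocks) > 0L) {
    ord <- order(blocks$query_lg, blocks$query_start, blocks$target_chromosome)
    b <- blocks[ord, ]
    lines <- sprintf("%s %s %s %s %s %s", b$query_lg,
                     format(round(b$query_start * cm_scale), scientific = FALSE, trim = TRUE),
                     format(round(b$query_end * cm_scale), scientific = FALSE, trim = TRUE),
                     b$target_chromosome,
                     format(b$target_start, scientific = FALSE, trim = TRUE),
                     format(b$target_end, scientific = FALSE, trim = TRUE))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
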