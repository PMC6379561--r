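# Interval work is delegated to IRanges/GenomicRanges; all public
# tables stay 0-based half-open and are converted at the boundary.

granges_from_df <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Associate DMRs with nearby genes
#'
#' A gene is associated with a DMR when the interval gap between them
#' is at most `max_dist_bp` (default 10 kb, which lets flanking
#' regulatory regions such as the promoter count as proximal);
#' overlapping intervals have gap 0. Strand is ignored and a DMR may
#' associate with several genes and vice versa.
#'
#' @param dmrs Tibble with `dmr_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (and
#'   optionally `symbol`).
#' @param max_dist_bp Maximum gap in bp, inclusive (default 10,000).
#' @return Tibble of association pairs: `dmr_id`, `gene_id`,
#'   (`symbol`,) `distance_bp`.
#' @export
associate_genes <- function(dmrs, genes, max_dist_bp = 10000) {
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) {
    return(tibble(dmr_id = character(), gene_id = character(),
                  distance_bp = integer()))
  }
  unknown <- setdiff(unique(dmrs$chrom), unique(genes$chrom))
  if (length(unknown) > 0L) {
    warn(sprintf("No genes on chromosome(s): %s.",
                 paste(unknown, collapse = ", ")))
  }
  gr_d <- granges_from_df(dmrs)
  gr_g <- granges_from_df(genes)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_d, gr_g, maxgap = max_dist_bp,
                                ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(gr_d[qi], gr_g[si])
  out <- tibble(dmr_id = dmrs$dmr_id[qi], gene_id = genes$gene_id[si],
                distance_bp = as.integer(dist))
  if ("symbol" %in% names(genes)) {
    out$symbol <- genes$symbol[si]
    out <- out[, c("dmr_id", "gene_id", "symbol", "distance_bp")]
  }
  arrange(out, .data$dmr_id, .data$distance_bp, .data$gene_id)
}

#' Overlap two interval sets (Venn counts)
#'
#' An element of A is "common" when it overlaps at least one element of
#' B by one bp or more, and symmetrically for B. Because one interval
#' can overlap several on the other side, the per-side common counts
#' can differ; both are reported, and `common` is their mean (which is
#' why a shared count can be a half-integer).
#'
#' @param set_a,set_b Tibbles with `chrom`, `start`, `end` (0-based
#'   half-open). Rows with missing coordinates (features of unknown
#'   location) are dropped with a message.
#' @return One-row tibble: `n_a`, `n_b`, `common_a`, `common_b`,
#'   `common`, `a_only`, `b_only`.
#' @export
venn_intervals <- function(set_a, set_b) {
  set_a <- drop_unplaced(set_a, "A")
  set_b <- drop_unplaced(set_b, "B")
  n_a <- nrow(set_a); n_b <- nrow(set_b)
  if (n_a == 0L || n_b == 0L) {
    return(tibble(n_a = n_a, n_b = n_b, common_a = 0L, common_b = 0L,
                  common = 0, a_only = n_a, b_only = n_b))
  }
  # disjoint seqlevels between the two sets are expected, not an error
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(granges_from_df(set_a),
                                granges_from_df(set_b),
                                ignore.strand = TRUE))
  common_a <- length(unique(S4Vectors::queryHits(hits)))
  common_b <- length(unique(S4Vectors::subjectHits(hits)))
  tibble(n_a = n_a, n_b = n_b, common_a = common_a, common_b = common_b,
         common = (common_a + common_b) / 2,
         a_only = n_a - common_a, b_only = n_b - common_b)
}

drop_unplaced <- function(df, label) {
  unplaced <- is.na(df$chrom) | is.na(df$start) | is.na(df$end)
  if (any(unplaced)) {
    inform(sprintf("Dropping %d feature(s) of unknown location from set %s.",
                   sum(unplaced), label))
  }
  df[!unplaced, , drop = FALSE]
}

#' Overlap two id lists (Venn counts)
#'
#' Exact set intersection and differences of feature identifiers, used
#' for cross-cell-type comparisons where identity, not genomic
#' position, defines sharing. Duplicates are removed with a warning.
#'
#' @param list_a,list_b Character vectors of ids.
#' @return One-row tibble: `n_a`, `n_b`, `common`, `a_only`, `b_only`.
#' @export
venn_ids <- function(list_a, list_b) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    warn("Duplicate ids removed before overlap.")
  }
  a <- unique(list_a); b <- unique(list_b)
  common <- length(intersect(a, b))
  tibble(n_a = length(a), n_b = length(b), common = common,
         a_only = length(a) - common, b_only = length(b) - common)
}

#' Tally genes per category or pathway label
#'
#' Counts, for each label in a gene-to-label mapping, the distinct
#' genes from `gene_list` carrying it; a gene with several labels
#' counts once under each. Genes absent from the mapping are tallied
#' under `"unknown"`.
#'
#' @param gene_list Character vector of gene ids (duplicates ignored).
#' @param mapping Tibble with columns `gene_id`, `label`, or the path
#'   of a two-column TSV (malformed rows are reported with their line
#'   number).
#' @return Tibble with `label`, `n_genes`, sorted by decreasing count;
#'   always contains an `unknown` row.
#' @export
map_counts <- function(gene_list, mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- read_mapping_tsv(mapping)
  }
  if (!all(c("gene_id", "label") %in% names(mapping))) {
    abort("`mapping` must have columns `gene_id` and `label`.")
  }
  genes <- unique(gene_list)
  hit <- mapping |>
    filter(.data$gene_id %in% genes) |>
    distinct(.data$gene_id, .data$label)
  n_unknown <- length(setdiff(genes, mapping$gene_id))
  hit |>
    count(.data$label, name = "n_genes") |>
    arrange(dplyr::desc(.data$n_genes), .data$label) |>
    bind_rows(tibble(label = "unknown", n_genes = n_unknown))
}

read_mapping_tsv <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  has_header <- length(body) > 0L &&
    identical(fields[[1]][1:2], c("gene_id", "label"))
  rows <- if (has_header) seq_along(body)[-1] else seq_along(body)
  bad <- rows[nf[rows] < 2L |
                vapply(fields[rows],
                       function(f) any(f[1:2] == "" | is.na(f[1:2])),
                       logical(1))]
  if (length(bad) > 0L) {
    abort(sprintf("Malformed mapping row at line %d of %s.",
                  body[bad[1]], path))
  }
  tibble(gene_id = vapply(fields[rows], `[[`, character(1), 1L),
         label = vapply(fields[rows], `[[`, character(1), 2L))
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 (via rtracklayer, converted from 1-based closed to the
#' package's 0-based half-open convention, keeping `gene`-type records)
#' or BED4+ (already 0-based).
#'
#' @param path Annotation file path; format guessed from extension.
#' @return Tibble with `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("Reading GFF3 requires the rtracklayer package.")
    }
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    ids <- S4Vectors::mcols(gr)$ID %||%
      S4Vectors::mcols(gr)$gene_id %||%
      paste0("gene_", seq_along(gr))
    sym <- S4Vectors::mcols(gr)$Name %||% ids
    tibble(gene_id = as.character(ids), symbol = as.character(sym),
           chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr),
           strand = as.character(GenomicRanges::strand(gr)))
  } else {
    df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                          show_col_types = FALSE, progress = FALSE)
    tibble(gene_id = if (ncol(df) >= 4) as.character(df[[4]])
           else paste0("gene_", seq_len(nrow(df))),
           symbol = if (ncol(df) >= 4) as.character(df[[4]])
           else paste0("gene_", seq_len(nrow(df))),
           chrom = as.character(df[[1]]),
           start = as.integer(df[[2]]), end = as.integer(df[[3]]),
           strand = if (ncol(df) >= 6) as.character(df[[6]]) else "*")
  }
}
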