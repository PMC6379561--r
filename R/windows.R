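#' Tile chromosomes into fixed-width genomic windows
#'
#' Breaks each chromosome into consecutive `width_bp` windows (default
#' 100 bp, the standard tiling for window-based MeDIP-seq analysis).
#' The terminal remainder, if any, is kept as a truncated window so the
#' tiling partitions the chromosome exactly.
#'
#' @param chrom_sizes Tibble with columns `chrom` and `size`, or a named
#'   numeric vector of chromosome lengths.
#' @param width_bp Window width in bp (default 100).
#' @return Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `index` (ordinal within chromosome, from 1).
#' @export
#' @examples
#' tile_genome(c(chr1 = 250), width_bp = 100)
tile_genome <- function(chrom_sizes, width_bp = 100L) {
  if (!is.data.frame(chrom_sizes)) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes),
                          size = as.numeric(chrom_sizes))
  }
  check_scalar(width_bp, "width_bp", lower = 1, integer = TRUE)
  if (anyDuplicated(chrom_sizes$chrom)) {
    abort("Duplicate chromosome names in `chrom_sizes`.")
  }
  if (any(chrom_sizes$size < 1)) abort("Chromosome sizes must be >= 1.")
  purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    size <- chrom_sizes$size[i]
    starts <- seq.int(0L, size - 1L, by = width_bp)
    tibble(chrom = chrom_sizes$chrom[i],
           start = as.integer(starts),
           end = as.integer(pmin(starts + width_bp, size)),
           index = seq_along(starts))
  })
}

#' Count CpG dinucleotides in a sequence
#'
#' A CpG is a cytosine immediately followed by a guanine. Counting is
#' case-insensitive; `N` is allowed but never participates in a CpG.
#'
#' @param sequence Character vector of DNA sequences over A/C/G/T/N.
#' @return Integer vector of CG-dinucleotide counts.
#' @export
#' @examples
#' count_cpg("CGCGCG")  # 3
count_cpg <- function(sequence) {
  if (!is.character(sequence)) abort("`sequence` must be character.")
  up <- toupper(sequence)
  bad <- stringr::str_extract(up, "[^ACGTN]")
  if (any(!is.na(bad))) {
    abort(sprintf("Invalid character '%s' in sequence.",
                  bad[which(!is.na(bad))[1]]))
  }
  out <- stringr::str_count(up, stringr::fixed("CG"))
  as.integer(out)
}

#' Annotate windows with CpG counts from a genome
#'
#' Each CpG is assigned to the window containing its cytosine, so a CpG
#' straddling a window boundary is counted once, in the left window.
#'
#' @param windows Window tibble from [tile_genome()].
#' @param genome A `sim_genome` object (or any list with a named `seq`
#'   character vector).
#' @return `windows` with an added integer `cpg_count` column.
#' @export
window_cpg_counts <- function(windows, genome) {
  seqs <- genome$seq
  missing <- setdiff(unique(windows$chrom), names(seqs))
  if (length(missing) > 0L) {
    abort(sprintf("No sequence for chromosome(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  cpg_count <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    rows <- which(windows$chrom == ch)
    w <- windows[rows, , drop = FALSE]
    # 0-based positions of the C of each CG
    m <- stringr::str_locate_all(toupper(seqs[[ch]]),
                                 stringr::fixed("CG"))[[1]]
    if (nrow(m) > 0L) {
      cpos <- m[, 1] - 1L
      idx <- findInterval(cpos, w$start)
      idx <- idx[idx >= 1L & cpos < w$end[idx]]
      cpg_count[rows] <- tabulate(idx, nbins = nrow(w))
    }
  }
  windows$cpg_count <- as.integer(cpg_count)
  windows
}

#' Build the window-by-sample fragment count matrix
#'
#' Assigns each mapped MeDIP fragment to exactly one window by its
#' midpoint (half-open arithmetic: a midpoint on a window boundary goes
#' to the right-hand window), or optionally to every window it overlaps
#' by at least 1 bp (`count_mode = "overlap"`, matching the coverage
#' convention of window-based MeDIP tools). Fragments on chromosomes
#' absent from `windows` are skipped with a warning.
#'
#' @param fragments Tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `sample`, e.g. from [read_fragments_bed()].
#' @param windows Window tibble from [tile_genome()] (optionally with
#'   `cpg_count`).
#' @param samples Optional character vector fixing sample order (and
#'   including samples with zero fragments).
#' @param count_mode `"midpoint"` (default) or `"overlap"`.
#' @return A list of class `window_counts`: `windows` (tibble),
#'   `counts` (integer matrix, windows x samples), `samples` (character
#'   vector), `n_skipped` (fragments on unknown chromosomes).
#' @export
count_fragments <- function(fragments, windows, samples = NULL,
                            count_mode = c("midpoint", "overlap")) {
  count_mode <- match.arg(count_mode)
  stopifnot(all(c("chrom", "start", "end", "sample") %in%
                  names(fragments)))
  if (any(fragments$start >= fragments$end)) {
    abort("Malformed fragments: `start` must be < `end`.")
  }
  samples <- samples %||% sort(unique(fragments$sample))
  known <- fragments$chrom %in% unique(windows$chrom)
  n_skipped <- sum(!known)
  if (n_skipped > 0L) {
    warn(sprintf("Skipping %d fragment(s) on chromosomes without windows.",
                 n_skipped))
    fragments <- fragments[known, , drop = FALSE]
  }
  counts <- matrix(0L, nrow = nrow(windows), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(fr) == 0L) next
    row_offset <- which(windows$chrom == ch)[1] - 1L
    if (count_mode == "midpoint") {
      mid <- (fr$start + fr$end) %/% 2L
      idx <- findInterval(mid, w$start)
      ok <- idx >= 1L & mid < w$end[pmax(idx, 1L)]
      tb <- table(factor(fr$sample[ok], levels = samples),
                  factor(idx[ok], levels = seq_len(nrow(w))))
      counts[row_offset + seq_len(nrow(w)), ] <-
        counts[row_offset + seq_len(nrow(w)), , drop = FALSE] + t(tb)
    } else {
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(fr$start + 1L, fr$end),
        IRanges::IRanges(w$start + 1L, w$end))
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      tb <- table(factor(fr$sample[qi], levels = samples),
                  factor(si, levels = seq_len(nrow(w))))
      counts[row_offset + seq_len(nrow(w)), ] <-
        counts[row_offset + seq_len(nrow(w)), , drop = FALSE] + t(tb)
    }
  }
  storage.mode(counts) <- "integer"
  new_window_counts(windows, counts, samples, n_skipped)
}

new_window_counts <- function(windows, counts, samples,
                              n_skipped = 0L) {
  structure(list(windows = as_tibble(windows), counts = counts,
                 samples = samples, n_skipped = n_skipped),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("<window_counts> %d windows x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy-dmrkit
#' @method tidy window_counts
#' @export
tidy.window_counts <- function(x, ...) {
  bind_cols(x$windows, as_tibble(x$counts)) |>
    tidyr::pivot_longer(cols = all_of(x$samples), names_to = "sample",
                        values_to = "count")
}

#' @rdname glance-dmrkit
#' @method glance window_counts
#' @export
glance.window_counts <- function(x, ...) {
  tibble(n_windows = nrow(x$counts), n_samples = ncol(x$counts),
         total_fragments = sum(x$counts),
         n_skipped_fragments = x$n_skipped)
}

#' Read fragments from BED files
#'
#' Reads one BED3+ file per sample (0-based half-open, `#` comment lines
#' ignored) into the single tidy fragment table [count_fragments()]
#' consumes.
#'
#' @param paths Named character vector of BED paths; names are sample
#'   ids (basenames used when unnamed).
#' @return Tibble with columns `chrom`, `start`, `end`, `sample`.
#' @export
read_fragments_bed <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.bed$", "", basename(paths))
  }
  purrr::imap_dfr(paths, function(p, nm) {
    df <- readr::read_tsv(p, comment = "#", col_names = FALSE,
                          show_col_types = FALSE, progress = FALSE)
    tibble(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
           end = as.integer(df[[3]]), sample = nm)
  })
}

#' Write windows as BED4 and the count matrix as TSV
#'
#' The window table is written as BED4 (name = within-chromosome
#' window index); the count matrix as TSV with rows labeled
#' `chrom:start-end` and one column per sample. Both carry a
#' provenance comment header.
#'
#' @param x A `window_counts` object (or, for `write_windows_bed`, a
#'   window tibble).
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return The path, invisibly.
#' @export
write_windows_bed <- function(x, path, seed = NULL) {
  w <- if (inherits(x, "window_counts")) x$windows else x
  writeLines(provenance_header(seed), path)
  readr::write_tsv(tibble(w$chrom, w$start, w$end, w$index), path,
                   append = TRUE, col_names = FALSE)
  invisible(path)
}

#' @rdname write_windows_bed
#' @export
write_count_matrix_tsv <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "window_counts"))
  df <- bind_cols(
    tibble(window = sprintf("%s:%d-%d", x$windows$chrom,
                            x$windows$start, x$windows$end)),
    as_tibble(x$counts))
  write_tsv_provenance(df, path, seed = seed)
}

#' Read a window count matrix TSV back into a `window_counts` object
#'
#' @param path TSV written by [write_count_matrix_tsv()].
#' @return A `window_counts` object.
#' @export
read_count_matrix_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  parts <- stringr::str_match(df$window, "^(.+):(\\d+)-(\\d+)$")
  windows <- tibble(chrom = parts[, 2],
                    start = as.integer(parts[, 3]),
                    end = as.integer(parts[, 4]))
  windows <- windows |>
    group_by(.data$chrom) |>
    mutate(index = row_number()) |>
    ungroup()
  samples <- setdiff(names(df), "window")
  counts <- as.matrix(df[, samples])
  storage.mode(counts) <- "integer"
  new_window_counts(windows, counts, samples)
}
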