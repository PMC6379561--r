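#' Call differentially methylated regions from window tests
#'
#' A window with `p_value < seed_p` (default 1e-6) seeds a DMR. Edges
#' are then extended: any window with `p_value < extend_p` (default
#' 0.1) whose interval lies within `extend_dist_bp` (default 1000 bp) of
#' the current region span is absorbed, repeatedly, until no such
#' window remains; regions whose extensions meet are merged. The result
#' is the fixed point of the absorption rule, equivalently the
#' connected component (under gap <= `extend_dist_bp` linkage among
#' sub-`extend_p` windows) containing each seed.
#'
#' Each region records the spanned and significant window counts, the
#' multiple-window flag (at least two significant windows on
#' immediately adjacent tiles), the extremal p-value, the direction of
#' methylation change taken from the most significant window's fold
#' change, its length, and the mean CpG density per 100 bp when the
#' windows carry `cpg_count`.
#'
#' @param window_results Tibble from [test_windows()] with columns
#'   `chrom`, `start`, `end`, `p_value`, `log2fc` (and optionally
#'   `cpg_count`), sorted by (chrom, start).
#' @param seed_p Seed significance threshold (default 1e-6).
#' @param extend_p Extension threshold (default 0.1).
#' @param extend_dist_bp Extension reach in bp (default 1000).
#' @param neighbor_rule `"adjacent"` (default): multiple-window status
#'   requires two significant windows on touching tiles; `"any"`: any
#'   two significant windows in the region qualify.
#' @return A tibble of class `dmr_set`, sorted and non-overlapping,
#'   with columns `dmr_id`, `chrom`, `start`, `end`, `length_bp`,
#'   `n_windows_total`, `n_windows_significant`, `is_multiple_window`,
#'   `min_p`, `direction`, `log2fc`, `cpg_density_per_100bp`.
#' @export
call_dmrs <- function(window_results, seed_p = 1e-6, extend_p = 0.1,
                      extend_dist_bp = 1000,
                      neighbor_rule = c("adjacent", "any")) {
  neighbor_rule <- match.arg(neighbor_rule)
  check_scalar(seed_p, "seed_p", lower = 0, upper = 1)
  check_scalar(extend_p, "extend_p", lower = 0, upper = 1)
  wr <- window_results
  need <- c("chrom", "start", "end", "p_value", "log2fc")
  if (!all(need %in% names(wr))) {
    abort(sprintf("`window_results` needs columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (nrow(wr) == 0L) return(empty_dmr_set(seed_p, extend_p,
                                           extend_dist_bp))
  resorted <- wr[order(wr$chrom, wr$start), , drop = FALSE]
  if (!identical(resorted$start, wr$start) ||
      !identical(resorted$chrom, wr$chrom)) {
    abort("`window_results` must be sorted by (chrom, start).")
  }

  has_cpg <- "cpg_count" %in% names(wr)
  out <- purrr::map_dfr(unique(wr$chrom), function(ch) {
    w <- wr[wr$chrom == ch, , drop = FALSE]
    cand_idx <- which(w$p_value < extend_p)
    if (length(cand_idx) == 0L) return(tibble())
    cand <- w[cand_idx, , drop = FALSE]
    gap <- c(Inf, cand$start[-1L] - cand$end[-nrow(cand)])
    comp <- cumsum(gap > extend_dist_bp)
    purrr::map_dfr(split(seq_len(nrow(cand)), comp), function(ii) {
      members <- cand[ii, , drop = FALSE]
      sig <- members[members$p_value < seed_p, , drop = FALSE]
      if (nrow(sig) == 0L) return(tibble())
      dmr_start <- min(members$start)
      dmr_end <- max(members$end)
      spanned <- w[w$start >= dmr_start & w$end <= dmr_end, ,
                   drop = FALSE]
      best <- which.min(members$p_value)
      mw <- multiple_window_flag(sig, neighbor_rule)
      tibble(
        chrom = ch, start = dmr_start, end = dmr_end,
        length_bp = dmr_end - dmr_start,
        n_windows_total = nrow(spanned),
        n_windows_significant = nrow(sig),
        is_multiple_window = mw,
        min_p = members$p_value[best],
        log2fc = members$log2fc[best],
        direction = ifelse(members$log2fc[best] >= 0, "increase",
                           "decrease"),
        cpg_density_per_100bp = if (has_cpg) {
          sum(spanned$cpg_count) * 100 / sum(spanned$end - spanned$start)
        } else {
          NA_real_
        })
    })
  })
  if (nrow(out) == 0L) return(empty_dmr_set(seed_p, extend_p,
                                            extend_dist_bp))
  out <- out |>
    arrange(.data$chrom, .data$start) |>
    mutate(dmr_id = sprintf("DMR_%04d", row_number())) |>
    select("dmr_id", dplyr::everything())
  new_dmr_set(out, seed_p, extend_p, extend_dist_bp)
}

multiple_window_flag <- function(sig, neighbor_rule) {
  if (nrow(sig) < 2L) return(FALSE)
  if (neighbor_rule == "any") return(TRUE)
  any(sig$start[-1L] == sig$end[-nrow(sig)])
}

new_dmr_set <- function(df, seed_p, extend_p, extend_dist_bp) {
  structure(as_tibble(df),
            class = c("dmr_set", class(tibble())),
            seed_p = seed_p, extend_p = extend_p,
            extend_dist_bp = extend_dist_bp)
}

empty_dmr_set <- function(seed_p, extend_p, extend_dist_bp) {
  new_dmr_set(
    tibble(dmr_id = character(), chrom = character(), start = integer(),
           end = integer(), length_bp = integer(),
           n_windows_total = integer(),
           n_windows_significant = integer(),
           is_multiple_window = logical(), min_p = numeric(),
           log2fc = numeric(), direction = character(),
           cpg_density_per_100bp = numeric()),
    seed_p, extend_p, extend_dist_bp)
}

#' Classify DMRs as multiple-window
#'
#' A region is "multiple window" when at least two windows significant
#' at `seed_p` inside it sit on immediately adjacent tiles (or simply
#' two anywhere, under `neighbor_rule = "any"`).
#'
#' @param dmrs A `dmr_set` (or tibble with `chrom`, `start`, `end`).
#' @param window_results The window test tibble used to call the DMRs.
#' @param seed_p Seed threshold.
#' @inheritParams call_dmrs
#' @return Tibble with `dmr_id`, `n_windows_significant`,
#'   `is_multiple_window`.
#' @export
classify_multiple_window <- function(dmrs, window_results,
                                     seed_p = attr(dmrs, "seed_p") %||% 1e-6,
                                     neighbor_rule = c("adjacent", "any")) {
  neighbor_rule <- match.arg(neighbor_rule)
  purrr::map_dfr(seq_len(nrow(dmrs)), function(i) {
    sig <- window_results[
      window_results$chrom == dmrs$chrom[i] &
        window_results$start >= dmrs$start[i] &
        window_results$end <= dmrs$end[i] &
        window_results$p_value < seed_p, , drop = FALSE]
    tibble(dmr_id = dmrs$dmr_id[i] %||% as.character(i),
           n_windows_significant = nrow(sig),
           is_multiple_window = multiple_window_flag(sig, neighbor_rule))
  })
}

#' DMR counts across p-value thresholds
#'
#' Re-runs [call_dmrs()] at each seed threshold and reports, per
#' threshold, the number of DMRs overall ("all window") and the number
#' containing at least two significant neighboring windows ("multiple
#' window"). Counts are non-increasing as the threshold tightens.
#'
#' @inheritParams call_dmrs
#' @param thresholds Seed thresholds; sorted to descending order.
#' @return Tibble with `threshold`, `n_dmrs_all`,
#'   `n_dmrs_multiple_window`.
#' @export
dmr_threshold_table <- function(window_results, thresholds = 10^-(2:8),
                                extend_p = 0.1, extend_dist_bp = 1000) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  purrr::map_dfr(thresholds, function(th) {
    d <- call_dmrs(window_results, seed_p = th, extend_p = extend_p,
                   extend_dist_bp = extend_dist_bp)
    tibble(threshold = th, n_dmrs_all = nrow(d),
           n_dmrs_multiple_window = sum(d$is_multiple_window))
  })
}

#' Summarize DMR genomic features
#'
#' Histograms of CpG density (integer bins: a density d falls in bin
#' ceiling(d) CpG per 100 bp) and of length (1 kb bins, bin 1 being
#' <= 1 kb), plus per-chromosome counts. Each table partitions the DMR
#' set.
#'
#' @param dmrs A `dmr_set`.
#' @return A list of class `dmr_features` with tibbles `cpg_density`,
#'   `length`, `chromosome`.
#' @export
summarize_dmr_features <- function(dmrs) {
  cpg <- dmrs |>
    mutate(bin = pmax(ceiling(.data$cpg_density_per_100bp), 0)) |>
    count(.data$bin, name = "n_dmrs") |>
    rename(cpg_per_100bp = "bin")
  len <- dmrs |>
    mutate(bin = pmax(ceiling(.data$length_bp / 1000), 1)) |>
    count(.data$bin, name = "n_dmrs") |>
    rename(length_kb_bin = "bin")
  chrom <- count(dmrs, .data$chrom, name = "n_dmrs")
  structure(list(cpg_density = cpg, length = len, chromosome = chrom),
            class = "dmr_features")
}

#' @export
print.dmr_features <- function(x, ...) {
  cat("<dmr_features>\nCpG density (per 100 bp):\n")
  print(x$cpg_density)
  cat("Length (kb bins):\n")
  print(x$length)
  invisible(x)
}

#' Cluster DMRs along chromosomes
#'
#' Maximal runs of at least `min_cluster_size` DMRs on one chromosome
#' whose consecutive start-to-start gaps are all within `max_gap_bp`.
#'
#' @param dmrs A `dmr_set` (sorted).
#' @param max_gap_bp Maximum start-to-start gap between consecutive
#'   cluster members (default 2 Mb).
#' @param min_cluster_size Minimum DMRs per cluster (default 3).
#' @return Tibble with `cluster_id`, `chrom`, `start`, `end`, `n_dmrs`,
#'   `dmr_ids`.
#' @export
cluster_dmrs <- function(dmrs, max_gap_bp = 2e6, min_cluster_size = 3L) {
  if (nrow(dmrs) == 0L) {
    return(tibble(cluster_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_dmrs = integer(),
                  dmr_ids = character()))
  }
  runs <- dmrs |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(new_run = c(TRUE, diff(.data$start) > max_gap_bp),
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$run) |>
    filter(n() >= min_cluster_size) |>
    ungroup()
  if (nrow(runs) == 0L) {
    return(tibble(cluster_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_dmrs = integer(),
                  dmr_ids = character()))
  }
  runs |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_dmrs = n(),
              dmr_ids = paste(.data$dmr_id, collapse = ","),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster_id = sprintf("cluster_%02d", row_number())) |>
    select("cluster_id", "chrom", "start", "end", "n_dmrs", "dmr_ids")
}

#' @rdname tidy-dmrkit
#' @method tidy dmr_set
#' @export
tidy.dmr_set <- function(x, ...) as_tibble(unclass_tbl(x))

#' @rdname glance-dmrkit
#' @method glance dmr_set
#' @export
glance.dmr_set <- function(x, ...) {
  tibble(n_dmrs = nrow(x),
         n_multiple_window = sum(x$is_multiple_window),
         n_increase = sum(x$direction == "increase"),
         n_decrease = sum(x$direction == "decrease"),
         median_length_bp = if (nrow(x)) median(x$length_bp) else NA_real_,
         seed_p = attr(x, "seed_p"),
         extend_p = attr(x, "extend_p"),
         extend_dist_bp = attr(x, "extend_dist_bp"))
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), "dmr_set")
  attr(x, "seed_p") <- NULL
  attr(x, "extend_p") <- NULL
  attr(x, "extend_dist_bp") <- NULL
  x
}

#' @rdname autoplot-dmrkit
#' @param type Which feature panel to draw for `dmr_set` objects.
#' @method autoplot dmr_set
#' @export
autoplot.dmr_set <- function(object,
                             type = c("length", "cpg_density",
                                      "chromosome"), ...) {
  type <- match.arg(type)
  feats <- summarize_dmr_features(object)
  df <- switch(type,
    length = feats$length |>
      mutate(x = factor(.data$length_kb_bin)),
    cpg_density = feats$cpg_density |>
      mutate(x = factor(.data$cpg_per_100bp)),
    chromosome = feats$chromosome |> mutate(x = .data$chrom))
  xlab <- switch(type, length = "DMR length (kb bin)",
                 cpg_density = "CpG density (CpG per 100 bp)",
                 chromosome = "chromosome")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$n_dmrs)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = xlab, y = "number of DMRs") +
    ggplot2::theme_minimal()
}

#' Write a DMR table as BED6+ and TSV
#'
#' BED6 columns: chrom, start, end, name (DMR id), score
#' (-log10 min p, capped at 1000), strand ('.'); the full table is
#' written alongside as TSV.
#'
#' @param dmrs A `dmr_set`.
#' @param bed_path,tsv_path Output paths (either may be `NULL`).
#' @param seed Optional seed recorded in the provenance header.
#' @return Invisibly, the written paths.
#' @export
write_dmr_tables <- function(dmrs, bed_path = NULL, tsv_path = NULL,
                             seed = NULL) {
  if (!is.null(bed_path)) {
    bed <- tibble(dmrs$chrom, dmrs$start, dmrs$end, dmrs$dmr_id,
                  round(pmin(-log10(dmrs$min_p), 1000), 3), ".")
    writeLines(provenance_header(seed), bed_path)
    readr::write_tsv(bed, bed_path, append = TRUE, col_names = FALSE)
  }
  if (!is.null(tsv_path)) {
    write_tsv_provenance(tidy(dmrs), tsv_path, seed = seed)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
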