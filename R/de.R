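#' Differential expression across RNA classes
#'
#' Applies the count-testing pipeline to a transcript table carrying
#' RNA-class labels: TMM normalization over all transcripts, a
#' method-of-moments common dispersion estimated separately within each
#' RNA class (mRNA, lncRNA, sncRNA), the conditional negative binomial
#' exact test and BH FDR per transcript, then tallies of differentially
#' expressed transcripts per class and, within sncRNA, per subclass
#' (miRNA, piRNA, tRNA, other). Transcripts pass at
#' `p_value < p_threshold` (default 0.001, the conventional stringency
#' for this analysis).
#'
#' @param transcripts Tibble with columns `id`, `class`, optionally
#'   `subclass`, `chrom`, `start`, `end`, plus one count column per
#'   sample (every name in `groups`).
#' @param groups Sample->group mapping with levels control/exposure.
#' @param p_threshold Significance threshold on the unadjusted p-value.
#' @param min_total_count Drop transcripts with total raw count below
#'   this (default 10).
#' @return A list of class `de_result`: `table` (all tested transcripts
#'   with statistics and `de` flag), `de` (significant subset),
#'   `class_tally`, `subclass_tally`, `p_threshold`.
#' @export
differential_expression <- function(transcripts, groups,
                                    p_threshold = 0.001,
                                    min_total_count = 10) {
  if (!all(c("id", "class") %in% names(transcripts))) {
    abort("`transcripts` must have `id` and `class` columns.")
  }
  if (anyNA(transcripts$class)) abort("Missing RNA class label(s).")
  classes <- c("mRNA", "lncRNA", "sncRNA")
  bad <- setdiff(unique(transcripts$class), classes)
  if (length(bad) > 0L) {
    abort(sprintf("Invalid RNA class label(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  g_named <- groups
  sample_cols <- if (is.data.frame(groups)) groups$sample else names(groups)
  if (is.null(sample_cols)) abort("`groups` must name the sample columns.")
  missing <- setdiff(sample_cols, names(transcripts))
  if (length(missing) > 0L) {
    abort(sprintf("Missing sample column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  m <- as.matrix(transcripts[, sample_cols, drop = FALSE])
  rownames(m) <- transcripts$id
  g <- resolve_groups(g_named, sample_cols,
                      levels = c("control", "exposure"))

  keep <- rowSums(m) >= min_total_count
  tx <- transcripts[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  norm <- normalization_factors(m)

  res <- purrr::map_dfr(intersect(classes, unique(tx$class)),
                        function(cls) {
    rows <- which(tx$class == cls)
    sub <- m[rows, , drop = FALSE]
    phi <- as.numeric(estimate_common_dispersion(sub, g, norm))
    p <- nb_exact_test(sub, g, norm, dispersion = phi)
    mm <- group_means_normalized(sub, g, norm)
    tibble(id = tx$id[rows], p_value = p,
           log2fc = log2((mm$exposure + 0.5) / (mm$control + 0.5)),
           mean_control = mm$control, mean_exposure = mm$exposure,
           dispersion_used = phi)
  })
  table <- tx |>
    select(-all_of(sample_cols)) |>
    inner_join(res, by = "id") |>
    mutate(fdr = bh_fdr(.data$p_value),
           de = .data$p_value < p_threshold)
  de <- filter(table, .data$de)
  class_tally <- tibble(class = classes) |>
    left_join(count(de, .data$class), by = "class") |>
    mutate(n_de = dplyr::coalesce(.data$n, 0L)) |>
    select("class", "n_de")
  subclasses <- c("miRNA", "piRNA", "tRNA", "other")
  snc <- filter(de, .data$class == "sncRNA")
  subclass_tally <- tibble(subclass = subclasses) |>
    left_join(count(snc, .data$subclass), by = "subclass") |>
    mutate(n_de = dplyr::coalesce(.data$n, 0L)) |>
    select("subclass", "n_de")
  structure(list(table = table, de = de, class_tally = class_tally,
                 subclass_tally = subclass_tally,
                 p_threshold = p_threshold),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %d transcripts tested, %d DE at p < %g\n",
              nrow(x$table), nrow(x$de), x$p_threshold))
  print(x$class_tally)
  invisible(x)
}

#' @rdname tidy-dmrkit
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname glance-dmrkit
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tallies <- setNames(x$class_tally$n_de,
                      paste0("n_de_", tolower(x$class_tally$class)))
  bind_cols(tibble(n_tested = nrow(x$table), n_de = nrow(x$de),
                   p_threshold = x$p_threshold),
            as_tibble(as.list(tallies)))
}

#' @rdname autoplot-dmrkit
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  df <- bind_rows(
    object$class_tally |> rename(label = "class") |>
      mutate(panel = "RNA class"),
    object$subclass_tally |> rename(label = "subclass") |>
      mutate(panel = "sncRNA subclass"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n_de)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "differentially expressed transcripts") +
    ggplot2::theme_minimal()
}
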