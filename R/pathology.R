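#' Control-based disease cutoffs (mean + 2 SD)
#'
#' For each observer and abnormality category, the cutoff is the mean
#' count among control animals plus `sd_multiplier` (default 2) sample
#' standard deviations. Observers score sections independently, so each
#' observer is compared against their own control scores; a pooled
#' variant is available via `per_observer = FALSE`.
#'
#' @param records Long pathology tibble: `animal_id`, `lineage`,
#'   `observer`, plus one numeric count column per category.
#' @param sd_multiplier Number of standard deviations above the control
#'   mean (default 2).
#' @param categories Category column names; defaults to every numeric
#'   column after the id columns.
#' @param per_observer Compute cutoffs per observer (default) or pooled
#'   over observers.
#' @return Tibble with `observer`, `category`, `cutoff`.
#' @export
#' @examples
#' rec <- tibble::tibble(animal_id = c("a", "b", "c"),
#'                       lineage = "control", observer = "obs1",
#'                       atrophy = c(1, 2, 3))
#' compute_cutoffs(rec)  # mean 2 + 2 * sd 1 = 4
compute_cutoffs <- function(records, sd_multiplier = 2,
                            categories = NULL, per_observer = TRUE) {
  categories <- categories %||% pathology_categories(records)
  ctrl <- filter(records, .data$lineage == "control")
  if (length(unique(ctrl$animal_id)) < 2L) {
    abort("Need at least two control animals to compute cutoffs.")
  }
  long <- ctrl |>
    tidyr::pivot_longer(all_of(categories), names_to = "category",
                        values_to = "count")
  if (!per_observer) {
    pooled <- long |>
      group_by(.data$category) |>
      summarise(cutoff = mean(.data$count) +
                  sd_multiplier * sd(.data$count), .groups = "drop")
    return(tidyr::crossing(observer = unique(records$observer),
                           pooled) |>
             select("observer", "category", "cutoff"))
  }
  long |>
    group_by(.data$observer, .data$category) |>
    summarise(cutoff = mean(.data$count) +
                sd_multiplier * sd(.data$count), .groups = "drop")
}

pathology_categories <- function(records) {
  setdiff(names(records)[vapply(records, is.numeric, logical(1))],
          c("animal_id", "lineage", "observer"))
}

#' Call disease per animal with observer consensus
#'
#' An observer marks an animal diseased when any category count is
#' strictly above that observer's cutoff for the category; the animal
#' is declared diseased when at least `min_observers` observers agree
#' (2-of-3 under the defaults). Control animals are classified under
#' the same rule, which yields the control background frequency.
#'
#' @param records Long pathology tibble (see [compute_cutoffs()]).
#' @param cutoffs Tibble from [compute_cutoffs()] covering every
#'   observer present in `records`.
#' @param min_observers Observers required for consensus (default 2).
#' @return A list of class `disease_calls`: `cutoffs`, `per_observer`
#'   (animal x observer calls), `consensus` (per-animal call),
#'   `table_2x2` (diseased/healthy x lineage matrix), `fisher_p`,
#'   `frequencies` (per-lineage disease frequency).
#' @export
call_disease <- function(records, cutoffs, min_observers = 2L) {
  categories <- intersect(unique(cutoffs$category),
                          names(records))
  if (length(categories) == 0L) {
    abort("No cutoff category matches a column of `records`.")
  }
  missing_obs <- setdiff(unique(records$observer),
                         unique(cutoffs$observer))
  if (length(missing_obs) > 0L) {
    abort(sprintf("No cutoffs for observer(s): %s.",
                  paste(missing_obs, collapse = ", ")))
  }
  per_obs <- records |>
    tidyr::pivot_longer(all_of(categories), names_to = "category",
                        values_to = "count") |>
    inner_join(cutoffs, by = c("observer", "category")) |>
    group_by(.data$animal_id, .data$lineage, .data$observer) |>
    summarise(diseased = any(.data$count > .data$cutoff),
              .groups = "drop")
  consensus <- per_obs |>
    group_by(.data$animal_id, .data$lineage) |>
    summarise(n_observers = n(),
              n_observers_diseased = sum(.data$diseased),
              diseased = sum(.data$diseased) >= min_observers,
              .groups = "drop")
  # control first when present
  lineages <- sort(unique(consensus$lineage))
  lineages <- c(intersect("control", lineages),
                setdiff(lineages, "control"))
  tab <- vapply(lineages, function(l) {
    x <- consensus$diseased[consensus$lineage == l]
    c(diseased = sum(x), healthy = sum(!x))
  }, numeric(2))
  freqs <- tibble(lineage = lineages,
                  n_animals = colSums(tab),
                  n_diseased = tab["diseased", ],
                  frequency = tab["diseased", ] / colSums(tab))
  fisher_p <- if (length(lineages) == 2L) {
    fisher_exact_2x2(tab)
  } else {
    NA_real_
  }
  structure(list(cutoffs = cutoffs, per_observer = per_obs,
                 consensus = consensus, table_2x2 = tab,
                 fisher_p = fisher_p, frequencies = freqs,
                 min_observers = min_observers),
            class = "disease_calls")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the count in cell (1,1) is
#' hypergeometric; the two-sided p-value sums the probabilities of all
#' tables no more probable than the observed one (probability-mass
#' ordering, ties included). Any zero margin gives p = 1.
#'
#' @param table A 2x2 matrix (or something coercible) of non-negative
#'   integer counts.
#' @return The two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) abort("Expected a 2x2 table.")
  if (any(tb < 0) || any(tb != floor(tb))) {
    abort("Table entries must be non-negative integers.")
  }
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  if (m == 0 || n == 0 || k == 0 || sum(tb[, 2]) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tb[1, 1], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Compare disease frequency between lineages
#'
#' The full pathology statistic: control-based mean + `sd_multiplier`
#' SD cutoffs per observer and category, per-animal disease calls with
#' observer consensus, the lineage 2x2 table and Fisher's exact test.
#'
#' @inheritParams compute_cutoffs
#' @inheritParams call_disease
#' @return A `disease_calls` object (see [call_disease()]).
#' @export
compare_lineages <- function(records, sd_multiplier = 2,
                             min_observers = 2L, per_observer = TRUE) {
  if (!all(c("control") %in% unique(records$lineage)) ||
      length(unique(records$lineage)) < 2L) {
    abort("`records` must contain a control lineage and one comparison lineage.")
  }
  cutoffs <- compute_cutoffs(records, sd_multiplier = sd_multiplier,
                             per_observer = per_observer)
  call_disease(records, cutoffs, min_observers = min_observers)
}

#' @export
print.disease_calls <- function(x, ...) {
  cat("<disease_calls>\n")
  print(x$frequencies)
  cat(sprintf("Fisher exact p = %.4g\n", x$fisher_p))
  invisible(x)
}

#' @rdname tidy-dmrkit
#' @method tidy disease_calls
#' @export
tidy.disease_calls <- function(x, ...) x$consensus

#' @rdname glance-dmrkit
#' @method glance disease_calls
#' @export
glance.disease_calls <- function(x, ...) {
  wide <- x$frequencies |>
    select("lineage", "frequency") |>
    tidyr::pivot_wider(names_from = "lineage",
                       values_from = "frequency",
                       names_prefix = "frequency_")
  bind_cols(wide, tibble(fisher_p = x$fisher_p,
                         n_animals = sum(x$frequencies$n_animals)))
}

#' @rdname autoplot-dmrkit
#' @method autoplot disease_calls
#' @export
autoplot.disease_calls <- function(object, ...) {
  ggplot2::ggplot(object$frequencies,
                  ggplot2::aes(x = .data$lineage, y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey30", width = 0.6) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "animals with prostate pathology",
                  subtitle = sprintf("Fisher exact p = %.3g",
                                     object$fisher_p)) +
    ggplot2::theme_minimal()
}
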