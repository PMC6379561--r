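#' Simulate observer-scored histopathology counts
#'
#' Each animal carries a latent abnormality rate per category:
#' `baseline_rate` for all control animals and unaffected exposed
#' animals, plus `excess_rate` in one or more categories for an
#' `affected_fraction` of exposed animals. Observers score the same
#' section independently, so observer replicates are independent
#' Poisson draws around the animal's latent rate.
#'
#' @param config A [simulation_config()] (uses its `pathology_config`
#'   and `seed`).
#' @return A list of class `pathology_sim`: `records` (long tibble with
#'   columns `animal_id`, `lineage`, `observer`, one column per
#'   category) and `truth` (tibble `animal_id`, `affected`,
#'   `categories`).
#' @export
simulate_pathology_scores <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pc <- config$pathology_config
  with_stage_seed(config$seed, 3L, {
    animals <- tibble(
      animal_id = c(sprintf("C%02d", seq_len(pc$n_control)),
                    sprintf("E%02d", seq_len(pc$n_exposed))),
      lineage = rep(c("control", "exposed"),
                    c(pc$n_control, pc$n_exposed)))
    affected <- animals$lineage == "exposed" &
      runif(nrow(animals)) < pc$affected_fraction
    # each affected animal gets the excess in >= 1 randomly chosen category
    n_cat <- length(pc$categories)
    rate <- matrix(pc$baseline_rate, nrow = nrow(animals), ncol = n_cat,
                   dimnames = list(animals$animal_id, pc$categories))
    affected_cats <- vector("list", nrow(animals))
    for (i in which(affected)) {
      k <- sample.int(n_cat, 1L)
      cats <- sample(pc$categories, k)
      rate[i, cats] <- rate[i, cats] + pc$excess_rate
      affected_cats[[i]] <- cats
    }
    records <- purrr::map_dfr(seq_len(pc$n_observers), function(obs) {
      cnt <- matrix(rpois(length(rate), rate), nrow = nrow(rate),
                    dimnames = dimnames(rate))
      bind_cols(animals,
                tibble(observer = paste0("obs", obs)),
                as_tibble(cnt))
    }) |>
      arrange(.data$animal_id, .data$observer)
    truth <- tibble(
      animal_id = animals$animal_id,
      lineage = animals$lineage,
      affected = affected,
      categories = vapply(affected_cats, function(x) {
        if (is.null(x)) "" else paste(x, collapse = ",")
      }, character(1)))
    structure(list(records = records, truth = truth, config = config),
              class = "pathology_sim")
  })
}

#' Write pathology records as TSV
#'
#' Long format: `animal_id`, `lineage`, `observer`, then one column per
#' category, with a provenance comment header.
#'
#' @param sim A `pathology_sim` object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_pathology_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "pathology_sim"))
  write_tsv_provenance(sim$records, path, seed = sim$config$seed)
}

#' Read pathology records from TSV
#'
#' @param path TSV with columns `animal_id`, `lineage`, `observer` and
#'   one count column per category.
#' @return Tibble of records.
#' @export
read_pathology_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  need <- c("animal_id", "lineage", "observer")
  if (!all(need %in% names(df))) {
    abort(sprintf("Pathology TSV must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  df
}
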