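#' Simulate transcript count tables with planted differential expression
#'
#' Generates mRNA, lncRNA and sncRNA transcripts (sncRNA subclassed into
#' miRNA, piRNA, tRNA, other) with negative binomial counts for
#' `n_samples_per_group` samples per lineage. A `de_fraction` of each
#' class carries a multiplicative group effect (`de_fold_change`,
#' direction split 50/50). Transcripts receive genomic intervals placed
#' uniformly on the simulated genome, except a configurable fraction of
#' sncRNAs left with unknown location, as is common for small-RNA
#' annotation.
#'
#' @param config A [simulation_config()] (uses its `de_config`,
#'   `n_samples_per_group`, `seed`).
#' @param genome Optional `sim_genome` supplying chromosome sizes for
#'   transcript intervals; without it all locations are unknown.
#' @return A list of class `rna_sim`: `transcripts` (tibble with columns
#'   `id`, `class`, `subclass`, `chrom`, `start`, `end` and one column
#'   per sample), `groups`, `truth` (tibble `id`, `class`, `direction`,
#'   `fold_change`) and `config`.
#' @export
simulate_transcript_counts <- function(config, genome = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  dc <- config$de_config
  n_per_class <- dc$n_transcripts
  if (sum(n_per_class) == 0L) abort("No transcripts configured.")

  with_stage_seed(config$seed, 2L, {
    n <- config$n_samples_per_group
    samples <- c(paste0("control_", seq_len(n)),
                 paste0("exposure_", seq_len(n)))
    groups <- setNames(rep(c("control", "exposure"), each = n), samples)

    tx <- purrr::imap_dfr(n_per_class, function(k, cls) {
      if (k == 0L) return(tibble())
      sub <- if (cls == "sncRNA") {
        sample(names(dc$sncrna_subclass_prop), k, replace = TRUE,
               prob = dc$sncrna_subclass_prop)
      } else {
        rep(NA_character_, k)
      }
      tibble(id = sprintf("%s_%04d", tolower(cls), seq_len(k)),
             class = cls, subclass = sub)
    })
    n_tx <- nrow(tx)

    # planted effects: an exact de_fraction per class
    truth <- tx |>
      group_by(.data$class) |>
      mutate(is_de = row_number() %in%
               sample.int(n(), size = round(dc$de_fraction * n()))) |>
      ungroup() |>
      filter(.data$is_de) |>
      mutate(direction = sample(rep(c("up", "down"), length.out = n())),
             fold_change = dc$de_fold_change) |>
      select("id", "class", "direction", "fold_change")

    # genomic intervals (sncRNA partially unplaced)
    tx$chrom <- NA_character_
    tx$start <- NA_integer_
    tx$end <- NA_integer_
    if (!is.null(genome)) {
      placed <- rep(TRUE, n_tx)
      is_snc <- tx$class == "sncRNA"
      placed[is_snc] <- runif(sum(is_snc)) >= dc$unknown_location_fraction
      sizes <- genome$chrom_sizes
      ci <- sample.int(nrow(sizes), n_tx, replace = TRUE,
                       prob = sizes$size)
      tx_len <- ifelse(tx$class == "mRNA", 2000L,
                       ifelse(tx$class == "lncRNA", 1000L, 100L))
      st <- floor(runif(n_tx) * pmax(sizes$size[ci] - tx_len, 1))
      tx$chrom[placed] <- sizes$chrom[ci[placed]]
      tx$start[placed] <- as.integer(st[placed])
      tx$end[placed] <- as.integer(pmin(st + tx_len,
                                        sizes$size[ci]))[placed]
    }

    mu <- matrix(dc$mean_count, nrow = n_tx, ncol = 2L * n,
                 dimnames = list(tx$id, samples))
    if (nrow(truth) > 0L) {
      ti <- match(truth$id, tx$id)
      eff <- ifelse(truth$direction == "up", truth$fold_change,
                    1 / truth$fold_change)
      mu[ti, groups == "exposure"] <-
        mu[ti, groups == "exposure"] * eff
    }
    counts <- draw_nb_counts(mu, dc$dispersion)
    structure(list(
      transcripts = bind_cols(tx, as_tibble(counts)),
      groups = groups,
      truth = truth,
      config = config
    ), class = "rna_sim")
  })
}

#' Write a transcript count TSV
#'
#' Columns `id`, `class`, `subclass`, `chrom`, `start`, `end` then one
#' column per sample, with a provenance comment header.
#'
#' @param rna An `rna_sim` object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_transcript_tsv <- function(rna, path) {
  stopifnot(inherits(rna, "rna_sim"))
  write_tsv_provenance(rna$transcripts, path, seed = rna$config$seed)
}

#' Simulate a gene annotation over the synthetic genome
#'
#' Places non-overlapping gene models uniformly along the genome, for
#' exercising gene association and category/pathway tallies. Each gene
#' also receives a functional category and zero or more pathway labels,
#' returned as a long mapping table of the kind normally supplied as a
#' static gene-to-category file.
#'
#' @param config A [simulation_config()].
#' @param genome A `sim_genome`.
#' @param n_genes Number of genes to place.
#' @param gene_length_bp Range of gene lengths.
#' @return A list of class `gene_sim`: `genes` (tibble `gene_id`,
#'   `symbol`, `chrom`, `start`, `end`, `strand`), `category_map` and
#'   `pathway_map` (tibbles `gene_id`, `label`).
#' @export
simulate_gene_models <- function(config, genome, n_genes = 300L,
                                 gene_length_bp = c(2000L, 20000L)) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genome, "sim_genome"))
  categories <- c("signaling", "transcription", "development",
                  "receptor", "metabolism", "cytoskeleton", "transport")
  pathways <- c("pathways_in_cancer", "wnt_signaling", "mapk_signaling",
                "calcium_signaling", "focal_adhesion")
  with_stage_seed(config$seed, 4L, {
    sizes <- genome$chrom_sizes
    per_chrom <- table(factor(
      sample(sizes$chrom, n_genes, replace = TRUE, prob = sizes$size),
      levels = sizes$chrom))
    genes <- purrr::map_dfr(sizes$chrom, function(ch) {
      k <- per_chrom[[ch]]
      if (k == 0L) return(tibble())
      size <- sizes$size[sizes$chrom == ch]
      len <- as.integer(runif(k, gene_length_bp[1], gene_length_bp[2]))
      st <- sort(as.integer(floor(runif(k) * pmax(size - len, 1))))
      en <- pmin(st + len, size)
      tibble(chrom = ch, start = st, end = as.integer(en))
    }) |>
      arrange(.data$chrom, .data$start)
    # drop overlapping placements (keep the first of each clash)
    genes <- genes |>
      group_by(.data$chrom) |>
      filter(is.na(lag(.data$end)) | .data$start >= cummax_lag(.data$end)) |>
      ungroup()
    n_kept <- nrow(genes)
    genes <- genes |>
      mutate(gene_id = sprintf("gene_%04d", row_number()),
             symbol = sprintf("Gn%04d", row_number()),
             strand = sample(c("+", "-"), n_kept, replace = TRUE)) |>
      select("gene_id", "symbol", "chrom", "start", "end", "strand")
    category_map <- tibble(
      gene_id = genes$gene_id,
      label = sample(categories, n_kept, replace = TRUE))
    n_pw <- rbinom(n_kept, 2L, 0.3)
    pathway_map <- purrr::map_dfr(seq_len(n_kept), function(i) {
      if (n_pw[i] == 0L) {
        return(tibble(gene_id = character(), label = character()))
      }
      tibble(gene_id = genes$gene_id[i],
             label = sample(pathways, n_pw[i]))
    })
    if (nrow(pathway_map) == 0L) {
      pathway_map <- tibble(gene_id = character(),
                            label = character())
    }
    structure(list(genes = genes, category_map = category_map,
                   pathway_map = pathway_map),
              class = "gene_sim")
  })
}

cummax_lag <- function(end) {
  cm <- cummax(end)
  c(-Inf, cm[-length(cm)])
}
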