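test_that("genome simulation is deterministic and hits the CpG rate", {
  cfg <- simulation_config(seed = 7, chrom_length_bp = 2e5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$seq, g2$seq)

  dens <- sum(count_cpg(g1$seq)) * 100 / sum(g1$chrom_sizes$size)
  expect_gt(dens, cfg$cpg_rate_background * 0.8)
  expect_lt(dens, cfg$cpg_rate_background * 1.2)

  # CpG-desert background: modal 100 bp window carries 1-2 CpGs
  w <- window_cpg_counts(tile_genome(g1$chrom_sizes, 100), g1)
  mode_cpg <- as.integer(names(which.max(table(w$cpg_count))))
  expect_true(mode_cpg %in% c(1L, 2L))
})

test_that("a zero CpG rate yields a CG-free genome", {
  cfg <- simulation_config(seed = 3, chrom_length_bp = 5e4,
                           cpg_rate_background = 0)
  g <- simulate_genome(cfg)
  expect_identical(sum(count_cpg(g$seq)), 0L)
})

test_that("genome simulation rejects non-positive lengths", {
  expect_error(simulation_config(chrom_length_bp = 0), "chrom_length_bp")
  expect_error(simulation_config(chrom_length_bp = -5), "chrom_length_bp")
})

test_that("planted regions are window-aligned, separated and exact in number", {
  cfg <- simulation_config(seed = 5, chrom_length_bp = 1e6,
                           n_planted_dmrs = 20,
                           min_dmr_separation_bp = 5000)
  sim <- simulate_medip_experiment(cfg, simulate_genome(cfg))
  tr <- sim$truth
  expect_identical(nrow(tr), 20L)
  expect_true(all(tr$start %% cfg$window_bp == 0))
  expect_true(all((tr$end - tr$start) %in% seq(300, 500, by = 100)))
  expect_true(all(tr$end <= cfg$chrom_length_bp))
  gaps <- tr$start[-1] - tr$end[-nrow(tr)]
  expect_true(all(gaps >= cfg$min_dmr_separation_bp))
  expect_setequal(unique(tr$direction), c("increase", "decrease"))
  expect_equal(sum(tr$direction == "increase"), 10)
})

test_that("a unit fold change means no planted effects", {
  cfg <- simulation_config(seed = 2, chrom_length_bp = 1e5,
                           n_planted_dmrs = 5,
                           methylation_fold_change = 1)
  sim <- simulate_medip_experiment(cfg, simulate_genome(cfg))
  expect_identical(nrow(sim$truth), 0L)
  expect_true(all(sim$mu == cfg$mean_fragment_count_per_window))
})

test_that("null window counts match the negative binomial moments", {
  cfg <- simulation_config(seed = 9, chrom_length_bp = 1e5,
                           n_planted_dmrs = 0, dispersion = 0.1,
                           mean_fragment_count_per_window = 50)
  g <- structure(list(seq = NULL,
                      chrom_sizes = tibble::tibble(chrom = "chr1",
                                                   size = 1e5)),
                 class = "sim_genome")
  sim <- simulate_medip_experiment(cfg, g)
  x <- as.numeric(sim$counts$counts)   # 1000 windows x 6 samples
  mu <- cfg$mean_fragment_count_per_window
  se <- sqrt((mu + cfg$dispersion * mu^2) / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("fragment emission conserves counts and round-trips exactly", {
  tm <- tiny_medip(13)
  frags <- fragments_from_counts(tm$sim)
  per_sample <- table(frags$sample)
  expect_identical(as.integer(per_sample[tm$sim$counts$samples]),
                   as.integer(colSums(tm$sim$counts$counts)))

  wc <- count_fragments(frags, tm$sim$counts$windows,
                        samples = tm$sim$counts$samples)
  expect_identical(unname(wc$counts), unname(tm$sim$counts$counts))

  # BED files carry the same fragments
  dir <- withr::local_tempdir()
  paths <- write_fragments_bed(tm$sim, dir)
  back <- read_fragments_bed(paths)
  expect_identical(nrow(back), nrow(frags))
  wc2 <- count_fragments(back, tm$sim$counts$windows,
                         samples = tm$sim$counts$samples)
  expect_identical(wc2$counts, wc$counts)
})

test_that("transcript simulation plants the configured DE set", {
  cfg <- simulation_config(
    seed = 4,
    de_config = de_config(n_transcripts = c(mRNA = 600, lncRNA = 200,
                                            sncRNA = 200),
                          de_fraction = 0.05))
  rna <- simulate_transcript_counts(cfg)
  expect_identical(nrow(rna$transcripts), 1000L)
  expect_identical(nrow(rna$truth), 50L)
  expect_true(all(rna$truth$id %in% rna$transcripts$id))
  expect_setequal(unique(rna$transcripts$class),
                  c("mRNA", "lncRNA", "sncRNA"))
  snc <- rna$transcripts[rna$transcripts$class == "sncRNA", ]
  expect_true(all(snc$subclass %in% c("miRNA", "piRNA", "tRNA",
                                      "other")))

  null_rna <- simulate_transcript_counts(
    simulation_config(seed = 4,
                      de_config = de_config(de_fraction = 0)))
  expect_identical(nrow(null_rna$truth), 0L)
})

test_that("sncRNA unknown-location fraction is honored with a genome", {
  cfg <- simulation_config(
    seed = 8, chrom_length_bp = 1e5,
    de_config = de_config(n_transcripts = c(sncRNA = 400L),
                          unknown_location_fraction = 0.5))
  g <- simulate_genome(cfg)
  rna <- simulate_transcript_counts(cfg, g)
  frac_unknown <- mean(is.na(rna$transcripts$chrom))
  expect_gt(frac_unknown, 0.35)
  expect_lt(frac_unknown, 0.65)
})

test_that("pathology simulation has the study's shape and honest truth", {
  ps <- simulate_pathology_scores(simulation_config(seed = 6))
  rec <- ps$records
  expect_identical(length(unique(rec$animal_id)), 53L)
  expect_identical(length(unique(rec$observer)), 3L)
  expect_identical(nrow(rec), 53L * 3L)
  expect_true(all(c("atrophy", "hyperplasia", "vacuoles") %in%
                    names(rec)))
  expect_identical(sum(ps$truth$lineage == "control"), 26L)
  expect_identical(sum(ps$truth$lineage == "exposed"), 27L)
  expect_true(all(!ps$truth$affected[ps$truth$lineage == "control"]))

  all_affected <- simulate_pathology_scores(simulation_config(
    seed = 6,
    pathology_config = pathology_config(affected_fraction = 1,
                                        excess_rate = 10)))
  expect_true(all(all_affected$truth$affected[
    all_affected$truth$lineage == "exposed"]))
})

test_that("with all effects off the group labels are exchangeable", {
  # Distribution of the sub-0.1 p-value fraction is unchanged when the
  # labeling is permuted, across replicate seeds.
  stat_orig <- numeric(50)
  stat_perm <- numeric(50)
  for (s in seq_len(50)) {
    cfg <- simulation_config(seed = 100 + s, chrom_length_bp = 2e4,
                             n_planted_dmrs = 0)
    g <- structure(list(seq = NULL,
                        chrom_sizes = tibble::tibble(chrom = "chr1",
                                                     size = 2e4)),
                   class = "sim_genome")
    sim <- simulate_medip_experiment(cfg, g)
    wr <- test_windows(sim$counts, sim$groups)
    stat_orig[s] <- mean(wr$p_value < 0.1)
    perm <- sim$groups
    perm[c("control_1", "exposure_1")] <- perm[c("exposure_1",
                                                 "control_1")]
    wr_p <- test_windows(sim$counts, perm)
    stat_perm[s] <- mean(wr_p$p_value < 0.1)
  }
  expect_gt(suppressWarnings(ks.test(stat_orig, stat_perm)$p.value),
            0.01)
})

test_that("gene model simulation places non-overlapping labeled genes", {
  cfg <- simulation_config(seed = 21, chrom_length_bp = 2e6)
  g <- simulate_genome(cfg)
  gs <- simulate_gene_models(cfg, g, n_genes = 100)
  genes <- gs$genes
  expect_true(all(genes$start < genes$end))
  by_chrom <- split(genes, genes$chrom)
  for (b in by_chrom) {
    if (nrow(b) > 1) {
      expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
  }
  expect_identical(nrow(gs$category_map), nrow(genes))
  expect_true(all(gs$pathway_map$gene_id %in% genes$gene_id))
})
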