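test_that("gene association honors the inclusive 10 kb gap convention", {
  dmrs <- tibble::tibble(dmr_id = c("d1", "d2", "d3"),
                         chrom = "chr1",
                         start = c(0L, 0L, 0L),
                         end = c(100L, 100L, 100L))
  genes <- tibble::tibble(gene_id = c("inside", "at10k", "beyond"),
                          chrom = "chr1",
                          start = c(50L, 10100L, 10101L),
                          end = c(500L, 10200L, 10200L))
  out <- associate_genes(dmrs[1, ], genes)
  # gap 0 (overlap), gap exactly 10000 (associated), gap 10001 (not)
  expect_setequal(out$gene_id, c("inside", "at10k"))
  expect_identical(out$distance_bp[out$gene_id == "inside"], 0L)
  expect_identical(out$distance_bp[out$gene_id == "at10k"], 10000L)
})

test_that("gene association matches the all-pairs oracle", {
  withr::with_seed(21, {
    for (i in 1:10) {
      dmrs <- random_intervals(40)
      dmrs$dmr_id <- sprintf("d%02d", seq_len(nrow(dmrs)))
      genes <- random_intervals(40)
      genes$gene_id <- sprintf("g%02d", seq_len(nrow(genes)))
      out <- associate_genes(dmrs, genes, max_dist_bp = 5000)
      orc <- oracle_associate(dmrs, genes, max_dist = 5000)
      got <- out[order(out$dmr_id, out$gene_id),
                 c("dmr_id", "gene_id")]
      expect_identical(unname(as.matrix(got)), unname(as.matrix(orc)))
    }
  })
})

test_that("association distance is symmetric under role reversal", {
  withr::with_seed(22, {
    a <- random_intervals(30)
    a$dmr_id <- paste0("a", seq_len(nrow(a)))
    b <- random_intervals(30)
    b$gene_id <- paste0("b", seq_len(nrow(b)))
  })
  ab <- associate_genes(a, b, max_dist_bp = 3000)
  b2 <- b; names(b2)[names(b2) == "gene_id"] <- "dmr_id"
  a2 <- a; names(a2)[names(a2) == "dmr_id"] <- "gene_id"
  ba <- associate_genes(b2, a2, max_dist_bp = 3000)
  expect_identical(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$dmr_id, ab$gene_id),
                  paste(ba$gene_id, ba$dmr_id))
})

test_that("DMRs on chromosomes without genes warn and associate nothing", {
  dmrs <- tibble::tibble(dmr_id = "d1", chrom = "chrUn",
                         start = 0L, end = 100L)
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 0L, end = 100L)
  expect_warning(out <- associate_genes(dmrs, genes), "chrUn")
  expect_identical(nrow(out), 0L)
})

test_that("interval Venn counts satisfy the partition identities", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                      end = c(100L, 1100L))
  same <- venn_intervals(a, a)
  expect_identical(same$common_a, 2L)
  expect_identical(same$a_only, 0L)
  expect_identical(same$b_only, 0L)

  b <- tibble::tibble(chrom = "chr2", start = 0L, end = 100L)
  disjoint <- venn_intervals(a, b)
  expect_identical(disjoint$common, 0)
  expect_identical(disjoint$a_only, 2L)
  expect_identical(disjoint$b_only, 1L)
})

test_that("interval Venn agrees with the quadratic oracle", {
  withr::with_seed(23, {
    for (i in 1:10) {
      a <- random_intervals(200)
      b <- random_intervals(200)
      v <- venn_intervals(a, b)
      fa <- oracle_overlap_flags(a, b)
      fb <- oracle_overlap_flags(b, a)
      expect_identical(v$common_a, sum(fa))
      expect_identical(v$common_b, sum(fb))
      expect_identical(v$a_only + v$common_a, v$n_a)
      expect_identical(v$b_only + v$common_b, v$n_b)
    }
  })
})

test_that("features of unknown location are excluded with a message", {
  a <- tibble::tibble(chrom = c("chr1", NA), start = c(0L, NA),
                      end = c(100L, NA))
  b <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L)
  expect_message(v <- venn_intervals(a, b), "unknown location")
  expect_identical(v$n_a, 1L)
  expect_identical(v$common_a, 1L)
})

test_that("id Venns compute exact set overlaps", {
  same <- venn_ids(c("x", "y"), c("x", "y"))
  expect_identical(same$common, 2L)
  disjoint <- venn_ids(c("x"), c("y"))
  expect_identical(disjoint$common, 0L)
  v <- venn_ids(c("x", "y", "z"), c("y", "z", "w"))
  expect_identical(v$common, 2L)
  expect_identical(v$a_only, 1L)
  expect_identical(v$b_only, 1L)
  expect_warning(vd <- venn_ids(c("x", "x", "y"), "y"), "Duplicate")
  expect_identical(vd$n_a, 2L)
})

test_that("category tallies count distinct genes once per label", {
  mapping <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g3"),
    label = c("signaling", "signaling", "signaling", "transport"))
  out <- map_counts(c("g1", "g2", "g3"), mapping)
  expect_identical(out$n_genes[out$label == "signaling"], 3L)
  expect_identical(out$n_genes[out$label == "transport"], 1L)
  expect_identical(out$n_genes[out$label == "unknown"], 0L)

  # unmapped genes fall into the unknown bucket
  out2 <- map_counts(c("g1", "g9"), mapping)
  expect_identical(out2$n_genes[out2$label == "unknown"], 1L)

  # empty gene list
  out3 <- map_counts(character(0), mapping)
  expect_identical(sum(out3$n_genes), 0L)
  expect_true("unknown" %in% out3$label)
})

test_that("malformed mapping files are rejected with a line number", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "map.tsv")
  writeLines(c("gene_id\tlabel", "g1\tsignaling", "g2"), path)
  expect_error(map_counts("g1", path), "line 3")
  path2 <- file.path(dir, "ok.tsv")
  writeLines(c("gene_id\tlabel", "g1\tsignaling"), path2)
  out <- map_counts("g1", path2)
  expect_identical(out$n_genes[out$label == "signaling"], 1L)
})

test_that("gene models read from BED keep half-open coordinates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "genes.bed")
  writeLines(c("#seed=1", "chr1\t100\t500\tgeneA\t0\t+"), path)
  gm <- read_gene_models(path)
  expect_identical(gm$start, 100L)
  expect_identical(gm$end, 500L)
  expect_identical(gm$gene_id, "geneA")
  expect_identical(gm$strand, "+")
})
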