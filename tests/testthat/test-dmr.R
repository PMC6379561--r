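flat_windows <- function(n, p_default = 0.5) {
  tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1L) * 100L,
                 end = seq_len(n) * 100L, p_value = p_default,
                 log2fc = 1)
}

test_that("an isolated seed window becomes a single-window DMR", {
  w <- flat_windows(50)
  w$p_value[20] <- 1e-8
  d <- call_dmrs(w)
  expect_identical(nrow(d), 1L)
  expect_identical(d$start, 1900L)
  expect_identical(d$end, 2000L)
  expect_identical(d$length_bp, 100L)
  expect_identical(d$n_windows_significant, 1L)
  expect_false(d$is_multiple_window)
  expect_identical(d$direction, "increase")
})

test_that("edges extend through sub-0.1 windows reachable within 1 kb", {
  # seed at [1000,1100); extension candidates at [1100,1200) and
  # [1900,2000); the next sub-0.1 window at [3100,3200) is more than
  # 1000 bp from the span and must be excluded.
  w <- flat_windows(100)
  w$p_value[11] <- 1e-8    # [1000,1100) seed
  w$p_value[12] <- 0.05    # [1100,1200)
  w$p_value[20] <- 0.05    # [1900,2000)
  w$p_value[32] <- 0.05    # [3100,3200)
  d <- call_dmrs(w)
  expect_identical(nrow(d), 1L)
  expect_identical(d$start, 1000L)
  expect_identical(d$end, 2000L)
  orc <- oracle_call_dmrs(w)
  expect_identical(d$start, orc$start)
  expect_identical(d$end, orc$end)
})

test_that("two seeds whose extensions chain together merge into one DMR", {
  w <- flat_windows(100)
  w$p_value[10] <- 1e-8
  w$p_value[15] <- 0.05   # bridges: within 1 kb of both seeds' spans
  w$p_value[20] <- 1e-8
  d <- call_dmrs(w)
  expect_identical(nrow(d), 1L)
  expect_identical(d$n_windows_significant, 2L)
})

test_that("call_dmrs matches the brute-force fixed point on random instances", {
  withr::with_seed(12, {
    for (i in 1:60) {
      w <- random_window_instance(sample(50:400, 1),
                                  n_chrom = sample(1:2, 1))
      d <- call_dmrs(w)
      orc <- oracle_call_dmrs(w)
      expect_identical(nrow(d), nrow(orc))
      if (nrow(d) > 0) {
        expect_identical(d$chrom, orc$chrom)
        expect_identical(as.integer(d$start), as.integer(orc$start))
        expect_identical(as.integer(d$end), as.integer(orc$end))
      }
    }
  })
})

test_that("extension is a fixed point: no outside sub-0.1 window is in reach", {
  withr::with_seed(13, {
    for (i in 1:20) {
      w <- random_window_instance(300)
      d <- call_dmrs(w)
      if (nrow(d) == 0) next
      cand <- w[w$p_value < 0.1, ]
      inside <- vapply(seq_len(nrow(cand)), function(j) {
        any(d$chrom == cand$chrom[j] & d$start <= cand$start[j] &
              d$end >= cand$end[j])
      }, logical(1))
      near <- vapply(seq_len(nrow(cand)), function(j) {
        any(d$chrom == cand$chrom[j] &
              cand$start[j] <= d$end + 1000 &
              cand$end[j] >= d$start - 1000)
      }, logical(1))
      # every reachable candidate was absorbed
      expect_true(all(inside[near]))
      # and re-calling on the same input is idempotent
      expect_identical(call_dmrs(w)$start, d$start)
    }
  })
})

test_that("inputs must be sorted; empty input gives an empty set", {
  w <- flat_windows(10)
  expect_error(call_dmrs(w[c(2, 1, 3:10), ]), "sorted")
  d <- call_dmrs(w[0, ])
  expect_identical(nrow(d), 0L)
})

test_that("multiple-window status needs adjacent significant tiles", {
  w <- flat_windows(50)
  # single significant window
  w1 <- w; w1$p_value[10] <- 1e-8
  d1 <- call_dmrs(w1)
  expect_false(d1$is_multiple_window)
  expect_identical(d1$n_windows_significant, 1L)

  # two adjacent significant windows
  w2 <- w; w2$p_value[10:11] <- 1e-8
  d2 <- call_dmrs(w2)
  expect_true(d2$is_multiple_window)
  expect_identical(d2$n_windows_significant, 2L)

  # two significant windows separated by a non-significant one
  w3 <- w; w3$p_value[c(10, 12)] <- 1e-8; w3$p_value[11] <- 0.05
  d3 <- call_dmrs(w3)
  expect_false(d3$is_multiple_window)
  expect_identical(d3$n_windows_significant, 2L)
  # under the "any two" reading it qualifies
  d3b <- call_dmrs(w3, neighbor_rule = "any")
  expect_true(d3b$is_multiple_window)
  # standalone classifier agrees
  cl <- classify_multiple_window(d3, w3)
  expect_false(cl$is_multiple_window)
  expect_identical(cl$n_windows_significant, 2L)
})

test_that("direction comes from the most significant window", {
  w <- flat_windows(50)
  w$p_value[10] <- 1e-9; w$log2fc[10] <- -2
  w$p_value[11] <- 1e-7; w$log2fc[11] <- 3
  d <- call_dmrs(w)
  expect_identical(d$direction, "decrease")
  expect_identical(d$min_p, 1e-9)
  expect_identical(d$log2fc, -2)
})

test_that("threshold table counts are monotone in the cutoff", {
  withr::with_seed(14, {
    w <- random_window_instance(2000)
  })
  tab <- dmr_threshold_table(w, thresholds = 10^-(2:8))
  expect_identical(tab$threshold, 10^-(2:8))
  expect_true(all(diff(tab$n_dmrs_all) <= 0))
  expect_true(all(tab$n_dmrs_multiple_window <= tab$n_dmrs_all))
  # each row matches a direct call
  d6 <- call_dmrs(w, seed_p = 1e-6)
  expect_identical(tab$n_dmrs_all[tab$threshold == 1e-6], nrow(d6))
})

test_that("feature histograms partition the DMR set", {
  withr::with_seed(15, {
    w <- random_window_instance(1500)
  })
  w$cpg_count <- rpois(nrow(w), 1.5)
  d <- call_dmrs(w, seed_p = 1e-4)
  feats <- summarize_dmr_features(d)
  expect_identical(sum(feats$cpg_density$n_dmrs), nrow(d))
  expect_identical(sum(feats$length$n_dmrs), nrow(d))
  expect_identical(sum(feats$chromosome$n_dmrs), nrow(d))

  one <- d[1, ]
  f1 <- summarize_dmr_features(one)
  expect_identical(nrow(f1$cpg_density), 1L)
  expect_identical(sum(f1$length$n_dmrs), 1L)
})

test_that("clustering follows the start-gap and size rules", {
  mk <- function(starts) {
    tibble::tibble(dmr_id = paste0("d", seq_along(starts)),
                   chrom = "chr1", start = as.integer(starts),
                   end = as.integer(starts + 400L))
  }
  expect_identical(nrow(cluster_dmrs(mk(5e6))), 0L)
  cl <- cluster_dmrs(mk(c(0, 1e6, 1.9e6)))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_dmrs, 3L)
  expect_identical(nrow(cluster_dmrs(mk(c(0, 2.5e6, 3.0e6)))), 0L)
  # four in a chain with one break keeps only the large run
  cl2 <- cluster_dmrs(mk(c(0, 1e6, 2e6, 7e6, 7.5e6, 8.0e6, 8.5e6)))
  expect_identical(cl2$n_dmrs, c(3L, 4L))
})

test_that("dmr_set round-trips through its writers", {
  withr::with_seed(16, {
    w <- random_window_instance(500)
  })
  w$cpg_count <- rpois(nrow(w), 1.5)
  d <- call_dmrs(w, seed_p = 1e-4)
  dir <- withr::local_tempdir()
  write_dmr_tables(d, bed_path = file.path(dir, "d.bed"),
                   tsv_path = file.path(dir, "d.tsv"), seed = 1)
  bed <- readr::read_tsv(file.path(dir, "d.bed"), comment = "#",
                         col_names = FALSE, show_col_types = FALSE)
  expect_identical(nrow(bed), nrow(d))
  tsv <- readr::read_tsv(file.path(dir, "d.tsv"), comment = "#",
                         show_col_types = FALSE)
  expect_identical(nrow(tsv), nrow(d))
  expect_identical(as.integer(tsv$start), d$start)
})
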