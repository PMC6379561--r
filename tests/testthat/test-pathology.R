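make_records <- function(control_counts, exposed_counts = NULL,
                         category = "atrophy", observer = "obs1") {
  mk <- function(counts, lineage, prefix) {
    tibble::tibble(animal_id = sprintf("%s%02d", prefix,
                                       seq_along(counts)),
                   lineage = lineage, observer = observer,
                   !!category := counts)
  }
  out <- mk(control_counts, "control", "C")
  if (!is.null(exposed_counts)) {
    out <- dplyr::bind_rows(out, mk(exposed_counts, "exposed", "E"))
  }
  out
}

test_that("cutoffs are control mean plus two sample SDs", {
  rec <- make_records(c(1, 2, 3))
  expect_equal(compute_cutoffs(rec)$cutoff, 4)   # 2 + 2*1

  rec2 <- make_records(c(0, 0, 1, 1, 2))
  expect_equal(compute_cutoffs(rec2)$cutoff,
               0.8 + 2 * sd(c(0, 0, 1, 1, 2)), tolerance = 1e-12)
  expect_equal(compute_cutoffs(rec2)$cutoff, 2.4733, tolerance = 1e-4)

  rec0 <- make_records(c(0, 0, 0, 0))
  expect_equal(compute_cutoffs(rec0)$cutoff, 0)
})

test_that("cutoffs are computed per observer per category", {
  rec <- dplyr::bind_rows(
    make_records(c(1, 2, 3), observer = "obs1"),
    make_records(c(10, 20, 30), observer = "obs2"))
  co <- compute_cutoffs(rec)
  expect_identical(nrow(co), 2L)
  expect_equal(co$cutoff[co$observer == "obs1"], 4)
  expect_equal(co$cutoff[co$observer == "obs2"], 40)
  # pooled variant collapses observers
  cp <- compute_cutoffs(rec, per_observer = FALSE)
  expect_identical(length(unique(cp$cutoff)), 1L)
})

test_that("fewer than two control animals is an error", {
  expect_error(compute_cutoffs(make_records(c(1))), "two control")
})

test_that("consensus requires two of three observers", {
  # one animal per lineage; counts chosen against cutoff 4
  rec <- purrr::map_dfr(c("obs1", "obs2", "obs3"), function(o) {
    make_records(c(1, 2, 3), observer = o)
  })
  add_exposed <- function(counts_by_obs) {
    dplyr::bind_rows(rec, purrr::imap_dfr(counts_by_obs, function(v, o) {
      tibble::tibble(animal_id = "E01", lineage = "exposed",
                     observer = o, atrophy = v)
    }))
  }
  co <- compute_cutoffs(rec)

  ttf <- call_disease(add_exposed(c(obs1 = 9, obs2 = 9, obs3 = 0)), co)
  expect_true(ttf$consensus$diseased[ttf$consensus$animal_id == "E01"])

  tff <- call_disease(add_exposed(c(obs1 = 9, obs2 = 0, obs3 = 0)), co)
  expect_false(tff$consensus$diseased[tff$consensus$animal_id == "E01"])

  # a count exactly at the cutoff is not above it
  at_cut <- call_disease(add_exposed(c(obs1 = 4, obs2 = 4, obs3 = 4)),
                         co)
  expect_false(at_cut$consensus$diseased[
    at_cut$consensus$animal_id == "E01"])
})

test_that("consensus is monotone in observer calls", {
  rec <- purrr::map_dfr(c("obs1", "obs2", "obs3"), function(o) {
    make_records(c(1, 2, 3), c(9, 0, 0)[match(o, c("obs1", "obs2",
                                                   "obs3"))],
                 observer = o)
  })
  co <- compute_cutoffs(rec)
  one <- call_disease(rec, co)
  # upgrade obs2's score: call count can only move toward diseased
  rec2 <- rec
  rec2$atrophy[rec2$animal_id == "E01" & rec2$observer == "obs2"] <- 9
  two <- call_disease(rec2, co)
  expect_gte(two$consensus$n_observers_diseased[
    two$consensus$animal_id == "E01"],
    one$consensus$n_observers_diseased[
      one$consensus$animal_id == "E01"])
  expect_true(two$consensus$diseased[two$consensus$animal_id == "E01"])
})

test_that("an observer without cutoffs is an error", {
  rec <- make_records(c(1, 2, 3))
  co <- compute_cutoffs(rec)
  rec2 <- rec
  rec2$observer <- "obs9"
  expect_error(call_disease(rec2, co), "obs9")
})

test_that("Fisher exact matches enumeration, fisher.test and its symmetries", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 21, 22), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  tb <- matrix(c(7, 2, 3, 12), 2)
  expect_equal(fisher_exact_2x2(tb), fisher_exact_2x2(t(tb)))
  expect_equal(fisher_exact_2x2(tb),
               stats::fisher.test(tb)$p.value, tolerance = 1e-9)
  # zero margin convention
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1)

  withr::with_seed(31, {
    for (i in 1:200) {
      n_tot <- sample(4:60, 1)
      cells <- as.vector(stats::rmultinom(1, n_tot, runif(4, 0.05, 1)))
      tb <- matrix(cells, 2)
      expect_equal(fisher_exact_2x2(tb), oracle_fisher_2x2(tb),
                   tolerance = 1e-12)
      expect_equal(fisher_exact_2x2(tb),
                   stats::fisher.test(tb)$p.value, tolerance = 1e-7)
    }
  })
})

test_that("the mean+2SD rule keeps control disease frequency low", {
  freqs <- vapply(1:20, function(s) {
    cfg <- simulation_config(
      seed = 300 + s,
      pathology_config = pathology_config(affected_fraction = 0))
    ps <- simulate_pathology_scores(cfg)
    dc <- compare_lineages(ps$records)
    dc$frequencies$frequency[dc$frequencies$lineage == "control"]
  }, numeric(1))
  expect_lte(mean(freqs), 0.20)
})

test_that("compare_lineages builds a conserved 2x2 table", {
  ps <- simulate_pathology_scores(simulation_config(seed = 44))
  dc <- compare_lineages(ps$records)
  expect_identical(unname(colSums(dc$table_2x2)), c(26, 27))
  expect_identical(sum(dc$frequencies$n_animals), 53)
  expect_true(dc$fisher_p > 0 && dc$fisher_p <= 1)
  g <- glance(dc)
  expect_true(all(c("frequency_control", "frequency_exposed",
                    "fisher_p") %in% names(g)))
  # a lineage-free table errors
  only_ctrl <- dplyr::filter(ps$records, lineage == "control")
  expect_error(compare_lineages(only_ctrl), "lineage")
})
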