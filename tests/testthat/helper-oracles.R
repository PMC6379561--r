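# Independent oracles used to validate the package's own
# implementations. Each one is written as directly as possible from
# the defining rule, without sharing code with the functions it checks.

# Position-by-position CpG scan.
oracle_count_cpg <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < 2L) return(0L)
  n <- 0L
  for (i in seq_len(length(chars) - 1L)) {
    if (chars[i] == "C" && chars[i + 1L] == "G") n <- n + 1L
  }
  n
}

# Conditional two-sided exact binomial test: in the Poisson limit with
# equal effective depths, A | A + B = T is Binomial(T, n1/(n1+n2)).
# Two-sided by probability-mass ordering, ties included.
oracle_binom_exact_p <- function(a, b, n1, n2) {
  tt <- a + b
  if (tt == 0) return(1)
  pi1 <- n1 / (n1 + n2)
  probs <- dbinom(0:tt, tt, pi1)
  sum(probs[probs <= probs[a + 1L] * (1 + 1e-7)])
}

# Brute-force fixed point of the DMR absorption rule: start from seed
# windows, repeatedly grow each region by any sub-extend_p window
# within extend_dist of its span, merge overlapping regions, until
# nothing changes. Returns sorted (chrom, start, end).
oracle_call_dmrs <- function(wr, seed_p = 1e-6, extend_p = 0.1,
                             extend_dist = 1000) {
  regions <- wr[wr$p_value < seed_p, c("chrom", "start", "end")]
  if (nrow(regions) == 0L) return(regions)
  cand <- wr[wr$p_value < extend_p, c("chrom", "start", "end")]
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(regions))) {
      near <- cand$chrom == regions$chrom[i] &
        cand$start <= regions$end[i] + extend_dist &
        cand$end >= regions$start[i] - extend_dist
      if (any(near)) {
        ns <- min(regions$start[i], cand$start[near])
        ne <- max(regions$end[i], cand$end[near])
        if (ns != regions$start[i] || ne != regions$end[i]) {
          changed <- TRUE
        }
        regions$start[i] <- ns
        regions$end[i] <- ne
      }
    }
    regions <- regions[order(regions$chrom, regions$start), ,
                       drop = FALSE]
    i <- 1L
    while (i < nrow(regions)) {
      if (regions$chrom[i] == regions$chrom[i + 1L] &&
          regions$start[i + 1L] <= regions$end[i]) {
        regions$end[i] <- max(regions$end[i], regions$end[i + 1L])
        regions <- regions[-(i + 1L), , drop = FALSE]
        changed <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!changed) break
  }
  rownames(regions) <- NULL
  regions
}

# Quadratic interval-overlap flags: does each row of `a` overlap any
# row of `b` by >= 1 bp (half-open intervals)?
oracle_overlap_flags <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] &
          a$start[i] < b$end)
  }, logical(1))
}

# Quadratic gene-association pairs under gap <= max_dist.
oracle_associate <- function(dmrs, genes, max_dist) {
  pairs <- list()
  for (i in seq_len(nrow(dmrs))) {
    for (j in seq_len(nrow(genes))) {
      if (dmrs$chrom[i] != genes$chrom[j]) next
      gap <- max(dmrs$start[i], genes$start[j]) -
        min(dmrs$end[i], genes$end[j])
      if (gap <= max_dist) {
        pairs[[length(pairs) + 1L]] <-
          c(dmrs$dmr_id[i], genes$gene_id[j])
      }
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(dmr_id = character(), gene_id = character()))
  }
  out <- as.data.frame(do.call(rbind, pairs),
                       stringsAsFactors = FALSE)
  names(out) <- c("dmr_id", "gene_id")
  out[order(out$dmr_id, out$gene_id), ]
}

# Full hypergeometric enumeration of the 2x2 exact test via log
# binomial coefficients (independent of dhyper).
oracle_fisher_2x2 <- function(tb) {
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  if (m == 0 || n == 0 || k == 0 || sum(tb[, 2]) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) -
    lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- probs[match(tb[1, 1], support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Random window-result instance for DMR property tests: contiguous
# 100 bp tiles with a p-value mixture rich in sub-threshold windows.
random_window_instance <- function(n_windows, n_chrom = 1L) {
  per <- ceiling(n_windows / n_chrom)
  purrr::map_dfr(seq_len(n_chrom), function(c) {
    k <- min(per, n_windows - (c - 1L) * per)
    u <- runif(k)
    p <- ifelse(u < 0.70, runif(k),
                ifelse(u < 0.90, runif(k, 0, 0.1), 10^-runif(k, 0, 9)))
    tibble::tibble(chrom = paste0("chr", c),
                   start = (seq_len(k) - 1L) * 100L,
                   end = seq_len(k) * 100L,
                   p_value = pmax(p, 1e-300),
                   log2fc = rnorm(k))
  })
}

# Random interval set on a small genome.
random_intervals <- function(n, n_chrom = 2L, span = 100000L,
                             min_len = 50L, max_len = 3000L) {
  len <- as.integer(runif(n, min_len, max_len))
  st <- as.integer(runif(n, 0, span - max_len))
  tibble::tibble(chrom = paste0("chr", sample.int(n_chrom, n,
                                                  replace = TRUE)),
                 start = st, end = st + len)
}
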