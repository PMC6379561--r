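#' Simulate a two-lineage MeDIP-seq experiment with planted DMRs
#'
#' Tiles the genome, plants non-overlapping window-aligned differential
#' regions, and draws per-window fragment counts for
#' `n_samples_per_group` pooled samples per lineage from a negative
#' binomial model: control windows at mean
#' `mean_fragment_count_per_window` with dispersion `dispersion`
#' (variance mu + phi mu^2), and exposed windows inside planted regions
#' at mean multiplied or divided by `methylation_fold_change`. Planted
#' directions are split 50/50 between methylation increases and
#' decreases.
#'
#' @param config A [simulation_config()].
#' @param genome A `sim_genome` from [simulate_genome()]; its
#'   `chrom_sizes` define the tiling and, when sequence is present,
#'   windows are annotated with CpG counts.
#' @return A list of class `medip_sim`: `counts` (a `window_counts`
#'   object), `groups` (named sample->group vector), `truth` (tibble of
#'   planted regions: `chrom`, `start`, `end`, `direction`,
#'   `fold_change`), `mu` (expected-count matrix) and `config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 3, chrom_length_bp = 2e4,
#'                          n_planted_dmrs = 2, min_dmr_separation_bp = 2000)
#' sim <- simulate_medip_experiment(cfg, simulate_genome(cfg))
#' sim$truth
simulate_medip_experiment <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genome, "sim_genome"))
  windows <- tile_genome(genome$chrom_sizes, config$window_bp)
  if (!is.null(genome$seq)) {
    windows <- window_cpg_counts(windows, genome)
  }
  genome_bp <- sum(genome$chrom_sizes$size)
  if (config$n_planted_dmrs * max(config$dmr_width_bp) >= genome_bp / 10) {
    abort("Planted regions would cover >= 10% of the genome; reduce
           `n_planted_dmrs` or widths.")
  }

  with_stage_seed(config$seed, 1L, {
    truth <- plant_dmr_intervals(config, genome$chrom_sizes)
    n <- config$n_samples_per_group
    samples <- c(paste0("control_", seq_len(n)),
                 paste0("exposure_", seq_len(n)))
    groups <- setNames(rep(c("control", "exposure"), each = n), samples)

    mu <- matrix(config$mean_fragment_count_per_window,
                 nrow = nrow(windows), ncol = 2L * n,
                 dimnames = list(NULL, samples))
    if (nrow(truth) > 0L) {
      for (i in seq_len(nrow(truth))) {
        in_region <- windows$chrom == truth$chrom[i] &
          windows$start >= truth$start[i] & windows$end <= truth$end[i]
        eff <- if (truth$direction[i] == "increase") {
          truth$fold_change[i]
        } else {
          1 / truth$fold_change[i]
        }
        mu[in_region, groups == "exposure"] <-
          mu[in_region, groups == "exposure"] * eff
      }
    }
    counts <- draw_nb_counts(mu, config$dispersion)
    structure(list(
      counts = new_window_counts(windows, counts, samples),
      groups = groups,
      truth = truth,
      mu = mu,
      config = config
    ), class = "medip_sim")
  })
}

draw_nb_counts <- function(mu, phi) {
  counts <- if (phi == 0) {
    rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / phi)
  }
  counts <- matrix(as.integer(counts), nrow = nrow(mu),
                   dimnames = dimnames(mu))
  counts
}

# Window-aligned, non-overlapping planted intervals with a minimum
# separation, placed by rejection sampling.
plant_dmr_intervals <- function(config, chrom_sizes) {
  n <- config$n_planted_dmrs
  empty <- tibble(chrom = character(), start = integer(),
                  end = integer(), direction = character(),
                  fold_change = numeric())
  # fold change 1 means no effect: the truth table carries no regions
  if (n == 0L || config$methylation_fold_change == 1) return(empty)
  w <- config$window_bp
  widths <- seq.int(ceiling(config$dmr_width_bp[1] / w) * w,
                    (config$dmr_width_bp[2] %/% w) * w, by = w)
  if (length(widths) == 0L) {
    widths <- ceiling(config$dmr_width_bp[1] / w) * w
  }
  # Separation-respecting placement by the spacing construction: draw
  # sorted uniforms on the slack left after widths and separations are
  # reserved, then lay regions down left to right. Starts snap down to
  # the window grid, so one extra window of separation is reserved to
  # keep the realized gaps >= min_dmr_separation_bp.
  chrom_i <- sort(sample.int(nrow(chrom_sizes), n, replace = TRUE,
                             prob = chrom_sizes$size))
  wd <- sample(widths, n, replace = TRUE)
  sep <- config$min_dmr_separation_bp + w
  out <- purrr::map_dfr(unique(chrom_i), function(ci) {
    ii <- which(chrom_i == ci)
    k <- length(ii)
    size <- chrom_sizes$size[ci]
    wk <- wd[ii]
    slack <- size - sum(wk) - (k - 1L) * sep
    if (slack < 0) {
      abort("Could not place non-overlapping planted regions; genome too
             small for `n_planted_dmrs` at the requested separation.")
    }
    u <- sort(runif(k, 0, slack))
    st <- (floor((u + cumsum(c(0, wk[-k] + sep))) / w)) * w
    tibble(chrom = chrom_sizes$chrom[ci], start = as.integer(st),
           end = as.integer(st + wk))
  })
  direction <- sample(rep(c("increase", "decrease"), length.out = n))
  out |>
    arrange(.data$chrom, .data$start) |>
    mutate(direction = direction,
           fold_change = config$methylation_fold_change)
}

#' Materialize window counts as BED fragments
#'
#' Each window's count becomes that many fragments of
#' `fragment_length_bp` (default 300 bp, the sonication target size)
#' centered on the window midpoint. Near chromosome ends fragments are
#' shrunk symmetrically about the midpoint, so every fragment's midpoint
#' stays in its source window and [count_fragments()] recovers the
#' simulated counts exactly.
#'
#' @param sim A `medip_sim` object.
#' @return Tibble with columns `chrom`, `start`, `end`, `sample`.
#' @export
fragments_from_counts <- function(sim) {
  stopifnot(inherits(sim, "medip_sim"))
  wc <- sim$counts
  sizes <- tapply(wc$windows$end, wc$windows$chrom, max)
  size_of <- setNames(as.integer(sizes), names(sizes))
  half_target <- sim$config$fragment_length_bp %/% 2L
  purrr::map_dfr(wc$samples, function(s) {
    cnt <- wc$counts[, s]
    keep <- cnt > 0L
    if (!any(keep)) {
      return(tibble(chrom = character(), start = integer(),
                    end = integer(), sample = character()))
    }
    w <- wc$windows[keep, , drop = FALSE]
    mid <- (w$start + w$end) %/% 2L
    size <- size_of[w$chrom]
    half <- pmin(half_target, mid, size - mid)
    half <- pmax(half, 0L)
    st <- mid - half
    en <- ifelse(half > 0L, mid + half, mid + 1L)
    idx <- rep(seq_len(nrow(w)), cnt[keep])
    tibble(chrom = w$chrom[idx], start = as.integer(st[idx]),
           end = as.integer(en[idx]), sample = s)
  })
}

#' Write per-sample fragment BED files
#'
#' BED3+name, 0-based half-open, with a provenance comment header.
#'
#' @param sim A `medip_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_fragments_bed <- function(sim, dir) {
  stopifnot(inherits(sim, "medip_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frags <- fragments_from_counts(sim)
  paths <- setNames(file.path(dir, paste0(sim$counts$samples, ".bed")),
                    sim$counts$samples)
  for (s in sim$counts$samples) {
    fr <- frags[frags$sample == s, , drop = FALSE]
    writeLines(provenance_header(sim$config$seed), paths[[s]])
    if (nrow(fr) > 0L) {
      readr::write_tsv(
        tibble(fr$chrom, fr$start, fr$end,
               paste0(s, "_frag", seq_len(nrow(fr)))),
        paths[[s]], append = TRUE, col_names = FALSE)
    }
  }
  invisible(paths)
}
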