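#' Simulate a CpG-sparse genome
#'
#' Generates chromosome sequences whose CpG dinucleotides are placed by
#' an explicit local-density process: filler sequence containing no CG
#' at all, then CpGs planted at positions drawn blockwise (1 kb blocks)
#' at either the background density or, for a small fraction of blocks,
#' an elevated patch density. The realized genome-wide CpG density
#' therefore matches `cpg_rate_background` up to Poisson noise, and most
#' 100 bp windows carry 1-2 CpGs — the CpG-desert background in which
#' transgenerational differentially methylated regions are typically
#' found.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_genome` with elements `seq` (named
#'   character vector of chromosome sequences), `chrom_sizes` (tibble
#'   with columns `chrom`, `size`) and `config`.
#' @export
#' @examples
#' g <- simulate_genome(simulation_config(seed = 7, chrom_length_bp = 1e4))
#' g$chrom_sizes
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$chrom_length_bp <= 0) abort("Chromosome length must be positive.")
  seqs <- with_stage_seed(config$seed, 0L, {
    vapply(seq_len(config$n_chromosomes), function(i) {
      simulate_chromosome_seq(
        len = config$chrom_length_bp,
        cpg_rate = config$cpg_rate_background,
        patch_fraction = config$cpg_patch_fraction,
        patch_multiplier = config$cpg_patch_multiplier
      )
    }, character(1))
  })
  names(seqs) <- paste0("chr", seq_len(config$n_chromosomes))
  structure(list(
    seq = seqs,
    chrom_sizes = tibble(chrom = names(seqs),
                         size = rep(config$chrom_length_bp,
                                    config$n_chromosomes)),
    config = config
  ), class = "sim_genome")
}

# One chromosome: CG-free filler plus planted CpGs.
simulate_chromosome_seq <- function(len, cpg_rate, patch_fraction,
                                    patch_multiplier) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, len, replace = TRUE)
  # Remove accidental CG by rewriting the G of each CG as A or T; the
  # replacement can never create a new CG, so one pass suffices.
  if (len >= 2L) {
    cg <- which(s[-len] == "C" & s[-1L] == "G")
    if (length(cg) > 0L) {
      s[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
    }
  }
  if (cpg_rate > 0 && len >= 2L) {
    block <- 1000L
    starts <- seq.int(1L, len, by = block)
    blens <- pmin(block, len - starts + 1L)
    mult_patch <- patch_multiplier
    mult_bg <- (1 - patch_fraction * mult_patch) / (1 - patch_fraction)
    is_patch <- runif(length(starts)) < patch_fraction
    mult <- ifelse(is_patch, mult_patch, mult_bg)
    n_cpg <- rpois(length(starts), cpg_rate * mult * blens / 100)
    pos <- unlist(lapply(seq_along(starts), function(b) {
      avail <- blens[b] - 1L   # C position must leave room for the G
      if (avail < 1L || n_cpg[b] == 0L) return(integer(0))
      p <- sort(sample.int(avail, min(n_cpg[b], avail)))
      # enforce spacing >= 2 within the block (drop the later of a pair)
      if (length(p) > 1L) p <- p[c(TRUE, diff(p) >= 2L)]
      starts[b] + p - 1L
    }))
    if (length(pos) > 0L) {
      s[pos] <- "C"
      s[pos + 1L] <- "G"
    }
  }
  paste(s, collapse = "")
}

#' Write simulated genome as FASTA
#'
#' @param genome A `sim_genome` object.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "sim_genome"))
  dna <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Read a genome FASTA into the package's genome container
#'
#' @param path FASTA path.
#' @return A list of class `sim_genome` (config slot `NULL`).
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dna)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(
    seq = seqs,
    chrom_sizes = tibble(chrom = names(seqs),
                         size = unname(Biostrings::width(dna))),
    config = NULL
  ), class = "sim_genome")
}
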