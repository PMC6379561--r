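#' Configuration for the synthetic MeDIP-seq study
#'
#' Bundles every tunable of the synthetic-data generator into one
#' validated list. The defaults reproduce the standard study design the
#' package is validated against: one 5 Mb CpG-sparse chromosome tiled
#' into 100 bp windows, three pooled samples per lineage, negative
#' binomial window counts (mean 50 fragments per window, dispersion 0.1),
#' and 100 planted differentially methylated regions of 300-500 bp with
#' an 8-fold methylation effect split evenly between increases and
#' decreases.
#'
#' @param seed Integer seed; all generator stages derive their RNG state
#'   from it, so a fixed config gives byte-identical outputs.
#' @param n_chromosomes Number of chromosomes to simulate.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param cpg_rate_background Mean CpG density, CpG dinucleotides per
#'   100 bp, of the local-density process (the genome-wide average; a
#'   small fraction of 1 kb blocks is denser, emulating CpG islands in an
#'   otherwise CpG-desert genome).
#' @param cpg_patch_fraction Fraction of 1 kb blocks drawn at the
#'   elevated patch density.
#' @param cpg_patch_multiplier Density multiplier inside patches; the
#'   non-patch density is rescaled so the genome-wide mean stays at
#'   `cpg_rate_background`.
#' @param window_bp Tiling window width in bp (default 100).
#' @param n_samples_per_group Pooled samples per lineage (default 3).
#' @param mean_fragment_count_per_window Baseline expected MeDIP fragment
#'   count per window per sample.
#' @param dispersion Negative binomial dispersion phi >= 0 of window
#'   counts (variance mu + phi * mu^2; 0 degenerates to Poisson).
#' @param n_planted_dmrs Number of planted differential regions.
#' @param dmr_width_bp Two-element range (bp) from which planted widths
#'   are drawn in whole windows.
#' @param methylation_fold_change Multiplicative effect on the exposed
#'   window mean inside planted regions (applied as x fold for increases
#'   and / fold for decreases; direction split 50/50).
#' @param min_dmr_separation_bp Minimum gap enforced between planted
#'   regions so that called regions cannot bridge two distinct truths.
#' @param fragment_length_bp Length of emitted BED fragments (default
#'   300, the sonication target size).
#' @param de_config Transcript-simulation settings from [de_config()].
#' @param pathology_config Pathology-simulation settings from
#'   [pathology_config()].
#'
#' @return A list of class `simulation_config`.
#' @seealso [simulate_genome()], [simulate_medip_experiment()],
#'   [simulate_transcript_counts()], [simulate_pathology_scores()]
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7, chrom_length_bp = 1e5,
#'                          n_planted_dmrs = 4)
#' cfg$window_bp
simulation_config <- function(seed = 1L,
                              n_chromosomes = 1L,
                              chrom_length_bp = 5e6,
                              cpg_rate_background = 1.5,
                              cpg_patch_fraction = 0.02,
                              cpg_patch_multiplier = 4,
                              window_bp = 100L,
                              n_samples_per_group = 3L,
                              mean_fragment_count_per_window = 50,
                              dispersion = 0.1,
                              n_planted_dmrs = 100L,
                              dmr_width_bp = c(300L, 500L),
                              methylation_fold_change = 8,
                              min_dmr_separation_bp = 5000L,
                              fragment_length_bp = 300L,
                              de_config = dmrkit::de_config(),
                              pathology_config = dmrkit::pathology_config()) {
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(n_chromosomes, "n_chromosomes", lower = 1, integer = TRUE)
  check_scalar(chrom_length_bp, "chrom_length_bp", lower = 1,
               integer = TRUE)
  check_scalar(cpg_rate_background, "cpg_rate_background", lower = 0)
  check_scalar(cpg_patch_fraction, "cpg_patch_fraction", lower = 0,
               upper = 1)
  check_scalar(cpg_patch_multiplier, "cpg_patch_multiplier", lower = 1)
  check_scalar(window_bp, "window_bp", lower = 1, integer = TRUE)
  check_scalar(n_samples_per_group, "n_samples_per_group", lower = 1,
               integer = TRUE)
  check_scalar(mean_fragment_count_per_window,
               "mean_fragment_count_per_window", lower = 0)
  check_scalar(dispersion, "dispersion", lower = 0)
  check_scalar(n_planted_dmrs, "n_planted_dmrs", lower = 0,
               integer = TRUE)
  if (length(dmr_width_bp) != 2L || any(dmr_width_bp < window_bp)) {
    abort("`dmr_width_bp` must be a (min, max) range of at least one window.")
  }
  check_scalar(methylation_fold_change, "methylation_fold_change",
               lower = 1)
  check_scalar(fragment_length_bp, "fragment_length_bp", lower = 1,
               integer = TRUE)
  if (cpg_patch_fraction * cpg_patch_multiplier >= 1) {
    abort("cpg_patch_fraction * cpg_patch_multiplier must be < 1 so the
           non-patch density stays positive.")
  }

  structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    cpg_rate_background = cpg_rate_background,
    cpg_patch_fraction = cpg_patch_fraction,
    cpg_patch_multiplier = cpg_patch_multiplier,
    window_bp = as.integer(window_bp),
    n_samples_per_group = as.integer(n_samples_per_group),
    mean_fragment_count_per_window = mean_fragment_count_per_window,
    dispersion = dispersion,
    n_planted_dmrs = as.integer(n_planted_dmrs),
    dmr_width_bp = as.integer(sort(dmr_width_bp)),
    methylation_fold_change = methylation_fold_change,
    min_dmr_separation_bp = as.integer(min_dmr_separation_bp),
    fragment_length_bp = as.integer(fragment_length_bp),
    de_config = de_config,
    pathology_config = pathology_config
  ), class = "simulation_config")
}

#' Transcript-count simulation settings
#'
#' Defaults give 3,000 transcripts across the three RNA classes (2,000
#' mRNA, 500 lncRNA, 500 sncRNA), 5% of them carrying an 8-fold
#' expression effect, with negative binomial counts at mean 100 and
#' dispersion 0.1 for three pooled samples per lineage. Small noncoding
#' RNAs are subclassed into miRNA, piRNA, tRNA and other; a configurable
#' fraction of sncRNAs has no genomic location (as is common for small
#' RNA annotation).
#'
#' @param n_transcripts Named integer vector of transcripts per class
#'   (names among mRNA, lncRNA, sncRNA).
#' @param de_fraction Fraction of transcripts per class carrying a
#'   planted group effect.
#' @param de_fold_change Multiplicative effect for planted transcripts
#'   (direction split 50/50).
#' @param mean_count Baseline expected count per transcript per sample.
#' @param dispersion Negative binomial dispersion phi >= 0.
#' @param sncrna_subclass_prop Named probabilities over sncRNA
#'   subclasses (miRNA, piRNA, tRNA, other).
#' @param unknown_location_fraction Fraction of sncRNAs left without a
#'   genomic interval.
#' @return A list of class `de_config`.
#' @export
de_config <- function(n_transcripts = c(mRNA = 2000L, lncRNA = 500L,
                                        sncRNA = 500L),
                      de_fraction = 0.05,
                      de_fold_change = 8,
                      mean_count = 100,
                      dispersion = 0.1,
                      sncrna_subclass_prop = c(miRNA = 0.4, piRNA = 0.3,
                                               tRNA = 0.2, other = 0.1),
                      unknown_location_fraction = 0.2) {
  classes <- c("mRNA", "lncRNA", "sncRNA")
  if (length(n_transcripts) == 0L ||
      !all(names(n_transcripts) %in% classes)) {
    abort("`n_transcripts` must be named with classes among mRNA, lncRNA, sncRNA.")
  }
  check_scalar(de_fraction, "de_fraction", lower = 0, upper = 1)
  check_scalar(de_fold_change, "de_fold_change", lower = 1)
  check_scalar(mean_count, "mean_count", lower = 0)
  check_scalar(dispersion, "dispersion", lower = 0)
  subclasses <- c("miRNA", "piRNA", "tRNA", "other")
  if (!setequal(names(sncrna_subclass_prop), subclasses)) {
    abort("`sncrna_subclass_prop` must name miRNA, piRNA, tRNA, other.")
  }
  check_scalar(unknown_location_fraction, "unknown_location_fraction",
               lower = 0, upper = 1)
  structure(list(
    n_transcripts = vapply(n_transcripts, as.integer, integer(1)),
    de_fraction = de_fraction,
    de_fold_change = de_fold_change,
    mean_count = mean_count,
    dispersion = dispersion,
    sncrna_subclass_prop = sncrna_subclass_prop / sum(sncrna_subclass_prop),
    unknown_location_fraction = unknown_location_fraction
  ), class = "de_config")
}

#' Pathology simulation settings
#'
#' Defaults emulate the standard design: 26 control and 27 exposed
#' animals, three blinded observers, Poisson(0.5) baseline abnormality
#' counts per category, and 40% of exposed animals carrying an excess
#' rate of +2.0 abnormalities in at least one category.
#'
#' @param n_control,n_exposed Animals per lineage.
#' @param n_observers Number of independent observers (default 3).
#' @param categories Histopathology category names.
#' @param baseline_rate Poisson baseline abnormality rate per category.
#' @param excess_rate Additional rate in affected categories of affected
#'   exposed animals.
#' @param affected_fraction Fraction of exposed animals affected.
#' @return A list of class `pathology_config`.
#' @export
pathology_config <- function(n_control = 26L,
                             n_exposed = 27L,
                             n_observers = 3L,
                             categories = c("atrophy", "hyperplasia",
                                            "vacuoles"),
                             baseline_rate = 0.5,
                             excess_rate = 2.0,
                             affected_fraction = 0.4) {
  check_scalar(n_control, "n_control", lower = 1, integer = TRUE)
  check_scalar(n_exposed, "n_exposed", lower = 1, integer = TRUE)
  check_scalar(n_observers, "n_observers", lower = 1, integer = TRUE)
  check_scalar(baseline_rate, "baseline_rate", lower = 0)
  check_scalar(excess_rate, "excess_rate", lower = 0)
  check_scalar(affected_fraction, "affected_fraction", lower = 0,
               upper = 1)
  if (length(categories) < 1L) abort("Need at least one category.")
  structure(list(
    n_control = as.integer(n_control),
    n_exposed = as.integer(n_exposed),
    n_observers = as.integer(n_observers),
    categories = as.character(categories),
    baseline_rate = baseline_rate,
    excess_rate = excess_rate,
    affected_fraction = affected_fraction
  ), class = "pathology_config")
}
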