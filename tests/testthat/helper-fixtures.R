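# Small shared fixtures, generated in code.

tiny_sim_config <- function(seed = 11, ...) {
  simulation_config(seed = seed, chrom_length_bp = 3e5,
                    n_planted_dmrs = 6, min_dmr_separation_bp = 5000,
                    ...)
}

tiny_medip <- function(seed = 11) {
  cfg <- tiny_sim_config(seed)
  genome <- simulate_genome(cfg)
  list(config = cfg, genome = genome,
       sim = simulate_medip_experiment(cfg, genome))
}

# Equal-depth normalization result (factors 1), for oracle comparisons
# that require equal effective library sizes.
unit_norm <- function(samples, lib = 1e6) {
  tibble::tibble(sample = samples, library_size = lib,
                 scale_factor = 1, effective_size = lib)
}

two_group_labels <- function(n1 = 3, n2 = 3) {
  s <- c(paste0("control_", seq_len(n1)),
         paste0("exposure_", seq_len(n2)))
  setNames(rep(c("control", "exposure"), c(n1, n2)), s)
}
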