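# Small, fast simulation configs shared across test files.

empty_cgi <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chromosomes = 2, chromosome_length = 4e5,
             n_genes = 40, n_probes = 2000, ...)
}

small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chromosomes = 2, chromosome_length = 8e5,
             n_genes = 120, n_probes = 6000, ...)
}

run_small_analysis <- function(sim, q = 0.05) {
  dm <- call_dmcpg(sim$methylation$betas, sim$methylation$samples, q)
  catalog <- build_region_catalog(sim$genome$genes, sim$genome$cgis,
                                  sim$genome$skew_regions,
                                  sim$genome$chrom_lengths)
  assignment <- assign_probe_categories(sim$genome$manifest, catalog)
  list(dm = dm, catalog = catalog, assignment = assignment)
}
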