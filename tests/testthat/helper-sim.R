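# Shared small simulations, built once per test run.
the_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(the_cache[[key]])) the_cache[[key]] <- force(expr)
  the_cache[[key]]
}

small_genome <- function() {
  cached("small_genome", generate_genome(
    sim_config(rng_seed = 101, n_hairpins = 6, genome_length = 25000,
               n_decoys = 6)))
}

small_tissue_sim <- function() {
  cached("small_tissue", generate_tissue_expression(
    sim_config(rng_seed = 202, n_tissues = 14,
               planted_target_correlation = -0.9)))
}
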