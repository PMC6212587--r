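# shared fixtures: short simulation configs and small genes keep the suite
# fast while leaving enough precision for the statistical assertions

fast_cfg <- function(seed = 1L, replicates = 4L, terms = 500L, ...) {
  sim_config(seed = seed, replicates = replicates,
             measure_terminations = terms, ...)
}

uniform_gene <- function(n = 100L, lambda0 = 0.1, rate = 1, s = 9L) {
  make_uniform_gene(n = n, rate = rate, lambda0 = lambda0, s = s)
}

# deterministic toy cohort with sequences for bookkeeping tests
toy_cohort <- function(n_genes = 20L, seed = 123L, len_meanlog = log(120),
                       len_sdlog = 0.2) {
  spec <- cohort_spec(n_genes = n_genes, seed = seed,
                      length_meanlog = len_meanlog, length_sdlog = len_sdlog)
  sample_cohort(spec)
}
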