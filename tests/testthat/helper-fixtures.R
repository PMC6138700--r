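# Shared fixtures, generated in code at fixed seeds (no data files).

tiny_genome <- function(seq = "ACGTACGTACGTACGT", name = "chr1", mask = NULL) {
  genome_seq(stats::setNames(seq, name), mask = mask)
}

random_seq <- function(n, seed, prob = c(0.3, 0.2, 0.2, 0.3)) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = ""))
}

# cohort fixture reused by several files: 200 kb genome, truth, singletons
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- gen_genome(2e5, gc_fraction = 0.4, n_contigs = 1, seed = 101)
      truth <- make_ground_truth(seed = 102)
      v <- gen_singletons(g, truth, n_samples = 60, seed = 103)
      cache <<- list(genome = g, truth = truth, variants = v)
    }
    cache
  }
})
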