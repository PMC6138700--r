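test_that("generated genomes hit the requested GC fraction and are reproducible", {
  g <- gen_genome(2e5, gc_fraction = 0.5, n_contigs = 1, seed = 151)
  bases <- table(strsplit(g$seq[["chr1"]], "")[[1]])
  gc <- (bases[["G"]] + bases[["C"]]) / sum(bases)
  se <- sqrt(0.25 / 2e5)
  expect_lt(abs(gc - 0.5), 3 * se)

  g2 <- gen_genome(5000, n_contigs = 2, seed = 152)
  expect_length(g2$seq, 2L)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(gen_genome(5000, seed = 153), f1)
  write_genome(gen_genome(5000, seed = 153), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(gen_genome(1000, gc_fraction = 1.2, seed = 1), "gc_fraction")

  # FASTA + mask round trip
  gm <- gen_genome(20000, seed = 154, mask_coverage = 0.3)
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_genome(gm, fa, mask_path = bed)
  back <- read_genome(fa, mask_bed = bed)
  expect_identical(back$seq, gm$seq)
  expect_equal(back$mask$start, gm$mask$start)
  expect_equal(back$mask$end, gm$mask$end)
})

test_that("feature tracks realize requested coverage and constant specs", {
  g <- gen_genome(5e5, seed = 155)
  spec <- data.frame(name = c("b1", "b0", "flat"),
                     kind = c("binary", "binary", "continuous"),
                     coverage = c(0.2, 0, NA),
                     mean = c(NA, NA, 3), sd = c(NA, NA, 0))
  tracks <- gen_feature_tracks(g, spec, seed = 156)
  cov <- sum(tracks$b1$intervals$end - tracks$b1$intervals$start) / 5e5
  expect_lt(abs(cov - 0.2), 0.02)
  expect_equal(nrow(tracks$b0$intervals), 0L)
  expect_true(all(abs(tracks$flat$intervals$value - 3) < 1e-12))
  expect_true("DP" %in% names(tracks))

  # BED round trip
  bed <- withr::local_tempfile(fileext = ".bed")
  write_feature_track(tracks$b1, bed)
  back <- read_feature_track(bed, name = "b1", kind = "binary")
  expect_equal(back$intervals$start, tracks$b1$intervals$start)
  expect_equal(back$intervals$end, tracks$b1$intervals$end)
})

test_that("singleton generation follows the per-subtype generative rates", {
  fx <- fixture_cohort()
  v <- fx$variants
  expected <- attr(v, "expected_counts")
  rt <- estimate_rates(v, fx$genome, 7)
  obs <- stats::setNames(rt$erv_count, rt$subtype)[names(expected)]
  # realized counts within exact Poisson-binomial (approximated by
  # Poisson) 99% CIs for at least 99% of subtypes with real expectation
  test_keys <- names(expected)[expected > 0.5]
  covered <- vapply(test_keys, function(k) {
    # realized count inside the central 99% of its (Poisson-approximated)
    # sampling distribution
    obs[[k]] >= stats::qpois(0.005, expected[[k]]) &&
      obs[[k]] <= stats::qpois(0.995, expected[[k]])
  }, logical(1))
  expect_gte(mean(covered), 0.98)

  # near-zero rates produce an empty set
  g <- gen_genome(20000, seed = 157)
  t0 <- make_ground_truth(seed = 158, rate_scale = 1e-9)
  v0 <- gen_singletons(g, t0, n_samples = 3, seed = 159)
  expect_equal(nrow(v0), 0L)

  # absurdly high rates are rejected
  thigh <- make_ground_truth(seed = 160, rate_scale = 1e6)
  expect_error(gen_singletons(g, thigh, n_samples = 3, seed = 161),
               "too high")
})

test_that("a known feature effect shows up as the expected rate ratio", {
  g <- gen_genome(3e5, seed = 163)
  tracks <- gen_feature_tracks(
    g, data.frame(name = "feat", kind = "binary", coverage = 0.5,
                  mean = NA, sd = NA), seed = 164)
  truth <- make_ground_truth(
    seed = 165,
    feature_effects = data.frame(feature = "feat", type = "A>G",
                                 beta = log(2)))
  v <- gen_singletons(g, truth, n_samples = 20, seed = 166,
                      tracks = tracks)
  ag <- v[paste0(ifelse(v$ref %in% c("A", "C"), v$ref,
                        oracle_complement[v$ref]), ">",
                 ifelse(v$ref %in% c("A", "C"), v$alt,
                        oracle_complement[v$alt])) == "A>G", ]
  inside <- annotate_features(ag, tracks["feat"], genome = g)$feat == 1
  # genome-wide A/T site split inside/outside the track
  all_pos <- which(strsplit(g$seq[["chr1"]], "")[[1]] %in% c("A", "T"))
  at_sites <- data.frame(chrom = "chr1", pos = all_pos)
  at_inside <- annotate_features(at_sites, tracks["feat"],
                                 genome = g)$feat == 1
  rate_in <- sum(inside) / sum(at_inside)
  rate_out <- sum(!inside) / sum(!at_inside)
  ratio <- rate_in / rate_out
  se_log <- sqrt(1 / sum(inside) + 1 / sum(!inside))
  expect_lt(abs(log(ratio) - log(2)), 3 * se_log)
})

test_that("de novo draws match the truth spectrum and avoid excluded sites", {
  fx <- fixture_cohort()
  g <- fx$genome; truth <- fx$truth
  expect_equal(nrow(gen_denovo(g, truth, 0, seed = 1)), 0L)

  dn <- gen_denovo(g, truth, 5000, seed = 167, exclude = fx$variants)
  expect_equal(nrow(dn), 5000L)
  expect_false(any(paste(dn$chrom, dn$pos) %in%
                     paste(fx$variants$chrom, fx$variants$pos)))

  # chi-squared goodness of fit of the drawn basic-type spectrum against
  # the truth-implied expectation; drawn without exclusions, since
  # excluding singleton positions preferentially removes high-rate sites
  # and shifts the conditional spectrum
  dn <- gen_denovo(g, truth, 5000, seed = 167)
  rt <- truth_rate_table(truth, g)
  drawn <- canonical_subtype(dn$ref, dn$alt,
                             contexts_at(g, dn$chrom, dn$pos, 7))
  obs <- table(factor(drawn$type, levels = sort(unique(rt$type))))
  exp_w <- tapply(rt$erv_count, rt$type, sum)
  exp_p <- exp_w[names(obs)] / sum(exp_w)
  gof <- stats::chisq.test(obs, p = exp_p)
  expect_gt(gof$p.value, 0.01)

  # uniform perturbation makes the uniform covariate the best strategy
  dn_u <- gen_denovo(g, truth, 3000, seed = 168, perturbation = "uniform")
  bg <- partition_background(
    sample_background(g, 30000, exclude = dn_u, seed = 169), seed = 170)
  t7 <- truth_rate_table(truth, g)
  enum <- enumerate_subtypes(7)
  uniform <- rate_table(
    stats::setNames(t7$motif_count * 0.01, enum$subtype),
    stats::setNames(t7$motif_count[!duplicated(t7$motif)],
                    t7$motif[!duplicated(t7$motif)]), K = 7)
  res <- validate_strategies(dn_u, bg, list(truth7 = t7, uniform = uniform),
                             g)
  # the uniform covariate is at worst within chance fluctuation of the
  # best model, and the truth-rate covariate carries no real signal here
  cmp <- res$comparison
  expect_lt(cmp$delta_aic[cmp$label == "uniform"], 10)
  expect_lt(cmp$r2_nagelkerke[cmp$label == "truth7"], 0.002)
})

test_that("spiked outliers have aberrant spectra and are recovered by the QC", {
  g <- gen_genome(1.5e5, seed = 171)
  truth <- make_ground_truth(seed = 172, rate_scale = 2)
  v <- gen_singletons(g, truth, n_samples = 200, seed = 173)

  expect_identical(spike_outliers(v, g, 0, seed = 1)$variants, v)

  sp <- spike_outliers(v, g, 10, seed = 174)
  expect_length(sp$outliers, 10L)
  spectra <- per_sample_spectra(sp$variants, g)
  centroid <- colMeans(spectra[!rownames(spectra) %in% sp$outliers, ])
  for (sid in sp$outliers)
    expect_lt(cosine_sim(spectra[sid, ], centroid), 0.9)
})
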