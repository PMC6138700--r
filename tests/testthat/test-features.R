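test_that("binary annotation respects half-open interval boundaries", {
  g <- tiny_genome(random_seq(2000, seed = 111))
  # BED interval [100, 200): 1-based positions 101..200 inclusive
  tr <- feature_track("cgi", "binary",
                      data.frame(chrom = "chr1", start = 100L, end = 200L))
  sites <- data.frame(chrom = "chr1", pos = c(100L, 101L, 200L, 201L))
  ann <- annotate_features(sites, list(tr), genome = g)
  expect_equal(ann$cgi, c(0, 1, 1, 0))
})

test_that("continuous annotation is a window mean, truncated at contig edges", {
  g <- tiny_genome(random_seq(50000, seed = 113))
  # constant track: window mean equals the constant everywhere
  const <- feature_track("flat", "continuous",
                         data.frame(chrom = "chr1", start = 0L, end = 50000L,
                                    value = 2.5))
  sites <- data.frame(chrom = "chr1", pos = c(1L, 17L, 25000L, 50000L))
  ann <- annotate_features(sites, list(const), genome = g)
  expect_equal(ann$flat, rep(2.5, 4))

  # sawtooth in 100-bp bins vs brute-force averaging at random sites
  brk <- seq(0L, 50000L, by = 100L)
  saw <- feature_track("saw", "continuous",
                       data.frame(chrom = "chr1", start = brk[-length(brk)],
                                  end = brk[-1],
                                  value = rep_len(c(1, 3, 7, 2, 9), 500)))
  per_base <- rep(rep_len(c(1, 3, 7, 2, 9), 500), each = 100)
  withr::with_seed(117, pos <- sample(1:50000, 100))
  ann2 <- annotate_features(data.frame(chrom = "chr1", pos = pos),
                            list(saw), genome = g, window_bp = 10000)
  brute <- vapply(pos, function(p)
    mean(per_base[max(1, p - 5000):min(50000, p + 5000)]), numeric(1))
  expect_equal(ann2$saw, brute)

  # track with no data in the window yields NA
  gap <- feature_track("gap", "continuous",
                       data.frame(chrom = "chr1", start = 0L, end = 100L,
                                  value = 1))
  ann3 <- annotate_features(data.frame(chrom = "chr1", pos = 40000L),
                            list(gap), genome = g, window_bp = 1000)
  expect_true(is.na(ann3$gap))

  # depth is the value at the central site
  dp <- feature_track("DP", "continuous",
                      data.frame(chrom = "chr1", start = c(0L, 25000L),
                                 end = c(25000L, 50000L), value = c(10, 44)))
  ann4 <- annotate_features(data.frame(chrom = "chr1", pos = c(10L, 30000L)),
                            list(), depth = dp, genome = g)
  expect_equal(ann4$DP, c(10, 44))
})

test_that("collected subtype sites are consistent with motif counts and the rate table", {
  fx <- fixture_cohort()
  rt <- estimate_rates(fx$variants, fx$genome, 7)
  top <- rt$subtype[order(-rt$erv_count)][1]
  motif <- sub(":.*", "", top); alt <- sub(".*:", "", top)
  ss <- collect_subtype_sites(fx$genome, motif, alt, fx$variants)
  expect_equal(nrow(ss), unname(count_motifs(fx$genome, 7)[[motif]]))
  expect_equal(sum(ss$Z), rt$erv_count[rt$subtype == top])

  # spot-check positions by brute-force motif matching
  seqs <- fx$genome$seq[["chr1"]]
  withr::with_seed(119, check <- sample(nrow(ss), 20))
  for (i in check) {
    w <- substr(seqs, ss$pos[i] - 3, ss$pos[i] + 3)
    expect_true(w == motif || oracle_revcomp(w) == motif)
  }
})

test_that("the mutability regression matches an independent Newton optimizer", {
  withr::with_seed(121, {
    n <- 500
    X <- data.frame(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.2))
    Z <- rbinom(n, 1, plogis(-2 + 0.8 * X$a - 0.5 * X$b))
  })
  if (sum(Z) < 20) Z[1:20] <- 1L
  m <- fit_subtype_model(Z, X, scale_continuous = FALSE)
  ora <- oracle_logistic(as.matrix(X), Z)
  expect_equal(unname(coef(m)), unname(ora$beta), tolerance = 1e-6)
})

test_that("with all features zero the fit reduces to the marginal rate", {
  withr::with_seed(123, Z <- rbinom(2000, 1, 0.05))
  if (sum(Z) < 20) Z[1:20] <- 1L
  X <- data.frame(f1 = numeric(2000), f2 = numeric(2000))
  m <- fit_subtype_model(Z, X)
  cf <- coef(m)
  expect_equal(unname(plogis(cf[["(Intercept)"]])), mean(Z), tolerance = 1e-9)
  expect_equal(unname(cf[c("f1", "f2")]), c(0, 0))
})

test_that("subtypes with fewer than 20 singletons are skipped with a reason", {
  m <- fit_subtype_model(c(rep(1L, 5), rep(0L, 95)),
                         data.frame(x = runif(100)))
  expect_null(m$coefficients)
  expect_match(m$skipped, "need >= 20")
})

test_that("continuous predictors are scaled to per-10%-of-range units", {
  withr::with_seed(127, {
    n <- 20000
    x <- runif(n, 0, 50)
    Z <- rbinom(n, 1, plogis(-3 + 0.04 * x))
  })
  m <- fit_subtype_model(Z, data.frame(x = x))
  # one fitted unit = 5 raw units (range 50 / 10), so effect ~ 0.2
  expect_equal(unname(m$scales[["x"]]), diff(range(x)) / 10)
  expect_equal(coef(m)[["x"]], 0.04 * m$scales[["x"]], tolerance = 0.3)
})

test_that("BH selection per feature matches a brute-force step-up", {
  withr::with_seed(129, p <- runif(1000)^2)
  models <- lapply(seq_along(p), function(i) {
    structure(list(subtype = paste0("s", i),
                   coefficients = data.frame(
                     term = c("(Intercept)", "feat"),
                     estimate = c(-3, rnorm(1)), se = 1, z = 1,
                     p = c(NA, p[i]))),
              class = "subtype_model")
  })
  sel <- fdr_select(models, q = 0.05)
  expect_equal(sel$significant, oracle_bh_flags(p, 0.05))
  expect_equal(sel$direction, ifelse(sel$estimate > 0, "+", "-"))

  # all p = 1: nothing flagged; single small p in family of one: flagged
  m1 <- models[[1]]; m1$coefficients$p[2] <- 1
  expect_false(any(fdr_select(list(m1))$significant))
  m2 <- models[[1]]; m2$coefficients$p[2] <- 0.04
  expect_true(all(fdr_select(list(m2))$significant))
})

test_that("exact binomial enrichment reproduces upper-tail oracles", {
  # null-proportion observation is not significant
  e0 <- signature_enrichment(round(4000 / 6), null_p = 1 / 6, n = 4000L)
  expect_gt(e0$p_two_sided, 0.9)

  e1 <- signature_enrichment(270L, null_p = 1 / 6, n = 403L)
  expect_lt(e1$p_upper, 1.09e-111)
  expect_equal(e1$p_upper,
               sum(stats::dbinom(270:403, 403, 1 / 6)), tolerance = 1e-10)

  e2 <- signature_enrichment(175L, null_p = 1 / 4, n = 270L)
  expect_lt(e2$p_upper, 4.12e-43)
  expect_equal(e2$p_upper,
               sum(stats::dbinom(175:270, 270, 1 / 4)), tolerance = 1e-10)

  expect_false(signature_enrichment(logical(0), null_p = 0.5)$testable)
})

test_that("de novo feature tests detect enrichment and match the Pearson formula", {
  g <- tiny_genome(random_seq(100000, seed = 131))
  tr <- feature_track("feat", "binary",
                      data.frame(chrom = "chr1", start = 0L, end = 50000L))
  # 2x enrichment inside the track at 2000 de novos
  withr::with_seed(133, {
    dn_pos <- c(sample(1:50000, 1333), sample(50001:100000, 667))
    bg_pos <- sample(1:100000, 20000)
  })
  res <- denovo_feature_test(data.frame(chrom = "chr1", pos = dn_pos),
                             data.frame(chrom = "chr1", pos = bg_pos), tr)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$direction, "+")
  expect_gt(res$rate_ratio, 1.5)

  # identical inside/outside rates: statistic near zero
  withr::with_seed(137, {
    dn0 <- sample(1:100000, 2000)
    bg0 <- sample(1:100000, 20000)
  })
  res0 <- denovo_feature_test(data.frame(chrom = "chr1", pos = dn0),
                              data.frame(chrom = "chr1", pos = bg0), tr)
  expect_lt(res0$statistic, 6)

  # hand-computed Pearson value on the produced 2x2 table
  tab <- res$table
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected))
  expect_equal(res$df, 1L)
})
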