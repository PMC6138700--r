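map_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- gen_genome(60000, gc_fraction = 0.4, n_contigs = 1, seed = 141)
      truth <- make_ground_truth(seed = 142)
      rt <- truth_rate_table(truth, g)
      tracks <- gen_feature_tracks(g, seed = 143)
      cache <<- list(genome = g, truth = truth, rates = rt, tracks = tracks)
    }
    cache
  }
})

test_that("site predictions fall back to the marginal 7-mer rate", {
  fx <- map_fixture()
  pred <- predict_site_rates(fx$genome, sites = data.frame(chrom = "chr1",
                                                           pos = 1000:1010),
                             rates = fx$rates)
  expect_equal(nrow(pred), 3 * 11)
  expect_true(all(pred$provenance == "marginal-7mer-fallback"))
  # annotation equals direct table lookup
  for (i in c(1, 17, 33)) {
    ctx <- extract_context(fx$genome, pred$chrom[i], pred$pos[i], 7)
    key <- canonical_subtype(pred$ref[i], pred$alt[i], ctx)$subtype
    expect_equal(pred$prob[i], fx$rates$rate[fx$rates$subtype == key])
  }
})

test_that("feature-model predictions apply the fitted linear predictor exactly", {
  fx <- map_fixture()
  # build one model by hand with known coefficients
  key <- "AAACAAA:T"
  cf <- data.frame(term = c("(Intercept)", "H3K36me3", "recomb_rate"),
                   estimate = c(-4, 0.7, 0.25), se = 0.1, z = 1, p = 0.01)
  model <- structure(list(subtype = key, coefficients = cf,
                          scales = c(H3K36me3 = 1, recomb_rate = 0.33),
                          n_sites = 100, n_ervs = 30, converged = TRUE,
                          skipped = NULL, flag = NULL),
                     class = "subtype_model")
  sites <- collect_subtype_sites(fx$genome, "AAACAAA", "T",
                                 data.frame(chrom = character(),
                                            pos = integer(),
                                            ref = character(),
                                            alt = character()))
  expect_gt(nrow(sites), 0)
  site1 <- sites[1, c("chrom", "pos")]
  pred <- predict_site_rates(fx$genome, sites = site1,
                             models = stats::setNames(list(model), key),
                             rates = fx$rates,
                             tracks = fx$tracks[c("H3K36me3", "recomb_rate")])
  row <- pred[pred$provenance == "feature-model", ]
  expect_equal(nrow(row), 1L)
  ann <- annotate_features(site1, fx$tracks[c("H3K36me3", "recomb_rate")],
                           genome = fx$genome)
  eta <- -4 + 0.7 * ann$H3K36me3 + 0.25 * (ann$recomb_rate / 0.33)
  expect_equal(row$prob, plogis(eta), tolerance = 1e-12)

  # within the telomeric exclusion the marginal rate is used
  pred_telo <- predict_site_rates(fx$genome, sites = site1,
                                  models = stats::setNames(list(model), key),
                                  rates = fx$rates,
                                  tracks = fx$tracks[c("H3K36me3",
                                                       "recomb_rate")],
                                  telomere_bp = chrom_lengths(fx$genome)[[1]])
  expect_true(all(pred_telo$provenance == "marginal-7mer-fallback"))
})

test_that("a zero-feature landscape reproduces the marginal rates through the model path", {
  fx <- map_fixture()
  key <- "AAACAAA:T"
  sites <- collect_subtype_sites(fx$genome, "AAACAAA", "T",
                                 data.frame(chrom = character(),
                                            pos = integer(),
                                            ref = character(),
                                            alt = character()))
  expect_gt(nrow(sites), 1)
  marginal <- fx$rates$rate[fx$rates$subtype == key]
  model <- structure(list(subtype = key,
                          coefficients = data.frame(
                            term = c("(Intercept)", "flat"),
                            estimate = c(qlogis(marginal), 0),
                            se = 0.1, z = 1, p = 0.5),
                          scales = c(flat = 1), n_sites = nrow(sites),
                          n_ervs = 30, converged = TRUE, skipped = NULL,
                          flag = NULL), class = "subtype_model")
  flat <- feature_track("flat", "binary",
                        data.frame(chrom = character(), start = integer(),
                                   end = integer()))
  pred <- predict_site_rates(fx$genome, sites = sites[, c("chrom", "pos")],
                             models = stats::setNames(list(model), key),
                             rates = fx$rates, tracks = list(flat = flat))
  model_rows <- pred$provenance == "feature-model"
  expect_true(any(model_rows))
  expect_equal(unique(pred$prob[model_rows]), marginal, tolerance = 1e-12)
})

test_that("map output round-trips and merges equal adjacent values", {
  fx <- map_fixture()
  pred <- predict_site_rates(fx$genome,
                             sites = data.frame(chrom = "chr1",
                                                pos = 2000:2050),
                             rates = fx$rates)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_map(pred, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(pred))
  expect_equal(back$prob,
               as.numeric(trimws(formatC(pred$prob, digits = 6,
                                         format = "g"))))

  # empty stream still yields a valid header-only file
  write_map(pred[0, ], tsv)
  expect_equal(readLines(tsv), "chrom\tpos\tref\talt\tprob\tprovenance")

  # bedGraph run-length merging vs brute force on the alt1 track
  prefix <- withr::local_tempfile()
  paths <- write_map(pred, prefix, format = "bedgraph")
  p1 <- pred[stats::ave(seq_len(nrow(pred)),
                        paste(pred$chrom, pred$pos),
                        FUN = function(i) rank(pred$alt[i])) == 1, ]
  vals <- trimws(formatC(p1$prob, digits = 6, format = "g"))
  runs <- rle(vals)
  got <- utils::read.delim(paste0(prefix, ".alt1.bedGraph"), skip = 1,
                           header = FALSE)
  expect_equal(nrow(got), length(runs$lengths))
  expect_equal(as.character(got$V4), runs$values)
  expect_equal(got$V3 - got$V2, runs$lengths)

  # out-of-order input is rejected
  expect_error(write_map(pred[rev(seq_len(nrow(pred))), ], tsv),
               "coordinate order")
})

test_that("VCF annotation matches direct rate lookup and passes non-SNVs through", {
  fx <- map_fixture()
  v <- gen_singletons(fx$genome, fx$truth, n_samples = 4, seed = 144)
  withr::with_seed(145, v <- v[sample(nrow(v), 100), ])
  v <- v[order(v$chrom, v$pos), ]
  vcf_in <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, vcf_in, genome = fx$genome)
  # append a non-SNV record
  lines <- readLines(vcf_in)
  lines <- c(lines, sprintf("chr1\t%d\t.\tAT\tA\t.\tPASS\t.",
                            chrom_lengths(fx$genome)[[1]] - 10L))
  writeLines(lines, vcf_in)
  vcf_out <- withr::local_tempfile(fileext = ".vcf")
  annotate_vcf(vcf_in, vcf_out, fx$genome, fx$rates)
  body <- grep("^[^#]", readLines(vcf_out), value = TRUE)
  expect_match(body[length(body)], "MRFLAG=NOT_SNV")
  snv <- body[-length(body)]
  rate_in_info <- as.numeric(sub(".*MRRATE=([0-9.eE+-]+).*", "\\1", snv))
  expected <- annotate_covariate(v, fx$rates, fx$genome)
  expect_equal(rate_in_info,
               as.numeric(trimws(formatC(expected, digits = 6,
                                         format = "g"))))
})
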