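#' Generate a synthetic reference genome
#'
#' Draws i.i.d. bases at a requested GC fraction over one or more contigs,
#' with an optional accessibility mask covering a random subset of the
#' sequence. Deterministic given `seed`.
#'
#' @param length_bp total length across contigs.
#' @param gc_fraction target G+C fraction, in (0,1).
#' @param n_contigs number of contigs (named `chr1`, `chr2`, ...).
#' @param seed integer seed.
#' @param mask_coverage fraction of each contig covered by the
#'   accessibility mask (0 = no mask).
#' @return a `genome_seq`.
#' @export
gen_genome <- function(length_bp, gc_fraction = 0.4, n_contigs = 1L, seed,
                       mask_coverage = 0) {
  if (missing(seed)) stop("seed is required")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  if (length_bp < 7L * n_contigs) stop("length_bp too small for n_contigs")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  per <- rep(length_bp %/% n_contigs, n_contigs)
  per[1] <- per[1] + length_bp %% n_contigs
  prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
            G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(per, function(n)
    paste(sample(names(prob), n, replace = TRUE, prob = prob),
          collapse = ""), character(1))
  names(seqs) <- paste0("chr", seq_len(n_contigs))
  mask <- NULL
  if (mask_coverage > 0) {
    mask <- do.call(rbind, lapply(seq_len(n_contigs), function(i) {
      iv <- random_intervals(per[i], mask_coverage,
                             mean_len = max(200L, per[i] %/% 50L))
      if (is.null(iv)) return(NULL)
      cbind(chrom = names(seqs)[i], iv)
    }))
  }
  genome_seq(seqs, mask = mask)
}

# Random union of intervals with approximately the requested coverage.
# Returns data.frame(start, end), 0-based half-open, merged and sorted.
random_intervals <- function(len, coverage, mean_len = 500L) {
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  if (coverage == 0) return(NULL)
  if (coverage == 1) return(data.frame(start = 0L, end = len))
  # aim the nominal interval mass at -log(1-coverage) so the realized
  # union coverage (after overlap merging) matches the request
  n <- max(1L, round(-log(1 - coverage) * len / mean_len))
  w <- pmax(1L, stats::rgeom(n, 1 / mean_len) + 1L)
  s <- sample.int(len, n, replace = TRUE) - 1L
  iv <- IRanges::reduce(IRanges::IRanges(start = s + 1L,
                                         end = pmin(len, s + w)))
  data.frame(start = IRanges::start(iv) - 1L, end = IRanges::end(iv))
}

#' Ground truth for synthetic cohorts
#'
#' Builds the generative parameters used by [gen_singletons()] and
#' [gen_denovo()]: per-7-mer-subtype base rates (per-type means modulated
#' by lognormal context noise, with a CpG transition boost), optional
#' per-feature log-odds effects, and all seeds. The defaults give a
#' spectrum dominated by transitions with hypermutable CpG C>T contexts,
#' and per-subtype singleton probabilities small enough that a 1-2 Mb
#' contig yields tens of thousands of singletons.
#'
#' @param seed integer seed.
#' @param type_means named base rate per basic type (probability per site
#'   per alternative).
#' @param cpg_boost multiplier on C>T (and, halved, C>A/C>G) rates at CpG
#'   motifs.
#' @param context_sd SD of the lognormal context modulation (log scale).
#'   The default (1) makes within-class context heterogeneity dominate
#'   between-class mean differences, mirroring the pervasive fine-context
#'   rate heterogeneity seen in singleton data; see the methods vignette
#'   for why the context-resolution ranking is only identifiable under a
#'   wide context spread.
#' @param feature_effects optional data.frame with columns `feature`,
#'   `type` (basic type, or `"all"`), `beta` (log odds per predictor
#'   unit).
#' @param rate_scale global multiplier on all rates.
#' @return object of class `ground_truth`: `rates` (named over subtype
#'   keys), `feature_effects`, `seed`.
#' @export
make_ground_truth <- function(seed,
                              type_means = c("A>C" = 0.002, "A>G" = 0.008,
                                             "A>T" = 0.002, "C>A" = 0.003,
                                             "C>G" = 0.003, "C>T" = 0.010),
                              cpg_boost = 6, context_sd = 1,
                              feature_effects = NULL, rate_scale = 1) {
  if (missing(seed)) stop("seed is required")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  enum <- enumerate_subtypes(7L)
  base <- type_means[enum$type]
  cpg <- enum$ref == "C" & substr(enum$motif, 5L, 5L) == "G"
  boost <- ifelse(cpg, ifelse(enum$type == "C>T", cpg_boost,
                              pmax(1, cpg_boost / 2)), 1)
  noise <- stats::rlnorm(nrow(enum), meanlog = -context_sd^2 / 2,
                         sdlog = context_sd)
  rates <- pmin(0.5, rate_scale * base * boost * noise)
  structure(list(
    rates = stats::setNames(as.numeric(rates), enum$subtype),
    feature_effects = feature_effects,
    seed = seed
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d subtype rates, mean %.2g, seed %d\n",
              length(x$rates), mean(x$rates), x$seed))
  if (!is.null(x$feature_effects)) {
    cat("  feature effects:\n")
    print.data.frame(x$feature_effects, row.names = FALSE)
  }
  invisible(x)
}

#' Write / read ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path file path.
#' @return `path` (write) or a `ground_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(rates = as.list(truth$rates),
                            feature_effects = truth$feature_effects,
                            seed = truth$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(rates = unlist(j$rates),
                 feature_effects = j$feature_effects,
                 seed = j$seed), class = "ground_truth")
}

#' Rate table implied by ground truth on a genome
#'
#' Builds the exact rate table the generative model implies: per-subtype
#' expected singleton counts (rate times motif occurrences) over the
#' genome's 7-mer motif counts. Aggregating with [aggregate_rates()]
#' yields the motif-count-weighted coarse strategies (5-, 3-, 1-mer) that
#' a rate-estimation method limited to that context width would converge
#' to, which is what model-comparison simulations rank against the full
#' 7-mer truth.
#'
#' @param truth a `ground_truth`.
#' @param genome a `genome_seq`.
#' @return a 7-mer `rate_table` (expected counts, not integers).
#' @export
truth_rate_table <- function(truth, genome) {
  mc <- count_motifs(genome, 7L)
  enum <- enumerate_subtypes(7L)
  ec <- truth$rates[enum$subtype] * mc[enum$motif]
  rate_table(stats::setNames(as.numeric(ec), enum$subtype), mc, K = 7L)
}

#' Generate synthetic genomic feature tracks
#'
#' Emulates the feature roster used by the mutability regressions: binary
#' tracks (histone marks, CpG islands, DHS, lamin domains, exons) as
#' random interval unions at a requested coverage; continuous tracks
#' (recombination rate, replication timing, GC content) as binned random
#' walks; per-site read depth as overdispersed counts in short bins.
#'
#' @param genome a `genome_seq`.
#' @param spec data.frame with columns `name`, `kind`, and `coverage`
#'   (binary) or `mean`/`sd` (continuous); default: the standard 14-track
#'   roster.
#' @param seed integer seed.
#' @param bin_bp bin width for continuous tracks.
#' @return named list of `feature_track`s, with the depth track under
#'   `$DP`.
#' @export
gen_feature_tracks <- function(genome, spec = default_track_spec(), seed,
                               bin_bp = 1000L) {
  if (missing(seed)) stop("seed is required")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  lens <- chrom_lengths(genome)
  out <- list()
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    if (spec$kind[i] == "binary") {
      iv <- do.call(rbind, lapply(names(lens), function(cm) {
        d <- random_intervals(lens[[cm]], spec$coverage[i])
        if (is.null(d)) return(NULL)
        cbind(chrom = cm, d)
      }))
      if (is.null(iv))
        iv <- data.frame(chrom = character(), start = integer(),
                         end = integer())
      out[[nm]] <- feature_track(nm, "binary", iv)
    } else {
      iv <- do.call(rbind, lapply(names(lens), function(cm) {
        brk <- seq(0L, lens[[cm]], by = bin_bp)
        if (brk[length(brk)] < lens[[cm]]) brk <- c(brk, lens[[cm]])
        nb <- length(brk) - 1L
        walk <- cumsum(stats::rnorm(nb, 0, spec$sd[i] / sqrt(nb)))
        val <- pmax(0, spec$mean[i] + walk - mean(walk))
        data.frame(chrom = cm, start = brk[-length(brk)], end = brk[-1],
                   value = val)
      }))
      out[[nm]] <- feature_track(nm, "continuous", iv)
    }
  }
  # read depth: negative-binomial counts in 100-bp bins
  dp <- do.call(rbind, lapply(names(lens), function(cm) {
    brk <- seq(0L, lens[[cm]], by = 100L)
    if (brk[length(brk)] < lens[[cm]]) brk <- c(brk, lens[[cm]])
    nb <- length(brk) - 1L
    data.frame(chrom = cm, start = brk[-length(brk)], end = brk[-1],
               value = stats::rnbinom(nb, mu = 30, size = 10))
  }))
  out$DP <- feature_track("DP", "continuous", dp)
  out
}

#' @rdname gen_feature_tracks
#' @export
default_track_spec <- function() {
  binary <- c("H3K4me1", "H3K4me3", "H3K9me3", "H3K27ac", "H3K27me3",
              "H3K36me3", "H3K9ac", "LAD", "CpG_island", "DHS", "exon")
  data.frame(
    name = c(binary, "recomb_rate", "repl_timing", "gc_content"),
    kind = c(rep("binary", 11L), rep("continuous", 3L)),
    coverage = c(c(0.15, 0.05, 0.25, 0.08, 0.12, 0.20, 0.06, 0.35, 0.02,
                   0.05, 0.03), rep(NA, 3)),
    mean = c(rep(NA, 11), 1.5, 0.5, 0.4),
    sd = c(rep(NA, 11), 1.0, 0.8, 0.1),
    stringsAsFactors = FALSE
  )
}

# Long table of every predictable (site, alt) pair with its canonical
# subtype index; kidx indexes enumerate_subtypes(7).
site_alt_table <- function(genome) {
  enum <- enumerate_subtypes(7L)
  ALTS <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  out <- do.call(rbind, lapply(names(genome$seq), function(cm) {
    s <- genome$seq[[cm]]
    len <- nchar(s)
    if (len < 7L) return(NULL)
    pos <- 4L:(len - 3L)
    ctx <- substring(s, pos - 3L, pos + 3L)
    ok <- !grepl("N", ctx, fixed = TRUE)
    pos <- pos[ok]; ctx <- ctx[ok]
    ref <- substr(ctx, 4L, 4L)
    canon <- ref %in% c("A", "C")
    cmotif <- ctx
    cmotif[!canon] <- revcomp(ctx[!canon])
    alt <- matrix(unlist(ALTS[ref], use.names = FALSE), ncol = 3L,
                  byrow = TRUE)
    calt <- alt
    calt[!canon, ] <- matrix(COMPLEMENT[alt[!canon, ]], ncol = 3L)
    kidx <- match(paste0(rep(cmotif, 3L), ":", as.vector(calt)),
                  enum$subtype)
    data.frame(chrom = rep(cm, length(pos) * 3L),
               pos = rep(pos, 3L),
               ref = rep(ref, 3L),
               alt = as.vector(alt),
               kidx = kidx,
               stringsAsFactors = FALSE)
  }))
  attr(out, "enum") <- enum
  out
}

# Per-(site, alt) Bernoulli probability under the generative model:
# logit p = logit(base rate of subtype) + sum_g beta_g * F_g(site).
site_alt_probs <- function(sat, truth, genome, tracks, window_bp) {
  enum <- attr(sat, "enum")
  p0 <- truth$rates[enum$subtype[sat$kidx]]
  eta <- stats::qlogis(pmin(pmax(p0, 1e-12), 1 - 1e-12))
  fe <- truth$feature_effects
  if (!is.null(fe) && nrow(fe)) {
    if (is.null(tracks)) stop("truth has feature effects but no tracks given")
    need <- unique(fe$feature)
    ann <- annotate_features(sat[!duplicated(paste(sat$chrom, sat$pos)),
                                 c("chrom", "pos")],
                             tracks[need], genome = genome,
                             window_bp = window_bp)
    site_key <- paste(sat$chrom, sat$pos)
    site_idx <- match(site_key,
                      unique(site_key))
    type <- enum$type[sat$kidx]
    for (i in seq_len(nrow(fe))) {
      hit <- if (fe$type[i] == "all") rep(TRUE, nrow(sat))
             else type == fe$type[i]
      eta[hit] <- eta[hit] +
        fe$beta[i] * ann[[fe$feature[i]]][site_idx[hit]]
    }
  }
  stats::plogis(eta)
}

#' Generate per-sample singleton variants from ground truth
#'
#' Forward model: for every eligible (site, alternative allele) pair,
#' draw an independent Bernoulli with probability given by the subtype's
#' base rate on the logit scale plus any feature effects. Each emitted
#' variant is a singleton (AC = 1) assigned to a sample, uniformly by
#' default.
#'
#' @param genome a `genome_seq`.
#' @param truth a `ground_truth`.
#' @param n_samples number of individuals.
#' @param seed integer seed.
#' @param tracks named list of `feature_track`s (needed when `truth` has
#'   feature effects).
#' @param window_bp continuous-feature window passed through.
#' @param sample_weights optional per-sample assignment weights.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `sample_id`,
#'   `ac`; attribute `expected_counts` (per-subtype expectations).
#' @export
gen_singletons <- function(genome, truth, n_samples = 100L, seed,
                           tracks = NULL, window_bp = 10000L,
                           sample_weights = NULL) {
  if (missing(seed)) stop("seed is required")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sat <- site_alt_table(genome)
  p <- site_alt_probs(sat, truth, genome, tracks, window_bp)
  n_sites <- nrow(sat) / 3
  if (sum(p) > n_sites)
    stop("rates too high: expected variant count exceeds site count")
  hit <- stats::runif(nrow(sat)) < p
  enum <- attr(sat, "enum")
  expected <- tapply(p, enum$subtype[sat$kidx], sum)
  out <- sat[hit, c("chrom", "pos", "ref", "alt")]
  ids <- sprintf("S%04d", seq_len(n_samples))
  out$sample_id <- if (nrow(out)) sample(ids, nrow(out), replace = TRUE,
                                         prob = sample_weights)
                   else character(0)
  out$ac <- rep(1L, nrow(out))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "expected_counts") <- expected
  attr(out, "samples") <- ids
  out
}

#' Generate a de novo mutation set from ground truth
#'
#' Draws `n` distinct (site, alternative) pairs with probability
#' proportional to the ground-truth rate of the pair's subtype
#' (optionally perturbed), excluding supplied positions (typically the
#' singleton set, so labels never conflict).
#'
#' @param genome a `genome_seq`.
#' @param truth a `ground_truth`.
#' @param n number of de novo mutations.
#' @param seed integer seed.
#' @param exclude optional data.frame with `chrom`, `pos`.
#' @param perturbation `NULL` (draw from truth) or `"uniform"` (ignore
#'   truth rates; used to test ranking robustness).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @export
gen_denovo <- function(genome, truth, n, seed, exclude = NULL,
                       perturbation = NULL) {
  if (missing(seed)) stop("seed is required")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sat <- site_alt_table(genome)
  if (!is.null(exclude) && nrow(exclude)) {
    keep <- !paste(sat$chrom, sat$pos) %in%
      paste(exclude$chrom, exclude$pos)
    en <- attr(sat, "enum")
    sat <- sat[keep, , drop = FALSE]
    attr(sat, "enum") <- en
  }
  if (n == 0) return(sat[0, c("chrom", "pos", "ref", "alt")])
  if (n > nrow(sat)) stop("n exceeds eligible (site, alt) pairs")
  enum <- attr(sat, "enum")
  w <- if (identical(perturbation, "uniform")) rep(1, nrow(sat))
       else truth$rates[enum$subtype[sat$kidx]]
  # draw with replacement so inclusion stays proportional to the weights
  # (heavy-tailed weights bias without-replacement draws), then thin
  # duplicates until n distinct pairs are collected
  idx <- unique(sample.int(nrow(sat), n, replace = TRUE, prob = w))
  guard <- 0L
  while (length(idx) < n && guard < 100L) {
    extra <- sample.int(nrow(sat), n - length(idx), replace = TRUE, prob = w)
    idx <- unique(c(idx, extra))
    guard <- guard + 1L
  }
  if (length(idx) < n) stop("could not draw n distinct de novo sites")
  out <- sat[idx, c("chrom", "pos", "ref", "alt")]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spike aberrant-spectrum outlier samples into a singleton set
#'
#' Replaces the variants of randomly chosen samples with variants drawn
#' from an aberrant 3-mer spectrum (each replacement keeps the sample's
#' variant count): a 3-mer subtype is drawn from the aberrant
#' distribution, then a uniform genome position carrying that context.
#' Used to exercise the NMF signature-contribution QC rule.
#'
#' @param variants singleton data.frame with `sample_id`.
#' @param genome a `genome_seq`.
#' @param n_outliers number of samples to spike.
#' @param seed integer seed.
#' @param aberrant named numeric vector of weights over the 96 3-mer
#'   subtype keys; default concentrates 90% of mass on C>G subtypes.
#' @return list with `variants` (modified data.frame) and `outliers`
#'   (spiked sample IDs).
#' @export
spike_outliers <- function(variants, genome, n_outliers, seed,
                           aberrant = NULL) {
  if (missing(seed)) stop("seed is required")
  samples <- sort(unique(variants$sample_id))
  if (n_outliers >= length(samples))
    stop("n_outliers must be smaller than the number of samples")
  if (n_outliers == 0) return(list(variants = variants,
                                   outliers = character(0)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  enum <- enumerate_subtypes(3L)
  if (is.null(aberrant)) {
    aberrant <- stats::setNames(rep(0.1 / 64, nrow(enum)), enum$subtype)
    cg <- enum$type == "C>G"
    aberrant[cg] <- 0.9 / sum(cg)
  }
  aberrant <- aberrant[enum$subtype]
  aberrant[is.na(aberrant)] <- 0
  # index genome positions by canonical 3-mer motif
  pos_by_motif <- list()
  for (cm in names(genome$seq)) {
    s <- genome$seq[[cm]]
    len <- nchar(s)
    if (len < 3L) next
    pos <- 2L:(len - 1L)
    ctx <- substring(s, pos - 1L, pos + 1L)
    ok <- !grepl("N", ctx, fixed = TRUE)
    pos <- pos[ok]; ctx <- ctx[ok]
    canon <- substr(ctx, 2L, 2L) %in% c("A", "C")
    ctx[!canon] <- revcomp(ctx[!canon])
    sp <- split(pos, ctx)
    for (m in names(sp))
      pos_by_motif[[m]] <- rbind(pos_by_motif[[m]],
                                 data.frame(chrom = cm, pos = sp[[m]]))
  }
  outliers <- sample(samples, n_outliers)
  for (sid in outliers) {
    idx <- which(variants$sample_id == sid)
    k <- length(idx)
    if (!k) next
    keys <- sample(enum$subtype, k, replace = TRUE, prob = aberrant)
    motif <- sub(":.*$", "", keys)
    calt <- sub("^.*:", "", keys)
    for (j in seq_len(k)) {
      cand <- pos_by_motif[[motif[j]]]
      pick <- cand[sample.int(nrow(cand), 1L), ]
      ref <- substr(genome$seq[[pick$chrom]], pick$pos, pick$pos)
      canon <- ref %in% c("A", "C")
      variants$chrom[idx[j]] <- pick$chrom
      variants$pos[idx[j]] <- pick$pos
      variants$ref[idx[j]] <- ref
      variants$alt[idx[j]] <- if (canon) calt[j]
                              else unname(COMPLEMENT[calt[j]])
    }
  }
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, outliers = sort(outliers))
}
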