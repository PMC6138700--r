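#' Predict per-site mutation probabilities
#'
#' For each site, emits three probabilities, one per possible alternative
#' allele: the inverse-logit of the site's feature-adjusted linear
#' predictor under the corresponding 7-mer subtype model. All estimated
#' effects are used, not only the statistically significant ones. Sites
#' within `telomere_bp` of a contig end, or whose subtype has no fitted
#' model (skipped or flagged), receive the marginal 7-mer rate from the
#' rate table instead, with provenance `"marginal-7mer-fallback"`. Sites
#' whose 7-mer context is unavailable (edge or N) yield no prediction and
#' are counted.
#'
#' @param genome a `genome_seq`.
#' @param sites data.frame with `chrom`, `pos`; default all positions of
#'   all contigs.
#' @param models named list of `subtype_model`s keyed by subtype
#'   (`motif:alt`), or NULL to use the marginal table everywhere.
#' @param rates a 7-mer `rate_table` providing the marginal fallback.
#' @param tracks,depth,window_bp feature annotation inputs passed to
#'   [annotate_features()] (needed when `models` is given).
#' @param telomere_bp width of the per-contig end exclusion within which
#'   the marginal rate is used (default 0 for short synthetic contigs; 5
#'   Mb matches recombination-map availability on real chromosomes).
#' @return data.frame of class `site_rate_prediction`: `chrom`, `pos`,
#'   `ref`, `alt`, `prob`, `provenance`; attribute `n_unpredictable`.
#' @export
predict_site_rates <- function(genome, sites = NULL, models = NULL, rates,
                               tracks = NULL, depth = NULL,
                               window_bp = 10000L, telomere_bp = 0L) {
  stopifnot(inherits(rates, "rate_table"), rates$K[1] == 7L)
  lens <- chrom_lengths(genome)
  if (is.null(sites)) {
    sites <- do.call(rbind, lapply(names(lens), function(cm)
      data.frame(chrom = cm, pos = seq_len(lens[[cm]]),
                 stringsAsFactors = FALSE)))
  }
  ctx <- contexts_at(genome, sites$chrom, sites$pos, 7L)
  ok <- !is.na(ctx)
  n_unpred <- sum(!ok)
  sites <- sites[ok, , drop = FALSE]
  ctx <- ctx[ok]
  ref <- substr(ctx, 4L, 4L)
  # three rows per site, one per alternative allele of the reference base
  alts <- matrix(unlist(lapply(ref, setdiff, x = BASES), use.names = FALSE),
                 ncol = 3L, byrow = TRUE)
  long <- data.frame(
    chrom = rep(sites$chrom, each = 3L),
    pos = rep(sites$pos, each = 3L),
    ref = rep(ref, each = 3L),
    alt = as.vector(t(alts)),
    stringsAsFactors = FALSE
  )
  sub <- canonical_subtype(long$ref, long$alt, rep(ctx, each = 3L))
  long$prob <- rates$rate[match(sub$subtype, rates$subtype)]
  long$provenance <- "marginal-7mer-fallback"
  if (!is.null(models)) {
    telo <- sites$pos <= telomere_bp |
      sites$pos > lens[sites$chrom] - telomere_bp
    fitted_keys <- names(models)[vapply(models, function(m)
      !is.null(m$coefficients), logical(1))]
    use <- rep(!telo, each = 3L) & sub$subtype %in% fitted_keys
    if (any(use)) {
      pred <- annotate_features(sites, tracks, depth = depth,
                                genome = genome, window_bp = window_bp)
      pred_long <- pred[rep(seq_len(nrow(sites)), each = 3L)[use], ,
                        drop = FALSE]
      keys <- sub$subtype[use]
      probs <- numeric(sum(use))
      for (k in unique(keys)) {
        sel <- keys == k
        probs[sel] <- predict(models[[k]], pred_long[sel, , drop = FALSE])
      }
      long$prob[use] <- probs
      long$provenance[use] <- "feature-model"
    }
  }
  attr(long, "n_unpredictable") <- n_unpred
  class(long) <- c("site_rate_prediction", "data.frame")
  long
}

#' Write a mutation-rate map
#'
#' Writes predictions either as a 6-column TSV (chrom, pos, ref, alt,
#' prob, provenance) or as bedGraph, one track file per alternative-allele
#' rank (suffixes `.alt1/.alt2/.alt3.bedGraph`, alternatives in
#' alphabetical order per site), with runs of adjacent equal values merged
#' into single intervals. Probabilities are formatted to 6 significant
#' digits; byte output is deterministic given input order. Input must be
#' coordinate-sorted.
#'
#' @param predictions a `site_rate_prediction`.
#' @param path output path (TSV) or path prefix (bedGraph).
#' @param format `"tsv"` or `"bedgraph"`.
#' @return the path(s) written, invisibly.
fmt6 <- function(x) trimws(formatC(x, digits = 6, format = "g"))

#' @export
write_map <- function(predictions, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  p <- as.data.frame(predictions)
  if (nrow(p)) {
    o <- order(p$chrom, p$pos, p$alt)
    if (any(o != seq_len(nrow(p))))
      stop("predictions must be streamed in coordinate order")
  }
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("chrom\tpos\tref\talt\tprob\tprovenance", con)
    if (nrow(p))
      writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t%s", p$chrom, p$pos, p$ref,
                         p$alt, fmt6(p$prob),
                         p$provenance), con)
    return(invisible(path))
  }
  # bedGraph: rank alternatives within site, one track per rank
  p$rank <- stats::ave(seq_len(nrow(p)),
                       paste(p$chrom, p$pos),
                       FUN = function(i) rank(p$alt[i]))
  paths <- character(3)
  for (r in 1:3) {
    pr <- p[p$rank == r, , drop = FALSE]
    f <- paste0(path, ".alt", r, ".bedGraph")
    con <- file(f, "w")
    writeLines(sprintf("track type=bedGraph name=\"mutation_rate_alt%d\"", r),
               con)
    if (nrow(pr)) {
      val <- fmt6(pr$prob)
      # merge runs of adjacent positions with identical formatted value
      new_run <- c(TRUE, pr$chrom[-1] != pr$chrom[-nrow(pr)] |
                     pr$pos[-1] != pr$pos[-nrow(pr)] + 1L |
                     val[-1] != val[-nrow(pr)])
      run <- cumsum(new_run)
      start <- tapply(pr$pos, run, min) - 1L
      end <- tapply(pr$pos, run, max)
      chrom <- tapply(pr$chrom, run, `[`, 1L)
      v <- tapply(val, run, `[`, 1L)
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start, end, v), con)
    }
    close(con)
    paths[r] <- f
  }
  invisible(paths)
}

#' Annotate a VCF with estimated mutation rates
#'
#' Adds INFO keys to each biallelic SNV record: `MRSUB` (canonical
#' subtype), `MRRATE` (the K-mer relative rate from the table) and, when
#' subtype models are given, `MRPRED` (the feature-adjusted predicted
#' probability). Records whose REF disagrees with the genome are flagged
#' with `MRFLAG=REF_MISMATCH` and left unannotated; non-SNV records pass
#' through with `MRFLAG=NOT_SNV`.
#'
#' @param vcf_in input VCF path (text).
#' @param vcf_out output VCF path.
#' @param genome a `genome_seq`.
#' @param rates a `rate_table`.
#' @param models optional named list of `subtype_model`s plus feature
#'   annotation inputs as in [predict_site_rates()].
#' @param tracks,depth,window_bp see [predict_site_rates()].
#' @return `vcf_out`, invisibly.
#' @export
annotate_vcf <- function(vcf_in, vcf_out, genome, rates, models = NULL,
                         tracks = NULL, depth = NULL, window_bp = 10000L) {
  K <- rates$K[1]
  lines <- readLines(vcf_in)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  extra <- c(
    sprintf("##INFO=<ID=MRSUB,Number=1,Type=String,Description=\"Canonical %d-mer mutation subtype\">", K),
    sprintf("##INFO=<ID=MRRATE,Number=1,Type=Float,Description=\"Relative mutation rate of the %d-mer subtype\">", K),
    if (!is.null(models))
      "##INFO=<ID=MRPRED,Number=1,Type=Float,Description=\"Feature-adjusted predicted singleton probability\">",
    "##INFO=<ID=MRFLAG,Number=1,Type=String,Description=\"Annotation flag\">")
  hdr <- append(hdr, extra, after = length(hdr) - 1L)
  body <- lines[!is_hdr]
  out_body <- character(length(body))
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    for (i in seq_along(f)) {
      rec <- f[[i]]
      info <- rec[8]
      add <- annotate_record(rec[1], as.integer(rec[2]), rec[4], rec[5],
                             genome, rates, models, tracks, depth,
                             window_bp, K)
      info <- if (info == "." || info == "") add else paste0(info, ";", add)
      rec[8] <- info
      out_body[i] <- paste(rec, collapse = "\t")
    }
  }
  writeLines(c(hdr, out_body), vcf_out)
  invisible(vcf_out)
}

annotate_record <- function(chrom, pos, ref, alt, genome, rates, models,
                            tracks, depth, window_bp, K) {
  if (nchar(ref) != 1L || nchar(alt) != 1L || !ref %in% BASES ||
      !alt %in% BASES)
    return("MRFLAG=NOT_SNV")
  ctx <- tryCatch(extract_context(genome, chrom, pos, K),
                  error = function(e) NULL)
  if (is.null(ctx)) return("MRFLAG=NO_CONTEXT")
  centre <- (K + 1L) %/% 2L
  if (substr(ctx, centre, centre) != ref) return("MRFLAG=REF_MISMATCH")
  sub <- canonical_subtype(ref, alt, ctx)
  rate <- rates$rate[match(sub$subtype, rates$subtype)]
  out <- sprintf("MRSUB=%s;MRRATE=%s", format_subtype(sub$subtype),
                 fmt6(rate))
  if (!is.null(models) && sub$subtype %in% names(models) &&
      !is.null(models[[sub$subtype]]$coefficients)) {
    pred <- annotate_features(data.frame(chrom = chrom, pos = pos),
                              tracks, depth = depth, genome = genome,
                              window_bp = window_bp)
    pr <- predict(models[[sub$subtype]], pred)
    out <- paste0(out, ";MRPRED=", fmt6(pr))
  }
  out
}
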