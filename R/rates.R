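#' Construct a relative mutation-rate table
#'
#' A rate table holds, for every canonical K-mer mutation subtype, the
#' number of singleton (extremely rare) variants observed at the central
#' position of the motif (`erv_count`), the number of occurrences of the
#' motif in the reference (`motif_count`), and their ratio, the estimated
#' relative mutation rate. The rate is a proportion, not a per-generation
#' mutation rate.
#'
#' @param erv_count named integer vector over subtype keys (`motif:alt`),
#'   or a data.frame with columns `subtype` and `erv_count`.
#' @param motif_count named integer vector over canonical motifs.
#' @param K the context width.
#' @return data.frame of class `rate_table` with columns `motif`, `ref`,
#'   `alt`, `type`, `subtype`, `erv_count`, `motif_count`, `rate`, in the
#'   fixed enumeration order.
#' @examples
#' # the arithmetic behind a printed worked value: 7548/53314 = 0.1416
#' rt <- rate_table(c("ATACGCA:T" = 7548),
#'                  c(ATACGCA = 53314), K = 7)
#' round(rt$rate[rt$subtype == "ATACGCA:T"], 4)
#' @export
rate_table <- function(erv_count, motif_count, K) {
  enum <- enumerate_subtypes(K)
  if (is.data.frame(erv_count))
    erv_count <- stats::setNames(erv_count$erv_count, erv_count$subtype)
  ec <- stats::setNames(numeric(nrow(enum)), enum$subtype)
  if (length(erv_count)) {
    unknown <- setdiff(names(erv_count), enum$subtype)
    if (length(unknown))
      stop("unknown subtype keys: ", paste(utils::head(unknown), collapse = ", "))
    ec[names(erv_count)] <- erv_count
  }
  mc <- stats::setNames(numeric(nrow(enum)), unique(enum$motif))
  mc[names(motif_count)] <- motif_count
  enum$erv_count <- as.numeric(ec)
  enum$motif_count <- as.numeric(mc[enum$motif])
  bad <- enum$motif_count == 0 & enum$erv_count > 0
  if (any(bad))
    stop("inconsistent input: ERVs observed at motifs absent from genome: ",
         paste(utils::head(enum$subtype[bad]), collapse = ", "))
  enum$rate <- ifelse(enum$motif_count > 0,
                      enum$erv_count / enum$motif_count, 0)
  class(enum) <- c("rate_table", "data.frame")
  enum
}

#' @export
print.rate_table <- function(x, n = 10L, ...) {
  K <- x$K[1]
  cat(sprintf("<rate_table> K = %d: %d subtypes, %s ERVs / %s motif occurrences\n",
              K, nrow(x), format(sum(x$erv_count), big.mark = ","),
              format(sum(x$motif_count), big.mark = ",")))
  skipped <- attr(x, "n_skipped")
  if (!is.null(skipped) && skipped > 0)
    cat(sprintf("  (%d variant(s) skipped at edge/N windows)\n", skipped))
  top <- x[order(-x$rate), c("subtype", "erv_count", "motif_count", "rate")]
  top$subtype <- format_subtype(top$subtype)
  top$rate <- round(top$rate, 4)
  print.data.frame(utils::head(top, n), row.names = FALSE)
  invisible(x)
}

#' @export
summary.rate_table <- function(object, ...) {
  by_type <- split(object, object$type)
  out <- data.frame(
    type = names(by_type),
    n_subtypes = vapply(by_type, nrow, integer(1)),
    erv_count = vapply(by_type, function(d) sum(d$erv_count), numeric(1)),
    motif_count = vapply(by_type, function(d) sum(d$motif_count), numeric(1))
  )
  out$rate <- out$erv_count / out$motif_count
  rownames(out) <- NULL
  out
}

#' Estimate relative mutation rates per subtype
#'
#' Classifies each variant into its canonical K-mer subtype via the
#' reference context at its position and divides per-subtype counts by
#' genome-wide motif counts. Variants whose context window runs off a
#' chromosome end or contains N are skipped and counted in the
#' `n_skipped` attribute. A variant whose VCF `ref` disagrees with the
#' genome is a hard error.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `ac` (cohort allele count) and
#'   `sample_id`.
#' @param genome a `genome_seq`.
#' @param K context width (1, 3, 5 or 7).
#' @param use_mask restrict motif counting and variants to
#'   mask-accessible central bases.
#' @param min_ac,max_ac allele-count filter applied when an `ac` column
#'   is present; the default `min_ac = max_ac = 1` keeps singletons only.
#'   Set e.g. `min_ac = 10, max_ac = Inf` for a common-variant table.
#' @return a [rate_table()].
#' @export
estimate_rates <- function(variants, genome, K, use_mask = FALSE,
                           min_ac = 1, max_ac = 1) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (!is.null(variants$ac))
    variants <- variants[variants$ac >= min_ac & variants$ac <= max_ac, ,
                         drop = FALSE]
  snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% BASES & variants$alt %in% BASES
  variants <- variants[snv, , drop = FALSE]
  if (use_mask) {
    keep <- in_mask(genome, variants$chrom, variants$pos)
    variants <- variants[keep, , drop = FALSE]
  }
  ctx <- contexts_at(genome, variants$chrom, variants$pos, K)
  ok <- !is.na(ctx)
  centre <- (K + 1L) %/% 2L
  mism <- ok & substr(ctx, centre, centre) != toupper(variants$ref)
  if (any(mism))
    stop(sprintf("reference mismatch between variants and genome at %d site(s), e.g. %s:%d",
                 sum(mism), variants$chrom[mism][1], variants$pos[mism][1]))
  sub <- canonical_subtype(variants$ref[ok], variants$alt[ok], ctx[ok])
  counts <- table(sub$subtype)
  rt <- rate_table(stats::setNames(as.numeric(counts), names(counts)),
                   count_motifs(genome, K, use_mask = use_mask), K = K)
  attr(rt, "n_skipped") <- sum(!ok)
  attr(rt, "n_classified") <- nrow(sub)
  attr(rt, "use_mask") <- use_mask
  rt
}

# Is each (chrom, pos) inside an accessibility-mask interval?
in_mask <- function(genome, chrom, pos) {
  if (is.null(genome$mask)) stop("genome has no accessibility mask")
  out <- logical(length(pos))
  for (cm in unique(chrom)) {
    idx <- chrom == cm
    mk <- genome$mask[genome$mask$chrom == cm, , drop = FALSE]
    if (!nrow(mk)) next
    iv <- IRanges::IRanges(mk$start + 1L, mk$end)
    out[idx] <- IRanges::overlapsAny(IRanges::IRanges(pos[idx], pos[idx]), iv)
  }
  out
}

#' Aggregate a rate table to a narrower context
#'
#' Each K-mer subtype splits into 16 (K+2)-mer constituents sharing the
#' same internal motif; conversely, a (K+2)-mer table aggregates to the
#' K-mer table by summing ERV and motif counts, making each parent rate
#' the motif-count-weighted mean of its constituents' rates. Aggregation
#' commutes with estimation: aggregating a directly estimated (K+2)-mer
#' table reproduces the directly estimated K-mer table exactly.
#'
#' @param x a `rate_table` at width K+2 (K+2 >= 3).
#' @return a `rate_table` at width K.
#' @export
aggregate_rates <- function(x) {
  stopifnot(inherits(x, "rate_table"))
  K <- x$K[1]
  if (K < 3L) stop("cannot aggregate below K = 1")
  parent_key <- paste0(shrink_motif(x$motif), ":", x$alt)
  ec <- tapply(x$erv_count, parent_key, sum)
  first <- !duplicated(x$motif)
  mc <- tapply(x$motif_count[first], shrink_motif(x$motif[first]), sum)
  rate_table(stats::setNames(as.numeric(ec), names(ec)),
             stats::setNames(as.numeric(mc), names(mc)), K = K - 2L)
}

#' Chi-squared heterogeneity test for one parent subtype
#'
#' Tests whether the relative rates of the 16 (K+2)-mer constituents of a
#' K-mer subtype are uniform, using a Pearson chi-squared statistic on the
#' 16 x 2 table of (ERV, non-ERV) counts with 15 degrees of freedom.
#' Constituents with zero motif occurrences contribute nothing to the
#' statistic; the degrees of freedom stay at 15 by construction of the
#' taxonomy. A parent with zero ERVs is untestable.
#'
#' @param erv_count,motif_count numeric vectors of length 16.
#' @return list with `statistic`, `df` (always 15), `p_value`, and
#'   `testable`.
#' @export
heterogeneity_test <- function(erv_count, motif_count) {
  stopifnot(length(erv_count) == 16L, length(motif_count) == 16L)
  if (any(erv_count > motif_count)) stop("erv_count exceeds motif_count")
  X <- sum(erv_count); M <- sum(motif_count)
  if (X == 0 || X == M)
    return(list(statistic = NA_real_, df = 15L, p_value = NA_real_,
                testable = FALSE))
  e1 <- motif_count * X / M
  e2 <- motif_count * (M - X) / M
  o1 <- erv_count; o2 <- motif_count - erv_count
  keep <- motif_count > 0
  stat <- sum((o1[keep] - e1[keep])^2 / e1[keep]) +
    sum((o2[keep] - e2[keep])^2 / e2[keep])
  list(statistic = stat, df = 15L,
       p_value = stats::pchisq(stat, df = 15L, lower.tail = FALSE),
       testable = TRUE)
}

#' Heterogeneity tests for all parents of a rate table
#'
#' Runs [heterogeneity_test()] for every (K-2)-mer parent subtype of a
#' K-mer rate table.
#'
#' @param x a `rate_table` at width K >= 3.
#' @return data.frame with one row per parent subtype: `subtype`,
#'   `statistic`, `df`, `p_value`, `testable`.
#' @export
heterogeneity_tests <- function(x) {
  stopifnot(inherits(x, "rate_table"))
  if (x$K[1] < 3L) stop("need K >= 3")
  parent <- paste0(shrink_motif(x$motif), ":", x$alt)
  res <- lapply(split(seq_len(nrow(x)), parent), function(idx) {
    heterogeneity_test(x$erv_count[idx], x$motif_count[idx])
  })
  out <- data.frame(
    subtype = names(res),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df = 15L,
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    testable = vapply(res, `[[`, logical(1), "testable")
  )
  rownames(out) <- NULL
  out[order(out$subtype), , drop = FALSE]
}

#' Write / read rate tables as TSV
#' @param x a `rate_table`.
#' @param path file path.
#' @return `path` (write) or a `rate_table` (read).
#' @export
write_rate_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  rate_table(stats::setNames(d$erv_count, d$subtype),
             stats::setNames(d$motif_count[!duplicated(d$motif)],
                             d$motif[!duplicated(d$motif)]),
             K = d$K[1])
}
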