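#' Compare two rate tables
#'
#' Compares two rate tables at the same context width, e.g. singleton-based
#' estimates against common-variant estimates. Rates are first normalized
#' within each table (divided by the table-wide sum) so the comparison is of
#' mutation spectra rather than absolute ERV yield. Reports the overall
#' Spearman rank correlation, per-basic-type Spearman correlations, the
#' per-subtype normalized ratio `b/a`, and the fraction of subtypes whose
#' normalized rates differ by 50% or more. Subtypes with a zero rate in
#' either table are excluded from ratio-based statistics and counted.
#'
#' @param a,b `rate_table`s at the same K.
#' @return object of class `rate_comparison`: list with `spearman_overall`,
#'   `spearman_by_type`, `ratios` (data.frame), `frac_diff_ge_50`,
#'   `n_excluded`, `K`.
#' @export
compare_rate_tables <- function(a, b) {
  stopifnot(inherits(a, "rate_table"), inherits(b, "rate_table"))
  if (a$K[1] != b$K[1]) stop("rate tables have different K")
  m <- merge(as.data.frame(a)[, c("subtype", "type", "motif", "alt", "rate")],
             as.data.frame(b)[, c("subtype", "rate")],
             by = "subtype", suffixes = c("_a", "_b"))
  m <- m[order(m$subtype), , drop = FALSE]
  m$norm_a <- m$rate_a / sum(m$rate_a)
  m$norm_b <- m$rate_b / sum(m$rate_b)
  overall <- stats::cor(m$norm_a, m$norm_b, method = "spearman")
  by_type <- vapply(split(m, m$type), function(d) {
    if (nrow(d) < 2L) return(NA_real_)
    stats::cor(d$norm_a, d$norm_b, method = "spearman")
  }, numeric(1))
  pos <- m$norm_a > 0 & m$norm_b > 0
  m$ratio <- ifelse(pos, m$norm_b / m$norm_a, NA_real_)
  frac <- mean(abs(m$ratio[pos] - 1) >= 0.5)
  structure(list(
    spearman_overall = overall,
    spearman_by_type = by_type,
    ratios = m[, c("subtype", "type", "norm_a", "norm_b", "ratio")],
    frac_diff_ge_50 = frac,
    n_excluded = sum(!pos),
    K = a$K[1],
    normalization = "rate / table-wide rate sum"
  ), class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("<rate_comparison> K = %d\n", x$K))
  cat(sprintf("  overall Spearman r = %.3f\n", x$spearman_overall))
  cat("  by type: ",
      paste(sprintf("%s %.2f", names(x$spearman_by_type), x$spearman_by_type),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  subtypes with normalized difference >= 50%%: %.1f%% (%d excluded)\n",
              100 * x$frac_diff_ge_50, x$n_excluded))
  invisible(x)
}

#' @export
plot.rate_comparison <- function(x, ...) {
  r <- x$ratios
  keep <- r$norm_a > 0 & r$norm_b > 0
  graphics::plot(r$norm_a[keep], r$norm_b[keep], log = "xy", pch = 16,
                 cex = 0.3, col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "normalized rate (table a)",
                 ylab = "normalized rate (table b)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' GC-strata test of rate discrepancies
#'
#' Within a basic type, classifies each 7-mer motif by its flanking G/C
#' content (count of G or C among the 6 non-central bases) into a high-GC
#' stratum (4-6) and a low-GC stratum (0-3), and compares the log rate
#' ratio `log(b/a)` between strata with a two-sample t-test. A systematic
#' positive shift in the high-GC stratum is the pattern expected under
#' GC-biased gene conversion inflating common-variant based estimates.
#'
#' @param a,b 7-mer `rate_table`s.
#' @param types basic types to test (default the A-centered transversions
#'   and transitions most affected, `A>C` and `A>G`).
#' @return data.frame with one row per type: `type`, `t`, `df`, `p_value`,
#'   `mean_log_ratio_high`, `mean_log_ratio_low`, `testable`.
#' @export
gc_strata_test <- function(a, b, types = c("A>C", "A>G")) {
  stopifnot(inherits(a, "rate_table"), inherits(b, "rate_table"))
  if (a$K[1] != 7L || b$K[1] != 7L) stop("gc_strata_test needs 7-mer tables")
  m <- merge(as.data.frame(a)[, c("subtype", "type", "motif", "rate")],
             as.data.frame(b)[, c("subtype", "rate")],
             by = "subtype", suffixes = c("_a", "_b"))
  m <- m[m$type %in% types & m$rate_a > 0 & m$rate_b > 0, , drop = FALSE]
  m$gc <- flank_gc_count(m$motif)
  m$log_ratio <- log(m$rate_b / m$rate_a)
  out <- do.call(rbind, lapply(types, function(ty) {
    d <- m[m$type == ty, , drop = FALSE]
    hi <- d$log_ratio[d$gc >= 4]
    lo <- d$log_ratio[d$gc <= 3]
    if (length(hi) < 2L || length(lo) < 2L)
      return(data.frame(type = ty, t = NA_real_, df = NA_real_,
                        p_value = NA_real_, mean_log_ratio_high = NA_real_,
                        mean_log_ratio_low = NA_real_, testable = FALSE))
    if (stats::sd(hi) == 0 && stats::sd(lo) == 0 && mean(hi) == mean(lo))
      return(data.frame(type = ty, t = 0, df = NA_real_, p_value = 1,
                        mean_log_ratio_high = mean(hi),
                        mean_log_ratio_low = mean(lo), testable = TRUE))
    tt <- stats::t.test(hi, lo)
    data.frame(type = ty, t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, mean_log_ratio_high = mean(hi),
               mean_log_ratio_low = mean(lo), testable = TRUE)
  }))
  rownames(out) <- NULL
  out
}

#' Count G/C bases in the flanks of a motif
#' @param motif character vector of odd-length motifs.
#' @return integer vector: number of G or C among the non-central bases.
#' @export
flank_gc_count <- function(motif) {
  K <- nchar(motif)
  centre <- (K + 1L) %/% 2L
  flanks <- paste0(substr(motif, 1L, centre - 1L),
                   substr(motif, centre + 1L, K))
  nchar(gsub("[^GC]", "", flanks))
}
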