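#' Genomic feature track
#'
#' A named feature track: binary tracks are interval sets (a site has the
#' feature iff it falls inside an interval); continuous tracks carry a
#' numeric value over intervals (bedGraph semantics) and are queried as a
#' mean over a window.
#'
#' @param name track name (used as the predictor column name).
#' @param kind `"binary"` or `"continuous"`.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open, BED convention) and, for continuous tracks, `value`; or a
#'   GRanges (with a `score` column for continuous tracks).
#' @return object of class `feature_track`.
#' @export
feature_track <- function(name, kind = c("binary", "continuous"), intervals) {
  kind <- match.arg(kind)
  if (methods::is(intervals, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(intervals)),
                     start = GenomicRanges::start(intervals) - 1L,
                     end = GenomicRanges::end(intervals),
                     stringsAsFactors = FALSE)
    if (kind == "continuous") df$value <- S4Vectors::mcols(intervals)$score
    intervals <- df
  }
  need <- c("chrom", "start", "end", if (kind == "continuous") "value")
  stopifnot(all(need %in% names(intervals)))
  intervals <- intervals[order(intervals$chrom, intervals$start), need,
                         drop = FALSE]
  structure(list(name = name, kind = kind, intervals = intervals),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> %s (%s): %d interval(s)\n",
              x$name, x$kind, nrow(x$intervals)))
  invisible(x)
}

#' Read a feature track from BED / bedGraph
#' @param path file path.
#' @param name track name (default: file base name).
#' @param kind `"binary"` (BED) or `"continuous"` (bedGraph).
#' @return a `feature_track`.
#' @export
read_feature_track <- function(path, name = NULL,
                               kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gr <- rtracklayer::import(path,
                            format = if (kind == "binary") "BED" else "bedGraph")
  feature_track(name, kind, gr)
}

#' Write a feature track to BED / bedGraph
#' @param track a `feature_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_track <- function(track, path) {
  iv <- track$intervals
  utils::write.table(iv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Annotate sites with feature predictors
#'
#' Builds the predictor matrix for the per-subtype mutability regressions:
#' binary features are 1 iff the central site lies inside an interval;
#' continuous features are the mean value over a window (default 10 kb)
#' centered at the site, truncated at contig edges and weighted by
#' interval overlap; read depth is the track value at the central site.
#' Sites with any missing predictor (continuous track with no data in the
#' window, or no depth value) get NA in that column.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based).
#' @param tracks named list of `feature_track`s.
#' @param depth optional continuous `feature_track` of per-site read
#'   depth.
#' @param genome a `genome_seq` (for contig-edge truncation).
#' @param window_bp window width for continuous features (default 10000).
#' @return data.frame of predictors, one column per track (plus `DP` when
#'   depth is given), rows aligned with `sites`.
#' @export
annotate_features <- function(sites, tracks, depth = NULL, genome,
                              window_bp = 10000L) {
  lens <- chrom_lengths(genome)
  half <- window_bp %/% 2L
  out <- lapply(tracks, function(tr) {
    if (tr$kind == "binary") {
      as.numeric(site_in_track(sites, tr))
    } else {
      window_mean(sites, tr, half, lens)
    }
  })
  names(out) <- vapply(tracks, `[[`, character(1), "name")
  out <- if (length(out)) as.data.frame(out, optional = TRUE)
         else data.frame(row.names = seq_len(nrow(sites)))
  if (!is.null(depth)) out$DP <- value_at(sites, depth)
  rownames(out) <- NULL
  out
}

site_in_track <- function(sites, track) {
  out <- logical(nrow(sites))
  iv <- track$intervals
  for (cm in unique(sites$chrom)) {
    idx <- sites$chrom == cm
    t_cm <- iv[iv$chrom == cm, , drop = FALSE]
    if (!nrow(t_cm)) next
    rng <- IRanges::IRanges(t_cm$start + 1L, t_cm$end)
    out[idx] <- IRanges::overlapsAny(
      IRanges::IRanges(sites$pos[idx], sites$pos[idx]), rng)
  }
  out
}

window_mean <- function(sites, track, half, lens) {
  out <- rep(NA_real_, nrow(sites))
  iv <- track$intervals
  for (cm in unique(sites$chrom)) {
    idx <- which(sites$chrom == cm)
    t_cm <- iv[iv$chrom == cm, , drop = FALSE]
    if (!nrow(t_cm)) next
    win <- IRanges::IRanges(pmax(1L, sites$pos[idx] - half),
                            pmin(lens[[cm]], sites$pos[idx] + half))
    rng <- IRanges::IRanges(t_cm$start + 1L, t_cm$end)
    hits <- IRanges::findOverlaps(win, rng)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(win[q], rng[s]))
    wsum <- tapply(ov * t_cm$value[s], q, sum)
    wtot <- tapply(ov, q, sum)
    out[idx[as.integer(names(wsum))]] <- wsum / wtot
  }
  out
}

value_at <- function(sites, track) {
  out <- rep(NA_real_, nrow(sites))
  iv <- track$intervals
  for (cm in unique(sites$chrom)) {
    idx <- which(sites$chrom == cm)
    t_cm <- iv[iv$chrom == cm, , drop = FALSE]
    if (!nrow(t_cm)) next
    rng <- IRanges::IRanges(t_cm$start + 1L, t_cm$end)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[idx], sites$pos[idx]), rng, select = "first")
    has <- !is.na(hits)
    out[idx[has]] <- t_cm$value[hits[has]]
  }
  out
}

#' Collect all genome sites of a 7-mer subtype with singleton outcomes
#'
#' Finds every position whose canonical centered 7-mer equals the
#' subtype's motif and labels it `Z = 1` iff a singleton of exactly that
#' subtype (same alternative allele after canonicalization) occurs there.
#'
#' @param genome a `genome_seq`.
#' @param motif canonical 7-mer motif (central base A or C).
#' @param alt canonical alternative allele.
#' @param variants data.frame of singletons (`chrom`, `pos`, `ref`,
#'   `alt`).
#' @return data.frame with `chrom`, `pos`, `Z`.
#' @export
collect_subtype_sites <- function(genome, motif, alt, variants) {
  K <- nchar(motif)
  h <- (K - 1L) %/% 2L
  rc <- revcomp(motif)
  out <- do.call(rbind, lapply(names(genome$seq), function(cm) {
    s <- Biostrings::DNAString(genome$seq[[cm]])
    fwd <- Biostrings::start(Biostrings::matchPattern(motif, s)) + h
    rev_ <- Biostrings::start(Biostrings::matchPattern(rc, s)) + h
    pos <- sort(unique(c(fwd, rev_)))
    if (!length(pos)) return(NULL)
    data.frame(chrom = cm, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(chrom = character(), pos = integer(), Z = integer()))
  out$Z <- 0L
  if (nrow(variants)) {
    ctx <- contexts_at(genome, variants$chrom, variants$pos, K)
    ok <- !is.na(ctx)
    sub <- canonical_subtype(variants$ref[ok], variants$alt[ok], ctx[ok])
    hit <- sub$motif == motif & sub$alt == alt
    key <- paste(variants$chrom[ok][hit], variants$pos[ok][hit])
    out$Z[paste(out$chrom, out$pos) %in% key] <- 1L
  }
  out
}

#' Per-subtype logistic regression of mutability on genomic features
#'
#' Fits the log-odds of a site carrying a singleton on an intercept plus
#' the feature predictors (by maximum likelihood / IRLS). Continuous
#' predictors are rescaled so a unit change is 10% of the predictor's
#' observed range, making reported odds ratios "per 10% increase";
#' binary predictors are left as 0/1. Subtypes with fewer than `min_ervs`
#' singletons are skipped (too little information). Zero-variance
#' predictors get a zero coefficient by construction. The fitted
#' intercept's inverse logit is the feature-adjusted relative mutation
#' rate of the subtype.
#'
#' @param outcomes 0/1 vector (`Z`), or the data.frame from
#'   [collect_subtype_sites()].
#' @param predictors data.frame from [annotate_features()]; rows with any
#'   NA are dropped and counted.
#' @param subtype optional subtype key carried into the result.
#' @param min_ervs minimum singleton count to fit (default 20).
#' @param scale_continuous rescale non-binary columns to per-10%-of-range
#'   units (default TRUE).
#' @return object of class `subtype_model`: `subtype`, `coefficients`
#'   (data.frame: term, estimate, se, z, p), `n_sites`, `n_ervs`,
#'   `n_dropped`, `scales`, `converged`, `skipped` (reason or NULL),
#'   `flag`.
#' @export
fit_subtype_model <- function(outcomes, predictors, subtype = NA_character_,
                              min_ervs = 20L, scale_continuous = TRUE) {
  Z <- if (is.data.frame(outcomes)) outcomes$Z else outcomes
  stopifnot(length(Z) == nrow(predictors))
  keep <- stats::complete.cases(predictors)
  n_dropped <- sum(!keep)
  Z <- as.integer(Z[keep])
  X <- predictors[keep, , drop = FALSE]
  res <- list(subtype = subtype, n_sites = length(Z), n_ervs = sum(Z),
              n_dropped = n_dropped, skipped = NULL, flag = NULL)
  if (res$n_ervs < min_ervs) {
    res$skipped <- sprintf("only %d singleton(s); need >= %d",
                           res$n_ervs, min_ervs)
    class(res) <- "subtype_model"
    return(res)
  }
  scales <- rep(1, ncol(X)); names(scales) <- names(X)
  if (scale_continuous) {
    for (j in names(X)) {
      v <- X[[j]]
      if (!all(v %in% c(0, 1))) {
        rng <- diff(range(v))
        if (rng > 0) { scales[j] <- rng / 10; X[[j]] <- v / scales[j] }
      }
    }
  }
  variable <- vapply(X, function(v) stats::var(v) > 0, logical(1))
  Xf <- X[, variable, drop = FALSE]
  dat <- cbind(data.frame(.Z = Z), Xf)
  fit <- stats::glm(.Z ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(maxit = 100L,
                                                 epsilon = 1e-10))
  est <- stats::coef(fit)
  if (anyNA(est)) {
    res$flag <- "separation or collinearity; coefficients withheld"
    res$converged <- FALSE
    class(res) <- "subtype_model"
    return(res)
  }
  sm <- summary(fit)$coefficients
  terms <- c("(Intercept)", names(X))
  cf <- data.frame(term = terms, estimate = 0, se = NA_real_,
                   z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  # glm backtick-quotes nonsyntactic names; strip them for matching
  fitted_terms <- gsub("`", "", rownames(sm))
  m <- match(fitted_terms, cf$term)
  cf$estimate[m] <- sm[, 1]
  cf$se[m] <- sm[, 2]
  cf$z[m] <- sm[, 3]
  cf$p[m] <- sm[, 4]
  res$coefficients <- cf
  res$scales <- scales
  res$converged <- fit$converged
  if (!fit$converged) res$flag <- "IRLS did not converge"
  class(res) <- "subtype_model"
  res
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> %s: %s sites, %d singleton(s)\n",
              if (is.na(x$subtype)) "(unnamed)" else format_subtype(x$subtype),
              format(x$n_sites, big.mark = ","), x$n_ervs))
  if (!is.null(x$skipped)) {
    cat("  skipped: ", x$skipped, "\n", sep = "")
  } else if (!is.null(x$flag)) {
    cat("  flag: ", x$flag, "\n", sep = "")
  }
  if (!is.null(x$coefficients)) {
    cf <- x$coefficients
    cf$estimate <- round(cf$estimate, 4)
    cf$se <- round(cf$se, 4)
    cf$p <- signif(cf$p, 3)
    print.data.frame(cf[, c("term", "estimate", "se", "p")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.subtype_model <- function(object, ...) {
  if (is.null(object$coefficients)) return(NULL)
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Predict singleton probability from a subtype model
#'
#' Inverse-logit of the fitted linear predictor on new predictor rows
#' (raw scale; the model's internal rescaling is applied automatically).
#'
#' @param object a fitted `subtype_model`.
#' @param newdata data.frame with the model's predictor columns.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.subtype_model <- function(object, newdata, ...) {
  if (is.null(object$coefficients)) stop("model has no coefficients")
  cf <- stats::setNames(object$coefficients$estimate,
                        object$coefficients$term)
  eta <- rep(cf[["(Intercept)"]], nrow(newdata))
  for (j in setdiff(names(cf), "(Intercept)")) {
    if (!j %in% names(newdata)) stop("newdata lacks predictor: ", j)
    eta <- eta + cf[[j]] * (newdata[[j]] / object$scales[[j]])
  }
  stats::plogis(eta)
}

#' Benjamini-Hochberg selection of feature effects across subtypes
#'
#' Collects Wald p-values for each feature across all fitted subtype
#' models and applies the Benjamini-Hochberg step-up procedure per
#' feature (one family per feature, across subtypes). Flags carry the
#' effect direction.
#'
#' @param models list of `subtype_model`s.
#' @param q FDR level (default 0.05).
#' @return data.frame with `subtype`, `term`, `estimate`, `p`, `q_bh`,
#'   `significant`, `direction` (`"+"` for OR > 1).
#' @export
fdr_select <- function(models, q = 0.05) {
  rows <- do.call(rbind, lapply(models, function(m) {
    if (is.null(m$coefficients)) return(NULL)
    cf <- m$coefficients
    cf <- cf[cf$term != "(Intercept)" & !is.na(cf$p), , drop = FALSE]
    if (!nrow(cf)) return(NULL)
    data.frame(subtype = m$subtype, term = cf$term, estimate = cf$estimate,
               p = cf$p, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(data.frame(subtype = character(), term = character(),
                      estimate = numeric(), p = numeric(), q_bh = numeric(),
                      significant = logical(), direction = character()))
  rows$q_bh <- NA_real_
  for (term in unique(rows$term)) {
    idx <- rows$term == term
    rows$q_bh[idx] <- stats::p.adjust(rows$p[idx], method = "BH")
  }
  rows$significant <- rows$q_bh <= q
  rows$direction <- ifelse(rows$estimate > 0, "+", "-")
  rownames(rows) <- NULL
  rows
}

#' Exact binomial enrichment of a category among flagged subtypes
#'
#' Given flagged subtypes and a category membership, tests whether the
#' category is over-represented relative to the null proportion implied
#' by the subtype enumeration (e.g. 1/6 for one basic type among all
#' types; 1/4 for W[A>G]W flank membership among A>G 3-mer contexts),
#' with an exact binomial upper-tail probability.
#'
#' @param is_member logical vector over the flagged set (TRUE = in
#'   category), or an integer count `k` if `n` is given.
#' @param null_p null category proportion.
#' @param n total flagged count when `is_member` is a count.
#' @return list with `k`, `n`, `null_p`, `observed_p`, `p_upper` (exact
#'   upper tail, P[X >= k]), `p_two_sided`, `testable`.
#' @export
signature_enrichment <- function(is_member, null_p, n = NULL) {
  if (is.null(n)) {
    n <- length(is_member)
    k <- sum(is_member)
  } else {
    k <- as.integer(is_member)
  }
  if (n == 0)
    return(list(k = 0L, n = 0L, null_p = null_p, observed_p = NA_real_,
                p_upper = NA_real_, p_two_sided = NA_real_,
                testable = FALSE))
  p_upper <- stats::pbinom(k - 1L, n, null_p, lower.tail = FALSE)
  bt <- stats::binom.test(k, n, p = null_p)
  list(k = k, n = n, null_p = null_p, observed_p = k / n,
       p_upper = p_upper, p_two_sided = bt$p.value, testable = TRUE)
}

#' Chi-squared test of de novo enrichment within a feature
#'
#' 2x2 Pearson chi-squared (1 df, no continuity correction) of de novo
#' versus background site counts, inside versus outside a feature track's
#' intervals, with a direction check against the expected sign. When any
#' expected cell count is zero the test falls back to Fisher's exact
#' test, labelled as such.
#'
#' @param denovo,background data.frames with `chrom`, `pos`.
#' @param track a binary `feature_track`.
#' @param expected_direction `"+"` (enrichment expected inside) or
#'   `"-"`.
#' @return list with the 2x2 `table`, `statistic`, `df`, `p_value`,
#'   `rate_ratio` (inside/outside de novo fraction ratio), `direction`,
#'   `direction_consistent`, `method`.
#' @export
denovo_feature_test <- function(denovo, background, track,
                                expected_direction = "+") {
  din <- site_in_track(denovo, track)
  bin <- site_in_track(background, track)
  tab <- matrix(c(sum(din), sum(!din), sum(bin), sum(!bin)), nrow = 2,
                dimnames = list(c("inside", "outside"),
                                c("denovo", "background")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    ft <- stats::fisher.test(tab)
    stat <- NA_real_; p <- ft$p.value; method <- "fisher_exact"
  } else {
    stat <- sum((tab - expected)^2 / expected)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "pearson_chisq"
  }
  frac_in <- tab["inside", "denovo"] /
    (tab["inside", "denovo"] + tab["inside", "background"])
  frac_out <- tab["outside", "denovo"] /
    (tab["outside", "denovo"] + tab["outside", "background"])
  rr <- frac_in / frac_out
  direction <- if (is.nan(rr) || rr == 1) "0" else if (rr > 1) "+" else "-"
  list(table = tab, statistic = stat, df = 1L, p_value = p,
       rate_ratio = rr, direction = direction,
       direction_consistent = identical(direction, expected_direction),
       method = method)
}
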