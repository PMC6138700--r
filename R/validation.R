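#' Sample a nonmutated background of genomic sites
#'
#' Draws `n` distinct positions uniformly from the mappable (non-N)
#' positions of the genome, excluding a supplied site set (typically the
#' de novo mutations being validated, so no site carries both labels).
#' Deterministic given `seed`.
#'
#' @param genome a `genome_seq`.
#' @param n number of sites.
#' @param exclude optional data.frame with `chrom`, `pos` to exclude.
#' @param seed integer seed.
#' @param use_mask restrict to accessibility-mask positions.
#' @return data.frame with `chrom`, `pos`, `ref`.
#' @export
sample_background <- function(genome, n, exclude = NULL, seed,
                              use_mask = FALSE) {
  if (missing(seed)) stop("seed is required")
  if (n < 0) stop("n must be non-negative")
  pool <- do.call(rbind, lapply(names(genome$seq), function(cm) {
    b <- strsplit(genome$seq[[cm]], "", fixed = TRUE)[[1]]
    keep <- b != "N"
    data.frame(chrom = cm, pos = which(keep), ref = b[keep],
               stringsAsFactors = FALSE)
  }))
  if (use_mask) pool <- pool[in_mask(genome, pool$chrom, pool$pos), ]
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(pool$chrom, pool$pos)
    pool <- pool[!key %in% paste(exclude$chrom, exclude$pos), , drop = FALSE]
  }
  if (n > nrow(pool))
    stop(sprintf("requested %d sites but only %d are available", n, nrow(pool)))
  if (n == 0) return(pool[0, , drop = FALSE])
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  out <- pool[sample.int(nrow(pool), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition background sites into three type sets
#'
#' Each nonmutated site could serve as background for any of the three
#' substitutions at its reference base, so the background is split into
#' three non-overlapping sets, each interpreted as one substitution per
#' reference base: set 1 = A>G / C>T, set 2 = A>C / C>G, set 3 =
#' A>T / C>A (reference bases read on the canonical strand, so a T-site in
#' set 1 is a nonmutated T>C, i.e. A>G). Set sizes are ceiling(n/3) for
#' set 1 and an equal split of the remainder, so 1,000,000 sites partition
#' as 333,334 / 333,333 / 333,333.
#'
#' @param sites data.frame with at least `chrom`, `pos`, `ref`.
#' @param seed integer seed for the random assignment.
#' @return `sites` with added columns `set` (1:3), `alt` (the assigned
#'   alternative allele on the reference strand) and `d` (0).
#' @export
partition_background <- function(sites, seed) {
  if (missing(seed)) stop("seed is required")
  n <- nrow(sites)
  s1 <- ceiling(n / 3)
  s2 <- ceiling((n - s1) / 2)
  s3 <- n - s1 - s2
  lab <- rep.int(1:3, c(s1, s2, s3))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  sites$set <- lab[sample.int(n)]
  # canonical-strand alt per (set, canonical ref); complement back for
  # reference bases on the other strand
  canon_alt <- rbind(`1` = c(A = "G", C = "T"),
                     `2` = c(A = "C", C = "G"),
                     `3` = c(A = "T", C = "A"))
  is_canon <- sites$ref %in% c("A", "C")
  cref <- ifelse(is_canon, sites$ref, unname(COMPLEMENT[sites$ref]))
  calt <- canon_alt[cbind(as.character(sites$set), cref)]
  sites$alt <- ifelse(is_canon, calt, unname(COMPLEMENT[calt]))
  sites$d <- 0L
  sites
}

#' Assign one of 9 basic mutation types to testing sites
#'
#' The 6 canonical substitution types, with the three C-types split by CpG
#' status: a C-site is CpG when the canonical-strand C is immediately
#' followed by G in the reference (for a G reference base this is a
#' preceding C on the plus strand). Sites whose dinucleotide context is
#' unavailable (chromosome edge or N) are dropped with a count.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param genome a `genome_seq`.
#' @return `sites` with added columns `type` (6-way) and `type9` (9-way),
#'   rows with undeterminable context removed; attribute `n_dropped`.
#' @export
assign_basic_type <- function(sites, genome) {
  ctx <- contexts_at(genome, sites$chrom, sites$pos, 3L)
  ok <- !is.na(ctx)
  dropped <- sum(!ok)
  sites <- sites[ok, , drop = FALSE]
  ctx <- ctx[ok]
  sub <- canonical_subtype(sites$ref, sites$alt, ctx)
  sites$type <- sub$type
  is_c <- sub$ref == "C"
  # canonical motif has the C at the centre; CpG iff followed by G
  cpg <- is_c & substr(sub$motif, 3L, 3L) == "G"
  sites$type9 <- sites$type
  sites$type9[is_c] <- paste0(sites$type[is_c],
                              ifelse(cpg[is_c], "_CpG", "_nonCpG"))
  attr(sites, "n_dropped") <- dropped
  sites
}

#' Annotate testing sites with a rate covariate
#'
#' Looks up, for each site, the relative mutation rate of its canonical
#' subtype under the supplied rate table (the "strategy"), using the
#' site's reference context at the table's K.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param rates a `rate_table`.
#' @param genome a `genome_seq`.
#' @return numeric vector of covariate values (NA where the context is
#'   unavailable).
#' @export
annotate_covariate <- function(sites, rates, genome) {
  K <- rates$K[1]
  ctx <- contexts_at(genome, sites$chrom, sites$pos, K)
  ok <- !is.na(ctx)
  out <- rep(NA_real_, nrow(sites))
  if (any(ok)) {
    sub <- canonical_subtype(sites$ref[ok], sites$alt[ok], ctx[ok])
    out[ok] <- rates$rate[match(sub$subtype, rates$subtype)]
  }
  out
}

#' Fit the single-covariate validation model
#'
#' Logistic regression of the de novo indicator on the rate covariate:
#' `logit Pr(d = 1) = a0 + a1 * r`, fitted by iteratively reweighted least
#' squares. Reports the maximized log-likelihood, the AIC computed with
#' p = 1 covariate parameter (`AIC = 2 - 2 lnL`), and Nagelkerke's
#' pseudo-R-squared against the intercept-only null. A constant covariate
#' makes the slope unidentifiable: the fit collapses to the null model
#' with R-squared 0 and is flagged.
#'
#' @param d 0/1 de novo indicator.
#' @param r non-negative rate covariate (used untransformed, on the
#'   probability scale).
#' @param label strategy label carried into comparisons.
#' @param max_iter IRLS iteration cap.
#' @return object of class `denovo_fit`: `label`, `alpha0`, `alpha1`,
#'   `logLik`, `logLik_null`, `aic`, `r2_nagelkerke`, `n`, `converged`,
#'   `flag`.
#' @export
fit_validation_model <- function(d, r, label = "model", max_iter = 100L) {
  stopifnot(length(d) == length(r))
  keep <- !is.na(d) & !is.na(r)
  d <- as.integer(d[keep]); r <- as.numeric(r[keep])
  if (!all(d %in% 0:1)) stop("d must be 0/1")
  if (!any(d == 1) || !any(d == 0))
    stop("need at least one de novo and one background site")
  n <- length(d)
  ll0 <- null_loglik(d)
  flag <- NULL
  if (stats::var(r) == 0) {
    a0 <- stats::qlogis(mean(d)); a1 <- NA_real_
    ll <- ll0
    flag <- "constant covariate; slope unidentifiable, null model reported"
    converged <- TRUE
  } else {
    fit <- stats::glm.fit(cbind(1, r), d,
                          family = stats::binomial(),
                          control = list(maxit = max_iter, epsilon = 1e-8))
    converged <- fit$converged
    a0 <- fit$coefficients[1]; a1 <- fit$coefficients[2]
    if (anyNA(c(a0, a1))) {
      a0 <- stats::qlogis(mean(d)); a1 <- NA_real_
      ll <- ll0
      flag <- "degenerate covariate; slope unidentifiable, null model reported"
      converged <- TRUE
    } else {
    eta <- a0 + a1 * r
    ll <- sum(d * eta - log1pexp(eta))
    if (!converged) flag <- "IRLS did not converge"
    mu <- stats::plogis(eta)
    if (all(mu[d == 1] > 1 - 1e-8) && all(mu[d == 0] < 1e-8))
      flag <- "complete separation"
    }
  }
  # p = 1 covariate parameter for a fitted slope; a constant covariate
  # leaves the null model, which has no covariate parameter (p = 0)
  p_cov <- if (is.na(a1)) 0 else 1
  structure(list(
    label = label, alpha0 = unname(a0), alpha1 = unname(a1),
    logLik = ll, logLik_null = ll0,
    aic = 2 * p_cov - 2 * ll,
    r2_nagelkerke = nagelkerke_r2(ll, ll0, n),
    n = n, converged = converged, flag = flag
  ), class = "denovo_fit")
}

# overflow-safe log(1 + exp(x))
log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

null_loglik <- function(d) {
  p <- mean(d)
  sum(d) * log(p) + sum(1 - d) * log(1 - p)
}

# R2 = (1 - exp((2/N)(l0 - l1))) / (1 - exp((2/N) l0)), in log space.
nagelkerke_r2 <- function(ll, ll0, n) {
  num <- 1 - exp((2 / n) * (ll0 - ll))
  den <- 1 - exp((2 / n) * ll0)
  max(0, min(1, num / den))
}

#' @export
print.denovo_fit <- function(x, ...) {
  cat(sprintf("<denovo_fit> %s: n = %s\n", x$label,
              format(x$n, big.mark = ",")))
  cat(sprintf("  alpha0 = %.4f, alpha1 = %s\n", x$alpha0,
              if (is.na(x$alpha1)) "NA" else sprintf("%.4f", x$alpha1)))
  cat(sprintf("  lnL = %.2f, AIC = %.2f, Nagelkerke R2 = %.4f\n",
              x$logLik, x$aic, x$r2_nagelkerke))
  if (!is.null(x$flag)) cat("  flag: ", x$flag, "\n", sep = "")
  invisible(x)
}

#' @export
coef.denovo_fit <- function(object, ...) {
  c(alpha0 = object$alpha0, alpha1 = object$alpha1)
}

#' @export
logLik.denovo_fit <- function(object, ...) {
  structure(object$logLik, df = 2, nobs = object$n, class = "logLik")
}

#' Compare validation models by AIC
#'
#' Ranks fitted validation models by AIC. All fits must be computed on
#' the same number of testing sites: AIC and Nagelkerke R-squared depend
#' on N and are not comparable across differing site sets. A model within
#' 10 AIC units of the best is flagged as comparable to the optimum.
#'
#' @param fits list of `denovo_fit` objects.
#' @return data.frame of class `model_comparison`: `label`, `aic`,
#'   `delta_aic`, `rank`, `r2_nagelkerke`, `comparable`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "denovo_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("fits were computed on differing site counts; AIC not comparable")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  out <- data.frame(
    label = vapply(fits, `[[`, character(1), "label"),
    aic = aic,
    delta_aic = aic - min(aic),
    rank = rank(aic, ties.method = "min"),
    r2_nagelkerke = vapply(fits, `[[`, numeric(1), "r2_nagelkerke")
  )
  out$comparable <- out$delta_aic < 10
  out <- out[order(out$aic), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> ", nrow(x), " model(s), N identical\n", sep = "")
  print.data.frame(cbind(x[, c("label", "rank")],
                         delta_aic = round(x$delta_aic, 1),
                         r2 = round(x$r2_nagelkerke, 4),
                         comparable = x$comparable),
                   row.names = FALSE)
  invisible(x)
}

#' Fit and compare several rate strategies on one testing set
#'
#' Convenience wrapper: builds the testing set (de novo sites labelled
#' d = 1, partitioned background d = 0), annotates the covariate for each
#' strategy (a named list of rate tables), fits each single-covariate
#' model, and compares by AIC. Sites where any strategy's covariate is
#' unavailable are dropped so all models see identical data. Optionally
#' stratifies by the 9 basic types.
#'
#' @param denovo data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param background output of [partition_background()].
#' @param strategies named list of `rate_table`s.
#' @param genome a `genome_seq`.
#' @param by_type also re-fit within each of the 9 basic types.
#' @return list with `fits`, `comparison`, and (if requested) `by_type`,
#'   a per-type list of comparisons.
#' @export
validate_strategies <- function(denovo, background, strategies, genome,
                                by_type = FALSE) {
  stopifnot(length(names(strategies)) == length(strategies))
  denovo$d <- 1L
  cols <- c("chrom", "pos", "ref", "alt", "d")
  sites <- rbind(denovo[, cols], background[, cols])
  sites <- assign_basic_type(sites, genome)
  cov <- sapply(strategies, function(rt)
    annotate_covariate(sites, rt, genome))
  keep <- stats::complete.cases(cov)
  sites <- sites[keep, , drop = FALSE]
  cov <- cov[keep, , drop = FALSE]
  fits <- lapply(names(strategies), function(nm)
    fit_validation_model(sites$d, cov[, nm], label = nm))
  names(fits) <- names(strategies)
  out <- list(fits = fits, comparison = compare_models(fits))
  if (by_type) {
    out$by_type <- lapply(split(seq_len(nrow(sites)), sites$type9),
                          function(idx) {
      if (length(unique(sites$d[idx])) < 2L) return(NULL)
      f <- lapply(names(strategies), function(nm)
        fit_validation_model(sites$d[idx], cov[idx, nm], label = nm))
      compare_models(f)
    })
  }
  out
}
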