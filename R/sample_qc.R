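#' Per-sample 3-mer mutation spectra
#'
#' Computes, for each individual, the vector of 96 3-mer relative mutation
#' rates using only that individual's singletons: per-sample subtype counts
#' divided by genome-wide 3-mer motif counts. Rows follow the sample order
#' given (or sorted unique sample IDs); columns follow the fixed subtype
#' enumeration order, so matrices are comparable across cohorts on the same
#' genome.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`.
#' @param genome a `genome_seq`.
#' @param samples optional character vector fixing the sample set and row
#'   order; variants from samples outside it are an error. Samples with no
#'   singletons get all-zero rows.
#' @return numeric matrix (n_samples x 96) of class `sample_spectra`, with
#'   attribute `motif_count`.
#' @export
per_sample_spectra <- function(variants, genome, samples = NULL) {
  stopifnot("sample_id" %in% names(variants))
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  unknown <- setdiff(unique(variants$sample_id), samples)
  if (length(unknown))
    stop("variants carry unknown sample IDs: ",
         paste(utils::head(unknown), collapse = ", "))
  enum <- enumerate_subtypes(3L)
  mc <- count_motifs(genome, 3L)
  ctx <- contexts_at(genome, variants$chrom, variants$pos, 3L)
  ok <- !is.na(ctx)
  sub <- canonical_subtype(variants$ref[ok], variants$alt[ok], ctx[ok])
  tab <- table(factor(variants$sample_id[ok], levels = samples),
               factor(sub$subtype, levels = enum$subtype))
  spec <- unclass(tab) / rep(mc[enum$motif], each = length(samples))
  dimnames(spec) <- list(samples, enum$subtype)
  structure(spec, motif_count = mc, n_skipped = sum(!ok),
            class = c("sample_spectra", class(spec)))
}

#' Non-negative matrix factorization of sample spectra
#'
#' Factorizes a non-negative matrix `V` (samples x subtypes) as `W %*% H`
#' with `W >= 0` (n x rank, per-sample signature loadings) and `H >= 0`
#' (rank x 96, the signatures), minimizing the Frobenius reconstruction
#' error by hierarchical alternating least squares (HALS): each column of
#' `W` and row of `H` is updated by its exact non-negative
#' coordinate-block minimizer, so the objective is non-increasing across
#' iterations (asserted). The best of `n_restarts` random initializations
#' is kept. Deterministic given `seed`.
#'
#' @param x non-negative matrix (rows = samples), e.g. from
#'   [per_sample_spectra()].
#' @param rank number of signatures (default 3).
#' @param seed integer seed (required; logged in the result).
#' @param n_restarts random restarts (default 5).
#' @param max_iter maximum update sweeps per restart.
#' @param tol convergence tolerance on the relative objective
#'   (iteration stops when the objective falls below `tol` times the
#'   norm of `x`, or stops improving by more than `tol` relatively).
#' @return object of class `nmf_fit`: `W`, `H`, `contributions` (rows of
#'   `W` normalized to proportions), `objective` (final Frobenius norm),
#'   `objective_trace`, `rank`, `seed`, `iterations`, `converged`.
#' @export
nmf_decompose <- function(x, rank = 3L, seed, n_restarts = 5L,
                          max_iter = 20000L, tol = 1e-8) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("matrix must be non-negative")
  if (all(x == 0)) stop("matrix is all zero; nothing to factorize")
  if (missing(seed)) stop("seed is required")
  if (rank < 1L) stop("rank must be >= 1")
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    fit <- nmf_once(x, rank, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  rownames(best$W) <- rownames(x)
  colnames(best$H) <- colnames(x)
  contrib <- best$W / pmax(rowSums(best$W), .Machine$double.eps)
  structure(list(
    W = best$W, H = best$H, contributions = contrib,
    objective = best$objective, objective_trace = best$trace,
    rank = rank, seed = seed, iterations = best$iterations,
    converged = best$converged
  ), class = "nmf_fit")
}

nmf_once <- function(V, rank, max_iter, tol) {
  n <- nrow(V); p <- ncol(V)
  floor_ <- 1e-16
  scale <- sqrt(mean(V) / rank)
  W <- matrix(stats::runif(n * rank, 0, 2 * scale), n, rank)
  H <- matrix(stats::runif(rank * p, 0, 2 * scale), rank, p)
  normV <- sqrt(sum(V^2))
  obj <- sqrt(sum((V - W %*% H)^2))
  trace <- obj
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    VHt <- V %*% t(H); HHt <- tcrossprod(H)
    for (j in seq_len(rank))
      W[, j] <- pmax(floor_, W[, j] +
                       (VHt[, j] - W %*% HHt[, j]) / max(HHt[j, j], floor_))
    WtV <- crossprod(W, V); WtW <- crossprod(W)
    for (j in seq_len(rank))
      H[j, ] <- pmax(floor_, H[j, ] +
                       (WtV[j, ] - WtW[j, ] %*% H) / max(WtW[j, j], floor_))
    new_obj <- sqrt(sum((V - W %*% H)^2))
    # each block update is an exact minimizer: objective cannot increase
    stopifnot(new_obj <= obj * (1 + 1e-9) + 1e-12)
    trace <- c(trace, new_obj)
    if (new_obj <= tol * normV ||
        obj - new_obj <= tol * max(obj, floor_)) {
      obj <- new_obj; converged <- TRUE; break
    }
    obj <- new_obj
  }
  list(W = W, H = H, objective = obj, trace = trace, iterations = it,
       converged = converged)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> rank %d, %d samples x %d features\n",
              x$rank, nrow(x$W), ncol(x$H)))
  cat(sprintf("  Frobenius objective %.4g after %d iteration(s)%s, seed %d\n",
              x$objective, x$iterations,
              if (x$converged) "" else " (not converged)", x$seed))
  invisible(x)
}

#' @export
fitted.nmf_fit <- function(object, ...) object$W %*% object$H

#' Flag outlier samples by signature contribution
#'
#' A sample is flagged when, for at least one signature, its contribution
#' deviates from the cohort mean contribution of that signature by more
#' than `k_sd` standard deviations. Contributions are the row-normalized
#' loadings (proportions) by default; set `normalize = FALSE` to apply the
#' rule to raw loadings. A signature with zero SD across samples flags
#' nobody.
#'
#' @param fit an `nmf_fit`.
#' @param k_sd deviation threshold in SD units (default 2).
#' @param normalize use row-normalized contributions (default TRUE).
#' @return character vector of flagged sample IDs (row names, or row
#'   indices as character), with a `details` attribute giving per-sample,
#'   per-signature deviations in SD units.
#' @export
flag_outliers <- function(fit, k_sd = 2, normalize = TRUE) {
  stopifnot(inherits(fit, "nmf_fit"))
  C <- if (normalize) fit$contributions else fit$W
  mu <- colMeans(C)
  sd_ <- apply(C, 2, stats::sd)
  z <- sweep(sweep(C, 2, mu, "-"), 2, ifelse(sd_ > 0, sd_, Inf), "/")
  flagged <- abs(z) > k_sd
  ids <- rownames(C)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(C)))
  out <- ids[rowSums(flagged) > 0]
  attr(out, "details") <- z
  out
}
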