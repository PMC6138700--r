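# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (no revcomp(), no count_motifs(), no glm()).

oracle_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(oracle_complement[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# position-by-position sliding-window scan with canonical folding
oracle_count_kmers <- function(seq, K) {
  h <- (K - 1L) %/% 2L
  counts <- new.env()
  len <- nchar(seq)
  for (pos in seq_len(len - K + 1L)) {
    w <- substr(seq, pos, pos + K - 1L)
    if (grepl("N", w, fixed = TRUE)) next
    centre <- substr(w, h + 1L, h + 1L)
    if (centre %in% c("G", "T")) w <- oracle_revcomp(w)
    counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

# Newton-Raphson maximizer of the logistic log-likelihood; independent of
# stats::glm.
oracle_logistic <- function(X, y, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - mu))
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  ll <- sum(y * eta - log(1 + exp(eta)))
  list(beta = beta, logLik = ll)
}

# Benjamini-Hochberg step-up from first principles
oracle_bh_flags <- function(p, q) {
  m <- length(p)
  o <- order(p)
  thresh <- seq_len(m) * q / m
  ok <- which(p[o] <= thresh)
  flags <- logical(m)
  if (length(ok)) flags[o[seq_len(max(ok))]] <- TRUE
  flags
}

# Spearman rank correlation via explicit ranks and the Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
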