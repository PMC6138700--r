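#' Reference genome container
#'
#' Holds per-chromosome base strings (alphabet A, C, G, T, N) and an
#' optional accessibility mask. The mask follows BED semantics: 0-based,
#' half-open intervals marking *accessible* positions; when motif counting
#' or rate estimation is run with `use_mask = TRUE`, only windows whose
#' central base falls inside a mask interval are counted.
#'
#' @param seq named character vector of chromosome sequences.
#' @param mask optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or a [GenomicRanges::GRanges].
#' @return an object of class `genome_seq`.
#' @export
genome_seq <- function(seq, mask = NULL) {
  if (is.null(names(seq)) || any(names(seq) == ""))
    stop("chromosome sequences must be named")
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("sequence contains characters outside A,C,G,T,N: ",
         paste(names(seq)[bad], collapse = ", "))
  if (!is.null(mask)) mask <- as_mask_df(mask)
  structure(list(seq = seq, mask = mask),
            class = "genome_seq")
}

as_mask_df <- function(mask) {
  if (methods::is(mask, "GRanges")) {
    mask <- data.frame(chrom = as.character(GenomicRanges::seqnames(mask)),
                       start = GenomicRanges::start(mask) - 1L,
                       end = GenomicRanges::end(mask),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
  mask <- mask[order(mask$chrom, mask$start), c("chrom", "start", "end")]
  if (any(mask$end <= mask$start)) stop("mask intervals must be non-empty")
  mask
}

#' @export
print.genome_seq <- function(x, ...) {
  len <- chrom_lengths(x)
  cat("<genome_seq> ", length(len), " contig(s), ",
      format(sum(len), big.mark = ","), " bp total",
      if (!is.null(x$mask)) sprintf(", mask: %d interval(s)", nrow(x$mask)),
      "\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `genome_seq`.
#' @return named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  vapply(genome$seq, nchar, integer(1))
}

#' Read a genome from FASTA (and optional mask BED)
#'
#' @param fasta path to a FASTA file.
#' @param mask_bed optional path to a BED file of accessible intervals.
#' @return a `genome_seq`.
#' @export
read_genome <- function(fasta, mask_bed = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seq <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  mask <- if (!is.null(mask_bed)) rtracklayer::import(mask_bed, format = "BED")
  genome_seq(seq, mask = mask)
}

#' Write a genome to FASTA
#' @param genome a `genome_seq`.
#' @param path output path.
#' @param mask_path optional path for the mask BED.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, mask_path = NULL) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  if (!is.null(mask_path)) {
    if (is.null(genome$mask)) stop("genome has no mask")
    utils::write.table(genome$mask, mask_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Extract the reference context around a site
#'
#' Returns the K reference bases centered on `pos` (1-based). Windows that
#' run off the chromosome end raise a condition of class
#' `ervrates_edge_error`; windows containing N raise
#' `ervrates_ambiguous_context`. Callers that must skip bad sites catch
#' these classes.
#'
#' @param genome a `genome_seq`.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param K odd window width.
#' @return length-K string.
#' @export
extract_context <- function(genome, chrom, pos, K) {
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  h <- (K - 1L) %/% 2L
  len <- nchar(genome$seq[[chrom]])
  if (pos - h < 1L || pos + h > len)
    stop(errorCondition(
      sprintf("window [%d,%d] off end of %s (length %d)",
              pos - h, pos + h, chrom, len),
      class = c("ervrates_edge_error", "ervrates_error")))
  ctx <- substr(genome$seq[[chrom]], pos - h, pos + h)
  if (grepl("N", ctx, fixed = TRUE))
    stop(errorCondition(
      sprintf("context at %s:%d contains N", chrom, pos),
      class = c("ervrates_ambiguous_context", "ervrates_error")))
  ctx
}

# Vectorized context extraction; returns NA for edge/N windows instead of
# raising, so bulk callers can count skips.
contexts_at <- function(genome, chrom, pos, K) {
  h <- (K - 1L) %/% 2L
  out <- rep(NA_character_, length(pos))
  for (cm in unique(chrom)) {
    idx <- which(chrom == cm)
    s <- genome$seq[[cm]]
    if (is.null(s)) stop("unknown chromosome: ", cm)
    len <- nchar(s)
    ok <- pos[idx] - h >= 1L & pos[idx] + h <= len
    ctx <- rep(NA_character_, length(idx))
    ctx[ok] <- substring(s, pos[idx][ok] - h, pos[idx][ok] + h)
    ctx[!is.na(ctx) & grepl("N", ctx, fixed = TRUE)] <- NA_character_
    out[idx] <- ctx
  }
  out
}

#' Count canonical K-mer motifs in a genome
#'
#' Slides a 1-bp window over every chromosome and counts each K-mer whose
#' window lies within one chromosome and contains no N; counts for a motif
#' and its reverse complement are folded onto the canonical motif (central
#' base A or C). With `use_mask = TRUE`, only windows whose *central* base
#' lies inside an accessibility-mask interval are counted (the flanks may
#' extend beyond the mask).
#'
#' @param genome a `genome_seq`.
#' @param K odd motif width, one of 1, 3, 5, 7.
#' @param use_mask count only windows centered at mask-accessible bases.
#' @return named integer vector over all canonical motifs (zeros included),
#'   in lexicographic motif order.
#' @export
count_motifs <- function(genome, K, use_mask = FALSE) {
  if (!K %in% c(1L, 3L, 5L, 7L)) stop("K must be one of 1, 3, 5, 7")
  K <- as.integer(K)
  h <- (K - 1L) %/% 2L
  raw <- integer(0)  # counts over plain (uncollapsed) K-mers
  add <- function(cnt, x) {
    if (length(x) == 0L) return(cnt)
    if (length(cnt) == 0L) return(x)
    cnt + x
  }
  if (use_mask) {
    if (is.null(genome$mask)) stop("genome has no accessibility mask")
    mk <- genome$mask
    for (cm in unique(mk$chrom)) {
      if (!cm %in% names(genome$seq)) next
      s <- genome$seq[[cm]]
      len <- nchar(s)
      iv <- IRanges::reduce(IRanges::IRanges(
        start = mk$start[mk$chrom == cm] + 1L,
        end = mk$end[mk$chrom == cm]))
      for (j in seq_along(iv)) {
        # centers in [start, end] -> windows live in [start-h, end+h],
        # clipped to the chromosome (clipping drops off-end windows only)
        from <- max(1L, IRanges::start(iv)[j] - h)
        to <- min(len, IRanges::end(iv)[j] + h)
        if (to - from + 1L < K) next
        raw <- add(raw, Biostrings::oligonucleotideFrequency(
          Biostrings::DNAString(substr(s, from, to)), width = K, step = 1L))
      }
    }
  } else {
    for (s in genome$seq) {
      if (nchar(s) < K) next
      raw <- add(raw, Biostrings::oligonucleotideFrequency(
        Biostrings::DNAString(s), width = K, step = 1L))
    }
  }
  motifs <- canonical_motifs(K)
  if (length(raw) == 0L)
    return(stats::setNames(integer(length(motifs)), motifs))
  folded <- raw[motifs] + raw[revcomp(motifs)]
  stats::setNames(as.integer(folded), motifs)
}
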