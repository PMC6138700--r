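#' @importFrom stats setNames
NULL

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement character vectors of DNA
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical mutation subtype of a variant
#'
#' A mutation subtype is the substitution type together with its centered
#' K-mer sequence context, collapsed onto the strand whose central reference
#' base is A or C: a T>G variant in context `x` is the same subtype as the
#' A>C variant in the reverse complement of `x`. All arguments are
#' vectorized and recycled to a common length.
#'
#' @param ref reference base at the central position.
#' @param alt alternative base (must differ from `ref`).
#' @param context odd-length context string centered on the variant site;
#'   its central base must equal `ref`.
#' @return data.frame with columns `motif` (canonical context), `ref`
#'   (canonical central base, A or C), `alt` (canonical alternative),
#'   `type` (e.g. `"C>T"`), `K`, and `subtype` (the `motif:alt` key used
#'   throughout the package).
#' @examples
#' canonical_subtype("G", "A", "TGCGTAT")  # folds to C>T at ATACGCA
#' @export
canonical_subtype <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  K <- unique(nchar(context))
  if (length(K) != 1L || K %% 2L == 0L)
    stop("all contexts must share one odd length")
  if (any(grepl("[^ACGT]", context)))
    stop("ambiguous context: non-ACGT base in context", call. = FALSE)
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("ref and alt must be A, C, G or T")
  if (any(ref == alt)) stop("alt must differ from ref")
  centre <- (K + 1L) %/% 2L
  if (any(substr(context, centre, centre) != ref))
    stop("central base of context must equal ref")
  flip <- ref %in% c("G", "T")
  if (any(flip)) {
    context[flip] <- revcomp(context[flip])
    ref[flip] <- unname(COMPLEMENT[ref[flip]])
    alt[flip] <- unname(COMPLEMENT[alt[flip]])
  }
  data.frame(
    motif = context, ref = ref, alt = alt,
    type = paste0(ref, ">", alt), K = K,
    subtype = paste0(context, ":", alt),
    stringsAsFactors = FALSE
  )
}

#' Enumerate all canonical K-mer mutation subtypes
#'
#' There are 6 basic substitution types (A>C, A>G, A>T, C>A, C>G, C>T after
#' strand collapsing) and 4^(K-1) flanking contexts, hence 6 * 4^(K-1)
#' subtypes: 6, 96, 1536 and 24,576 for K = 1, 3, 5, 7. The order is
#' lexicographic by motif then alternative allele, and is fixed so tables
#' and matrices indexed by subtype are diffable.
#'
#' @param K odd context width, one of 1, 3, 5, 7.
#' @return data.frame with columns `motif`, `ref`, `alt`, `type`, `K`,
#'   `subtype`, one row per subtype.
#' @export
enumerate_subtypes <- function(K) {
  if (length(K) != 1L || !K %in% c(1L, 3L, 5L, 7L))
    stop("K must be one of 1, 3, 5, 7")
  K <- as.integer(K)
  motifs <- canonical_motifs(K)
  centre <- substr(motifs, (K + 1L) %/% 2L, (K + 1L) %/% 2L)
  # three alternatives per motif, already in alphabetical order
  alt <- ifelse(rep(centre, each = 3L) == "A",
                rep(c("C", "G", "T"), length(motifs)),
                rep(c("A", "G", "T"), length(motifs)))
  out <- data.frame(
    motif = rep(motifs, each = 3L),
    ref = rep(centre, each = 3L),
    alt = alt,
    type = paste0(rep(centre, each = 3L), ">", alt),
    K = K,
    subtype = paste0(rep(motifs, each = 3L), ":", alt),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# All canonical K-mer motifs (central base A or C), sorted.
canonical_motifs <- function(K) {
  h <- (K - 1L) %/% 2L
  if (h == 0L) return(c("A", "C"))
  flank <- do.call(expand.grid,
                   c(rep(list(BASES), 2L * h), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE))
  left <- do.call(paste0, flank[, seq_len(h), drop = FALSE])
  right <- do.call(paste0, flank[, h + seq_len(h), drop = FALSE])
  sort(c(paste0(left, "A", right), paste0(left, "C", right)))
}

#' Display form of a subtype key
#'
#' Converts the internal `motif:alt` key (e.g. `"ATACGCA:T"`) to the
#' conventional bracket notation `ATA[C>T]GCA`.
#'
#' @param subtype character vector of subtype keys.
#' @return character vector.
#' @export
format_subtype <- function(subtype) {
  parts <- strsplit(subtype, ":", fixed = TRUE)
  vapply(parts, function(p) {
    K <- nchar(p[[1]])
    h <- (K - 1L) %/% 2L
    centre <- substr(p[[1]], h + 1L, h + 1L)
    if (K == 1L) return(paste0(centre, ">", p[[2]]))
    paste0(substr(p[[1]], 1L, h), "[", centre, ">", p[[2]], "]",
           substr(p[[1]], h + 2L, K))
  }, character(1))
}

# Central (K-2)-mer of each motif, for aggregation across context widths.
shrink_motif <- function(motif) {
  K <- nchar(motif[1])
  substr(motif, 2L, K - 1L)
}
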