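#' Read variants from a VCF file
#'
#' Reads biallelic SNV records into the package's variant data.frame.
#' Sample assignment for singleton sets is carried in the INFO key `SID`
#' and cohort allele count in `AC` (both optional). Requires the vcfR
#' package.
#'
#' @param path path to a VCF (uncompressed or gzipped).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, and where
#'   present `sample_id`, `ac`.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  info <- fix$INFO
  sid <- sub(".*(?:^|;)SID=([^;]*).*", "\\1", info)
  sid[!grepl("(?:^|;)SID=", info)] <- NA
  if (any(!is.na(sid))) out$sample_id <- sid
  ac <- suppressWarnings(as.integer(
    sub(".*(?:^|;)AC=([^;]*).*", "\\1", info)))
  ac[!grepl("(?:^|;)AC=", info)] <- NA
  if (any(!is.na(ac))) out$ac <- ac
  out
}

#' Write variants to a VCF file
#'
#' Writes a minimal sites-only VCF (uncompressed text). `sample_id` and
#' `ac` columns are emitted as INFO keys `SID` and `AC`.
#'
#' @param variants variant data.frame.
#' @param path output path.
#' @param genome optional `genome_seq` for contig header lines.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ervrates",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", names(genome$seq),
              unname(chrom_lengths(genome))),
    "##INFO=<ID=SID,Number=1,Type=String,Description=\"Carrier sample ID\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Cohort allele count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    info <- rep("", nrow(variants))
    if (!is.null(variants$sample_id))
      info <- paste0("SID=", variants$sample_id)
    if (!is.null(variants$ac))
      info <- paste0(info, ifelse(nzchar(info), ";", ""),
                     "AC=", variants$ac)
    info[!nzchar(info)] <- "."
    ord <- order(variants$chrom, variants$pos)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       variants$chrom[ord], variants$pos[ord],
                       variants$ref[ord], variants$alt[ord], info[ord]), con)
  }
  invisible(path)
}

#' Read a de novo mutation set from TSV
#'
#' 4-column TSV: chrom, pos, ref, alt (header optional).
#'
#' @param path file path.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @export
read_denovo_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("chrom", first, ignore.case = TRUE)
  d <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  d <- d[, 1:4]
  names(d) <- c("chrom", "pos", "ref", "alt")
  d$chrom <- as.character(d$chrom)
  d$pos <- as.integer(d$pos)
  d
}
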