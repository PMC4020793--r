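#' Write alignment records as a SAM file
#'
#' Emits a plain-text SAM file with `@SQ` header lines for every contig.
#' Coordinates are written as stored in the records (local, 1-based).
#'
#' @param aln Alignment data.frame as produced by
#'   [emit_oracle_alignments()] or [read_sam()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @param path Output path.
#' @param meta Optional named character vector written as `@CO` comment
#'   lines (e.g. config hash and seed).
#' @return Invisibly, `path`.
#' @export
write_sam <- function(aln, contig_lengths, path, meta = NULL) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)),
              "@PG\tID:tgmap\tPN:tgmap")
  if (!is.null(meta))
    header <- c(header, sprintf("@CO\t%s=%s", names(meta), meta))
  flag <- 1L +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$mate_strand == "-", 32L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                  aln$read_id, flag, aln$contig, aln$pos, aln$mapq, aln$cigar,
                  ifelse(aln$mate_contig == aln$contig, "=", aln$mate_contig),
                  aln$mate_pos, aln$seq, strrep("I", nchar(aln$seq)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Uses Rsamtools (SAM -> BAM conversion, then `scanBam`) so that any
#' spec-conforming SAM, including externally aligned data, can enter the
#' pipeline. Secondary/supplementary and unmapped records are dropped.
#'
#' @param path Path to a SAM (or BAM) file with `@SQ` header lines.
#' @return A list with `alignments` (data.frame in the package's record
#'   layout) and `contig_lengths` (named integer vector from the header).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  lens <- hdr$targets
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "strand", "seq"),
    flag = flags)
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  cig <- parse_cigar(b$cigar)
  aln <- data.frame(
    read_id = b$qname,
    mate = ifelse(bitwAnd(b$flag, 64L) > 0L, 1L, 2L),
    contig = as.character(b$rname),
    pos = b$pos,
    end = b$pos + cig$ref_span - 1L,
    strand = as.character(b$strand),
    mapq = b$mapq,
    cigar = b$cigar,
    lclip = cig$lclip,
    rclip = cig$rclip,
    aligned_span = cig$ref_span,
    seq = as.character(b$seq),
    mapped = TRUE,
    mate_contig = as.character(b$mrnm),
    mate_pos = b$mpos,
    mate_strand = ifelse(bitwAnd(b$flag, 32L) > 0L, "-", "+"),
    mate_mapped = bitwAnd(b$flag, 8L) == 0L,
    stringsAsFactors = FALSE)
  aln <- aln[order(aln$read_id, aln$mate), , drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln, contig_lengths = lens)
}
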