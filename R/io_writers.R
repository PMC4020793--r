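# Plain-text report writers. All genomic intervals are written 1-based
# inclusive except BED/bedGraph, which are converted to 0-based half-open
# here, at the writer layer only.

meta_lines <- function(meta, prefix = "#tgmap") {
  if (is.null(meta)) return(character(0))
  sprintf("%s %s=%s", prefix, names(meta), meta)
}

#' Write a data frame as TSV with provenance comment lines
#'
#' @param df Data frame.
#' @param path Output path.
#' @param meta Optional named character vector written as `#tgmap key=value`
#'   comment lines before the header.
#' @return Invisibly, `path`.
#' @export
write_tgmap_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_lines(meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df Data frame with columns contig, start, end (1-based inclusive)
#'   and optionally name.
#' @inheritParams write_tgmap_tsv
#' @export
write_bed <- function(df, path, meta = NULL) {
  name <- if ("name" %in% names(df)) df$name else "."
  lines <- sprintf("%s\t%d\t%d\t%s", df$contig, df$start - 1L, df$end, name)
  writeLines(c(meta_lines(meta), lines), path)
  invisible(path)
}

#' Write a depth profile as bedGraph
#'
#' @param profile A `depth_profile`.
#' @inheritParams write_tgmap_tsv
#' @export
write_bedgraph <- function(profile, path, meta = NULL) {
  b <- profile$bins
  lines <- sprintf("%s\t%d\t%d\t%.4f", b$contig, b$start - 1L, b$end, b$depth)
  writeLines(c(meta_lines(meta),
               "track type=bedGraph name=tgmap_depth", lines), path)
  invisible(path)
}

#' Write an insertion call as VCF breakend records
#'
#' Emits a minimal VCF 4.2 with one BND record per boundary (HOMLEN/HOMSEQ
#' style microhomology annotation, split-read and discordant-pair support)
#' and the deleted host interval as a DEL record.
#'
#' @param call An `insertion_call` (frame coordinates).
#' @param contig_lengths Named lengths for `##contig` lines (optional).
#' @param path Output path.
#' @param meta Optional named character vector written as `##tgmap_...`
#'   header lines.
#' @export
write_insertion_vcf <- function(call, path, contig_lengths = NULL,
                                meta = NULL) {
  stopifnot(inherits(call, "insertion_call"))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##tgmap_%s=%s", names(meta), meta),
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
           "##INFO=<ID=PARTNER,Number=1,Type=String,Description=\"Partner cassette\">",
           "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
           "##INFO=<ID=HOMSEQ,Number=1,Type=String,Description=\"Microhomology sequence\">",
           "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Soft-clip support\">",
           "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Discordant pair support\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of deleted interval\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length (coordinate difference)\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  bnd <- function(b, id, mate, mh) {
    alt <- if (b$side == "left")
      sprintf("N[%s:1[", ifelse(is.na(b$partner_cassette), "unknown",
                                b$partner_cassette))
    else sprintf("]%s:1]N", ifelse(is.na(b$partner_cassette), "unknown",
                                   b$partner_cassette))
    info <- sprintf("SVTYPE=BND;MATEID=%s;PARTNER=%s;HOMLEN=%s;HOMSEQ=%s;SR=%d;PE=%s",
                    mate, ifelse(is.na(b$partner_cassette), ".",
                                 b$partner_cassette),
                    ifelse(is.na(mh$length), ".", mh$length),
                    ifelse(nzchar(mh$seq), mh$seq, "."), b$n_softclip,
                    ifelse(is.na(b$n_discordant), ".", b$n_discordant))
    sprintf("%s\t%d\t%s\tN\t%s\t.\t%s\t%s", b$contig, b$coordinate, id, alt,
            ifelse(b$status == "exact", "PASS", "IMPRECISE"), info)
  }
  rec <- c(bnd(call$left, "tgmap_bnd_L", "tgmap_bnd_R",
               call$left_microhomology),
           bnd(call$right, "tgmap_bnd_R", "tgmap_bnd_L",
               call$right_microhomology),
           sprintf("%s\t%d\ttgmap_del\tN\t<DEL>\t.\t%s\tSVTYPE=DEL;END=%d;SVLEN=%d",
                   call$contig, call$left$coordinate,
                   ifelse(call$status == "exact", "PASS", "IMPRECISE"),
                   call$right$coordinate - 1L, -call$deletion_length))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
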