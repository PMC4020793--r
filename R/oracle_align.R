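#' Emit oracle alignments for simulated reads
#'
#' Produces the alignment records a local-mode aligner would emit, using the
#' truth tags instead of running an aligner: reads wholly inside a flank map
#' to the insertion contig; reads wholly inside the array map to the donor
#' contig of their cassette (all tandem copies collapse onto the single
#' reference unit, so these alignments are unique and get mapq 60); reads
#' spanning a junction are aligned to the side holding the longer match and
#' soft-clipped on the other side, with the clip placed exactly at the true
#' junction coordinate. Reads spanning a same-cassette unit-unit junction
#' admit two equally good local placements on the donor contig and get
#' mapq 0. Pairs whose mates land on different contigs thereby become
#' inter-chromosomal discordant pairs.
#'
#' @param genome A `sim_genome`.
#' @param sim A `sim_reads` object simulated from `genome`.
#' @return A data.frame of alignment records (two rows per pair): read_id,
#'   mate, contig, pos, end, strand, mapq, cigar, lclip, rclip,
#'   aligned_span, seq, mate_contig, mate_pos, mate_strand, mapped,
#'   mate_mapped.
#' @export
emit_oracle_alignments <- function(genome, sim) {
  stopifnot(inherits(genome, "sim_genome"), inherits(sim, "sim_reads"))
  tr <- sim$truth
  rl <- sim$params$read_length
  n <- nrow(tr)
  mates <- data.frame(
    read_id = rep(tr$read_id, 2L),
    mate = rep(c(1L, 2L), each = n),
    kind = rep(tr$kind, 2L),
    s = c(tr$frag_start, tr$frag_end - rl + 1L),
    e = c(tr$frag_start + rl - 1L, tr$frag_end),
    allele_strand = rep(c("+", "-"), each = n),
    fwd_seq = c(sim$reads$seq1, revcomp(sim$reads$seq2)),
    stringsAsFactors = FALSE)

  m <- nrow(mates)
  contig <- character(m); pos <- integer(m); strand <- character(m)
  mapq <- rep(60L, m); lclip <- integer(m); rclip <- integer(m)
  span <- rep(as.integer(rl), m); seq_out <- mates$fwd_seq

  direct <- mates$kind != "tg"
  if (any(direct)) {
    contig[direct] <- ifelse(mates$kind[direct] == "wt",
                             genome$truth$insertion_contig, mates$kind[direct])
    pos[direct] <- mates$s[direct]
    strand[direct] <- mates$allele_strand[direct]
  }

  tgi <- which(!direct)
  if (length(tgi)) {
    segs <- genome$segments
    idx <- findInterval(mates$s[tgi], segs$a_start)
    inside <- mates$e[tgi] <= segs$a_end[idx]

    # reads wholly inside one segment (vectorised)
    si <- tgi[inside]; sx <- idx[inside]
    fwd <- segs$strand[sx] == "+"
    contig[si] <- segs$contig[sx]
    pos[si] <- as.integer(
      ifelse(fwd, segs$r_start[sx] + (mates$s[si] - segs$a_start[sx]),
             segs$r_start[sx] + (segs$a_end[sx] - mates$e[si])))
    strand[si] <- ifelse(fwd, mates$allele_strand[si],
                         ifelse(mates$allele_strand[si] == "+", "-", "+"))
    if (any(!fwd)) seq_out[si[!fwd]] <- revcomp(mates$fwd_seq[si[!fwd]])

    # junction-spanning reads (few): align the longer side, clip the rest
    for (j in tgi[!inside]) {
      s <- mates$s[j]; e <- mates$e[j]
      ov_idx <- which(segs$a_start <= e & segs$a_end >= s)
      ov <- pmin(e, segs$a_end[ov_idx]) - pmax(s, segs$a_start[ov_idx]) + 1L
      k <- ov_idx[which.max(ov)]
      as2 <- max(s, segs$a_start[k]); ae2 <- min(e, segs$a_end[k])
      lc_a <- as2 - s; rc_a <- e - ae2
      contig[j] <- segs$contig[k]
      span[j] <- ae2 - as2 + 1L
      if (segs$strand[k] == "+") {
        pos[j] <- segs$r_start[k] + (as2 - segs$a_start[k])
        strand[j] <- mates$allele_strand[j]
        lclip[j] <- lc_a; rclip[j] <- rc_a
      } else {
        pos[j] <- segs$r_start[k] + (segs$a_end[k] - ae2)
        strand[j] <- if (mates$allele_strand[j] == "+") "-" else "+"
        lclip[j] <- rc_a; rclip[j] <- lc_a
        seq_out[j] <- revcomp(mates$fwd_seq[j])
      }
      ids <- unique(segs$cassette_id[ov_idx])
      if (all(segs$type[ov_idx] == "unit") && length(ids) == 1 &&
          genome$truth$copies[[ids]] > 1) {
        mapq[j] <- 0L
      }
    }
  }

  cigar <- paste0(ifelse(lclip > 0, paste0(lclip, "S"), ""), span, "M",
                  ifelse(rclip > 0, paste0(rclip, "S"), ""))
  aln <- data.frame(
    read_id = mates$read_id, mate = mates$mate, contig = contig,
    pos = as.integer(pos), end = as.integer(pos + span - 1L),
    strand = strand, mapq = mapq, cigar = cigar,
    lclip = as.integer(lclip), rclip = as.integer(rclip),
    aligned_span = as.integer(span), seq = seq_out,
    mapped = TRUE, stringsAsFactors = FALSE)

  # attach mate info
  key <- paste(aln$read_id, 3L - aln$mate)
  self <- paste(aln$read_id, aln$mate)
  mt <- match(key, self)
  aln$mate_contig <- aln$contig[mt]
  aln$mate_pos <- aln$pos[mt]
  aln$mate_strand <- aln$strand[mt]
  aln$mate_mapped <- TRUE
  aln[order(aln$read_id, aln$mate), , drop = FALSE]
}
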