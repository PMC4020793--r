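#' Build reference contigs and transgenic/wild-type alleles from a locus spec
#'
#' Materialises the world described by a [locus_spec()]: a wild-type insertion
#' contig (the reference surrogate of the host chromosome), one donor contig
#' per cassette (pad + one forward-orientation unit copy + pad, the reference
#' surrogate of the endogenous locus the transgene derives from), and the two
#' sample alleles. The transgenic allele is
#' `leftFlank(1..left) + array + rightFlank(right..end)` where the tandem
#' array is expanded per multiplicities/orientations and each duplicated
#' boundary sequence is present once physically (carried by the flank copy;
#' the array is trimmed of its duplicated prefix/suffix), so that alignments
#' are ambiguous over the duplicated span exactly as at a real
#' microhomology-flanked junction.
#'
#' @param spec A [locus_spec()].
#' @param seed Integer seed used to generate flank/pad sequence (default 8).
#' @param donor_pad Pad length (bp) on each side of the unit on donor contigs.
#' @return An object of class `sim_genome`: list with `reference_contigs`
#'   (named character), `transgenic_allele`, `wildtype_allele`,
#'   `cassette_loci` (unit intervals on donor contigs), `segments` (the
#'   transgenic-allele-to-reference segment map used by the oracle aligner)
#'   and `truth` (spec plus derived local/frame junction coordinates).
#' @export
build_alleles <- function(spec, seed = 8L, donor_pad = 2000L) {
  stopifnot(inherits(spec, "locus_spec"))
  set.seed(as.integer(seed))
  ldup <- nchar(spec$left_dup_seq)
  rdup <- nchar(spec$right_dup_seq)
  fl <- spec$flank_length
  del_len <- spec$right_boundary - spec$left_boundary - 1L # bases removed
  bl <- fl                      # local coordinate of last retained left base
  br <- fl + del_len + 1L       # local coordinate of first retained right base
  wlen <- 2L * fl + del_len

  # wild-type insertion contig, with duplicated motifs forced into the flanks
  W <- random_dna(wlen)
  if (ldup > 0) substr(W, bl - ldup + 1L, bl) <- spec$left_dup_seq
  if (rdup > 0) substr(W, br, br + rdup - 1L) <- spec$right_dup_seq

  # expand the cassette array
  units <- spec$cassette_units
  expansion <- list()  # one element per physical unit copy
  for (i in seq_len(nrow(units))) {
    id <- units$cassette_id[i]
    n <- spec$array_multiplicities[[id]]
    if (n == 0) next
    oseq <- if (units$orientation[i] == "+") units$seq[i] else revcomp(units$seq[i])
    for (k in seq_len(n)) {
      expansion[[length(expansion) + 1L]] <- list(
        cassette_id = id, seq = oseq, orientation = units$orientation[i],
        copy_index = k)
    }
  }

  if (length(expansion) > 0) {
    A <- paste(vapply(expansion, `[[`, "", "seq"), collapse = "")
    if (ldup > 0 && substr(A, 1L, ldup) != spec$left_dup_seq)
      stop("left duplicated sequence is not a prefix of the first cassette ",
           "unit (left side inconsistent)", call. = FALSE)
    if (rdup > 0 && substr(A, nchar(A) - rdup + 1L, nchar(A)) != spec$right_dup_seq)
      stop("right duplicated sequence is not a suffix of the last cassette ",
           "unit (right side inconsistent)", call. = FALSE)
    A_trim <- substr(A, ldup + 1L, nchar(A) - rdup)
  } else {
    if (ldup > 0 || rdup > 0)
      stop("duplicated boundary sequences require a non-empty cassette array",
           call. = FALSE)
    A <- ""; A_trim <- ""
  }
  tg <- paste0(substr(W, 1L, bl), A_trim, substr(W, br, wlen))

  # donor contigs (reference carries one forward-orientation unit copy)
  donor_pad <- as.integer(donor_pad)
  contigs <- stats::setNames(list(W), spec$insertion_chrom_name)
  loci <- data.frame(cassette_id = character(0), contig = character(0),
                     start = integer(0), end = integer(0),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(units))) {
    id <- units$cassette_id[i]
    dn <- paste0("donor_", id)
    contigs[[dn]] <- paste0(random_dna(donor_pad), units$seq[i],
                            random_dna(donor_pad))
    loci <- rbind(loci, data.frame(
      cassette_id = id, contig = dn, start = donor_pad + 1L,
      end = donor_pad + nchar(units$seq[i]), stringsAsFactors = FALSE))
  }

  # segment map: transgenic-allele intervals -> reference intervals.
  segs <- data.frame(a_start = integer(0), a_end = integer(0),
                     contig = character(0), r_start = integer(0),
                     r_end = integer(0), strand = character(0),
                     type = character(0), cassette_id = character(0),
                     stringsAsFactors = FALSE)
  add_seg <- function(a1, a2, contig, r1, r2, strand, type, id = NA_character_) {
    rbind(segs, data.frame(a_start = a1, a_end = a2, contig = contig,
                           r_start = r1, r_end = r2, strand = strand,
                           type = type, cassette_id = id,
                           stringsAsFactors = FALSE))
  }
  segs <- add_seg(1L, bl, spec$insertion_chrom_name, 1L, bl, "+", "flank_left")
  if (length(expansion) > 0) {
    a_cursor <- 0L  # cumulative position within untrimmed array A
    total <- nchar(A)
    for (e in expansion) {
      u <- nchar(e$seq)
      a1 <- a_cursor + 1L; a2 <- a_cursor + u  # copy occupies A[a1..a2]
      b1 <- max(a1, ldup + 1L)                 # clip trimmed dup ends
      b2 <- min(a2, total - rdup)
      a_cursor <- a2
      if (b1 > b2) next
      # oriented positions within this unit copy
      o1 <- b1 - a1 + 1L; o2 <- b2 - a1 + 1L
      lrow <- loci[loci$cassette_id == e$cassette_id, ]
      if (e$orientation == "+") {
        r1 <- lrow$start + o1 - 1L; r2 <- lrow$start + o2 - 1L; strand <- "+"
      } else {
        r1 <- lrow$end - o2 + 1L; r2 <- lrow$end - o1 + 1L; strand <- "-"
      }
      segs <- add_seg(bl + (b1 - ldup), bl + (b2 - ldup), lrow$contig,
                      r1, r2, strand, "unit", e$cassette_id)
    }
  }
  tail_start <- bl + nchar(A_trim) + 1L
  segs <- add_seg(tail_start, nchar(tg), spec$insertion_chrom_name,
                  br, wlen, "+", "flank_right")

  copies <- vapply(split(vapply(expansion, `[[`, "", "cassette_id"),
                         vapply(expansion, `[[`, "", "cassette_id")),
                   length, 1L)
  truth <- list(
    spec = spec,
    insertion_contig = spec$insertion_chrom_name,
    coordinate_offset = spec$coordinate_offset,
    left_local = bl, right_local = br,
    left_frame = bl + spec$coordinate_offset,
    right_frame = br + spec$coordinate_offset,
    deletion_length = spec$right_boundary - spec$left_boundary,
    left_dup_seq = spec$left_dup_seq, right_dup_seq = spec$right_dup_seq,
    left_partner = if (length(expansion)) expansion[[1]]$cassette_id else NA,
    right_partner = if (length(expansion))
      expansion[[length(expansion)]]$cassette_id else NA,
    copies = copies)

  structure(list(
    reference_contigs = vapply(contigs, identity, ""),
    transgenic_allele = tg,
    wildtype_allele = W,
    cassette_loci = loci,
    segments = segs,
    truth = truth
  ), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("Simulated transgenic genome\n")
  cat(sprintf("  reference contigs: %s\n",
              paste(sprintf("%s (%d bp)", names(x$reference_contigs),
                            nchar(x$reference_contigs)), collapse = ", ")))
  cat(sprintf("  alleles: transgenic %d bp, wild-type %d bp\n",
              nchar(x$transgenic_allele), nchar(x$wildtype_allele)))
  cat(sprintf("  true junctions (frame): left %d, right %d (deletion %d bp)\n",
              x$truth$left_frame, x$truth$right_frame,
              x$truth$deletion_length))
  invisible(x)
}

#' Contig lengths of a simulated genome
#' @param genome A `sim_genome`.
#' @return Named integer vector of reference contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  vapply(genome$reference_contigs, nchar, 1L)
}

#' Cassette sequences oriented as they sit at the array junctions
#'
#' Returns, for each cassette, the unit sequence in the orientation it takes
#' inside the array (used for partner matching and microhomology).
#' @param genome A `sim_genome`.
#' @return Named character vector, cassette_id -> oriented unit sequence.
#' @export
cassette_seqs <- function(genome) {
  stopifnot(inherits(genome, "sim_genome"))
  u <- genome$truth$spec$cassette_units
  s <- ifelse(u$orientation == "+", u$seq, revcomp(u$seq))
  stats::setNames(s, u$cassette_id)
}
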