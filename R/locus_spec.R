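#' Describe a synthetic transgenic locus
#'
#' A `locus_spec` is the ground-truth description of a transgene integration
#' event: a host chromosome surrogate in which the sequence between
#' `left_boundary` (last retained base of the left flank) and `right_boundary`
#' (first retained base of the right flank) is replaced by a tandem array of
#' transgene cassette units. Short sequences are duplicated at the boundaries:
#' `left_dup_seq` is simultaneously a suffix of the retained left flank and a
#' prefix of the first cassette unit; `right_dup_seq` is a suffix of the last
#' cassette unit and a prefix of the retained right flank. Physically each
#' duplicated sequence is present once at the junction; the "duplication" is
#' an alignment ambiguity (microhomology) that breakpoint resolution must
#' handle.
#'
#' Coordinates are 1-based inclusive. Positions are reported in an offset
#' frame (`coordinate_offset + local position`) so a small simulated window
#' can report positions matching a real chromosome, e.g. mouse chr2. The
#' deletion length is defined as `right_boundary - left_boundary` (the
#' coordinate difference, not the inclusive base count, which is one less);
#' see the methods vignette.
#'
#' @param insertion_chrom_name Name of the host (insertion) contig surrogate.
#' @param left_boundary,right_boundary 1-based boundary coordinates in the
#'   offset frame; `right_boundary > left_boundary`.
#' @param left_dup_seq,right_dup_seq Duplicated boundary sequences (may be
#'   `""` when the cassette array is empty).
#' @param cassette_units `data.frame` with columns `cassette_id`, `seq`,
#'   `orientation` (`"+"` forward or `"-"` reverse), one row per distinct
#'   cassette, in the order their blocks appear in the array.
#' @param array_multiplicities Named integer vector, `cassette_id` -> tandem
#'   copy count (>= 0).
#' @param endogenous_copies Named 0/1 vector: whether the sampled genome also
#'   carries a divergence-free endogenous copy of each cassette donor contig.
#'   Defaults to 0 for all cassettes.
#' @param flank_length Length (bp) of each retained flank on the insertion
#'   contig.
#' @param coordinate_offset Offset such that local position + offset equals
#'   the reported coordinate. Computed as `left_boundary - flank_length`
#'   when not supplied.
#' @return An object of class `locus_spec`.
#' @seealso [simulate_locus_spec()] for a seeded generator with the default
#'   (paper-frame) geometry, and [build_alleles()] to materialise sequences.
#' @export
locus_spec <- function(insertion_chrom_name = "chr2",
                       left_boundary = 68208872L,
                       right_boundary = 68209029L,
                       left_dup_seq = "CCAGCAG",
                       right_dup_seq = "TGGAT",
                       cassette_units,
                       array_multiplicities,
                       endogenous_copies = NULL,
                       flank_length = 12000L,
                       coordinate_offset = NULL) {
  left_boundary <- as.integer(left_boundary)
  right_boundary <- as.integer(right_boundary)
  flank_length <- as.integer(flank_length)
  if (right_boundary <= left_boundary)
    stop("right_boundary must be greater than left_boundary", call. = FALSE)
  if (flank_length < 1) stop("flank_length must be positive", call. = FALSE)
  check_dna(left_dup_seq, "left_dup_seq")
  check_dna(right_dup_seq, "right_dup_seq")
  if (!is.data.frame(cassette_units) ||
      !all(c("cassette_id", "seq", "orientation") %in% names(cassette_units)))
    stop("cassette_units must be a data.frame with columns ",
         "cassette_id, seq, orientation", call. = FALSE)
  for (s in cassette_units$seq) check_dna(s, "cassette unit sequence")
  if (!all(cassette_units$orientation %in% c("+", "-")))
    stop("cassette orientations must be '+' or '-'", call. = FALSE)
  if (is.null(names(array_multiplicities)) ||
      !all(cassette_units$cassette_id %in% names(array_multiplicities)))
    stop("array_multiplicities must be named by cassette_id", call. = FALSE)
  if (any(array_multiplicities < 0))
    stop("array multiplicities must be >= 0", call. = FALSE)
  if (is.null(endogenous_copies)) {
    endogenous_copies <- stats::setNames(
      integer(nrow(cassette_units)), cassette_units$cassette_id)
  }
  if (!all(endogenous_copies %in% c(0L, 1L)))
    stop("endogenous_copies entries must be 0 or 1", call. = FALSE)
  if (is.null(coordinate_offset))
    coordinate_offset <- left_boundary - flank_length
  coordinate_offset <- as.integer(coordinate_offset)
  if (left_boundary - coordinate_offset != flank_length)
    stop("coordinate_offset inconsistent: left_boundary - coordinate_offset ",
         "must equal flank_length", call. = FALSE)
  structure(list(
    insertion_chrom_name = insertion_chrom_name,
    coordinate_offset = coordinate_offset,
    left_boundary = left_boundary,
    right_boundary = right_boundary,
    left_dup_seq = left_dup_seq,
    right_dup_seq = right_dup_seq,
    cassette_units = cassette_units,
    array_multiplicities = array_multiplicities,
    endogenous_copies = endogenous_copies,
    flank_length = flank_length
  ), class = "locus_spec")
}

#' Generate a seeded default transgenic locus
#'
#' Builds a `locus_spec` with the default geometry used throughout the
#' package: boundary coordinates in the mouse chr2 frame
#' (68,208,872 / 68,209,029, i.e. a 157-bp deletion by coordinate
#' difference), a tandem array of `beta_copies` beta cassette units followed
#' by `alpha_copies` alpha units, a 7-bp CCAGCAG duplicated sequence at the
#' left boundary (shared with the beta cassette start) and a 5-bp TGGAT
#' duplicated sequence at the right boundary (shared with the alpha cassette
#' end). Unit sequences are random DNA with the duplicated motifs embedded.
#'
#' @param seed Integer seed for unit-sequence generation (default 8).
#' @param alpha_copies,beta_copies Tandem multiplicities (defaults 16 and 4).
#' @param alpha_length,beta_length Unit lengths in bp (defaults 2000 and
#'   4000; the beta unit, which carries the junction the genotyping assay
#'   reads out, is kept above the 3-kb amplifiable window so tandem-ladder
#'   PCR products are out of range, as with real vector-scale cassettes).
#' @param flank_length Retained flank length per side (default 12000 bp).
#' @param endogenous_copies Named 0/1 vector (default: no endogenous copies).
#' @inheritParams locus_spec
#' @return A `locus_spec`.
#' @export
simulate_locus_spec <- function(seed = 8L,
                                alpha_copies = 16L, beta_copies = 4L,
                                alpha_length = 2000L, beta_length = 4000L,
                                flank_length = 12000L,
                                left_boundary = 68208872L,
                                right_boundary = 68209029L,
                                left_dup_seq = "CCAGCAG",
                                right_dup_seq = "TGGAT",
                                endogenous_copies = NULL) {
  set.seed(as.integer(seed))
  ldup <- nchar(left_dup_seq); rdup <- nchar(right_dup_seq)
  if (beta_length <= ldup || alpha_length <= rdup)
    stop("cassette units must be longer than the duplicated sequences",
         call. = FALSE)
  beta_seq <- paste0(left_dup_seq, random_dna(beta_length - ldup))
  alpha_seq <- paste0(random_dna(alpha_length - rdup), right_dup_seq)
  units <- data.frame(
    cassette_id = c("beta", "alpha"),
    seq = c(beta_seq, alpha_seq),
    orientation = c("+", "+"),
    stringsAsFactors = FALSE)
  locus_spec(
    left_boundary = left_boundary, right_boundary = right_boundary,
    left_dup_seq = left_dup_seq, right_dup_seq = right_dup_seq,
    cassette_units = units,
    array_multiplicities = c(beta = as.integer(beta_copies),
                             alpha = as.integer(alpha_copies)),
    endogenous_copies = endogenous_copies,
    flank_length = flank_length)
}

#' @export
print.locus_spec <- function(x, ...) {
  cat("Transgenic locus specification\n")
  cat(sprintf("  insertion contig: %s (offset frame +%d)\n",
              x$insertion_chrom_name, x$coordinate_offset))
  cat(sprintf("  boundaries: %d / %d  (deletion length %d bp)\n",
              x$left_boundary, x$right_boundary,
              x$right_boundary - x$left_boundary))
  cat(sprintf("  boundary duplications: left %s (%d bp), right %s (%d bp)\n",
              x$left_dup_seq, nchar(x$left_dup_seq),
              x$right_dup_seq, nchar(x$right_dup_seq)))
  m <- x$array_multiplicities[x$cassette_units$cassette_id]
  cat(sprintf("  array: %s\n",
              paste(sprintf("%s x%d (%d bp, %s)", x$cassette_units$cassette_id,
                            m, nchar(x$cassette_units$seq),
                            x$cassette_units$orientation), collapse = ", ")))
  cat(sprintf("  flanks: %d bp each side\n", x$flank_length))
  invisible(x)
}
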