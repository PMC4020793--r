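# Breakpoint resolution from soft-clip consensus.

# Per-column majority consensus (>= 50% of covering reads), truncated at the
# first dissenting column. `anchor = "left"` aligns sequences at their first
# base (clips that follow an alignment); `anchor = "right"` at their last
# base (clips that precede an alignment).
clip_consensus <- function(seqs, anchor = c("left", "right")) {
  anchor <- match.arg(anchor)
  if (length(seqs) == 0) return("")
  if (anchor == "right")
    seqs <- vapply(lapply(strsplit(seqs, ""), rev), paste, "", collapse = "")
  chars <- strsplit(seqs, "")
  maxlen <- max(nchar(seqs))
  out <- character(0)
  for (j in seq_len(maxlen)) {
    col <- unlist(lapply(chars, function(x) if (length(x) >= j) x[j]))
    if (length(col) == 0) break
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / length(col) < 0.5) break
    # strict majority required on ties
    if (length(tab) > 1 && tab[1] == tab[2]) break
    out <- c(out, names(tab)[1])
  }
  cons <- paste(out, collapse = "")
  if (anchor == "right")
    cons <- paste(rev(strsplit(cons, "")[[1]]), collapse = "")
  cons
}

n_mismatch <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Best placement of a junction consensus against a cassette end, allowing a
# shift of up to max_shift bp (the shift absorbs the duplicated/microhomology
# span). For a left boundary the consensus continues INTO the cassette, so it
# is matched against the cassette 5' region; for a right boundary it ends the
# cassette, so it is matched against the 3' region (shift measured from the
# end). Returns list(mismatches, shift, length) or NULL.
match_cassette_end <- function(consensus, cass_seq, side, max_shift = 50L) {
  L <- nchar(consensus)
  if (L == 0 || nchar(cass_seq) < L) return(NULL)
  best <- NULL
  for (off in 0:min(max_shift, nchar(cass_seq) - L)) {
    cand <- if (side == "left") substr(cass_seq, off + 1L, off + L)
    else substr(cass_seq, nchar(cass_seq) - off - L + 1L,
                nchar(cass_seq) - off)
    mm <- n_mismatch(consensus, cand)
    if (is.null(best) || mm < best$mismatches)
      best <- list(mismatches = mm, shift = off, length = L)
    if (mm == 0) break
  }
  best
}

#' Resolve an insertion boundary from soft-clip evidence
#'
#' The boundary coordinate is the mode of the clip boundary positions (ties
#' towards the smaller coordinate). For a left boundary the evidence is
#' right-side clips and the coordinate is the last retained flank base; for
#' a right boundary it is left-side clips and the coordinate is the first
#' retained flank base (one past the stored `boundary_pos`, which records
#' the last aligned base). The clipped sequences at the modal position are
#' collapsed into a majority consensus, which is matched against the
#' junction-proximal ends of the candidate cassette sequences: the cassette
#' with the fewest mismatches (below 10% of the consensus length) becomes
#' the partner, and the placement shift estimates the duplicated-sequence
#' (microhomology) span. With no clip evidence the call falls back to the
#' midpoint of the discordant-pair interval and is flagged `approximate`.
#'
#' @param clips Clip-event data.frame ([extract_clips()]), already windowed
#'   to the candidate region; the relevant clip side is selected internally.
#' @param side `"left"` or `"right"` boundary.
#' @param cassettes Optional named character vector of cassette sequences
#'   oriented as they sit at the junction (see [cassette_seqs()]).
#' @param fallback_interval Optional `c(start, end)` used when no clips are
#'   available.
#' @param contig Contig of the boundary (required with `fallback_interval`;
#'   otherwise taken from the clips).
#' @param max_shift Maximum duplicated-sequence span searched (default 50).
#' @return An object of class `boundary_call`.
#' @export
resolve_boundary <- function(clips, side = c("left", "right"),
                             cassettes = NULL, fallback_interval = NULL,
                             contig = NULL, max_shift = 50L) {
  side <- match.arg(side)
  clip_side <- if (side == "left") "right" else "left"
  ev <- clips[clips$side == clip_side, , drop = FALSE]
  if (nrow(ev) == 0) {
    if (is.null(fallback_interval) || is.null(contig))
      stop("no soft-clip evidence and no fallback interval for the ", side,
           " boundary", call. = FALSE)
    return(structure(list(
      contig = contig, coordinate = as.integer(round(mean(fallback_interval))),
      side = side, partner_cassette = NA_character_, n_discordant = NA_integer_,
      n_softclip = 0L, clip_consensus = "", status = "approximate",
      mh_shift = NA_integer_), class = "boundary_call"))
  }
  bp <- stat_mode(ev$boundary_pos)
  at <- ev[ev$boundary_pos == bp, , drop = FALSE]
  coordinate <- if (side == "left") bp else bp + 1L
  cons <- clip_consensus(at$clipped_seq,
                         anchor = if (side == "left") "left" else "right")
  partner <- NA_character_; status <- "exact"; shift <- NA_integer_
  if (!is.null(cassettes) && nchar(cons) > 0) {
    cand <- c(cassettes, stats::setNames(revcomp(cassettes),
                                         paste0(names(cassettes), "_rc")))
    hits <- lapply(cand, match_cassette_end, consensus = cons, side = side,
                   max_shift = max_shift)
    mm <- vapply(hits, function(h) if (is.null(h)) Inf else h$mismatches, 1)
    k <- which.min(mm)
    if (is.finite(mm[k]) && mm[k] < 0.1 * nchar(cons)) {
      partner <- sub("_rc$", "", names(cand)[k])
      shift <- hits[[k]]$shift
    } else {
      status <- "approximate"
    }
  }
  structure(list(
    contig = at$contig[1], coordinate = as.integer(coordinate), side = side,
    partner_cassette = partner, n_discordant = NA_integer_,
    n_softclip = nrow(at), clip_consensus = cons, status = status,
    mh_shift = shift), class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat(sprintf("%s boundary: %s:%d [%s]  partner=%s  clips=%d  discordant=%s\n",
              x$side, x$contig, x$coordinate, x$status,
              ifelse(is.na(x$partner_cassette), "?", x$partner_cassette),
              x$n_softclip,
              ifelse(is.na(x$n_discordant), "?", x$n_discordant)))
  invisible(x)
}

#' Duplicated sequence (microhomology) at a junction
#'
#' For a left boundary: the longest string that is simultaneously a suffix
#' of the retained flank and a prefix of the cassette side. For a right
#' boundary, the mirror image: the longest string that is simultaneously a
#' suffix of the cassette side and a prefix of the retained flank. Matching
#' is exact.
#'
#' @param flank_seq Retained flank sequence adjacent to the junction (for a
#'   left boundary, the sequence ending at the boundary; for a right
#'   boundary, the sequence starting at it).
#' @param cassette_seq Cassette-side junction sequence (for a left boundary,
#'   the cassette 5' end; for a right boundary, its 3' end).
#' @param side `"left"` or `"right"`.
#' @param max_len Maximum homology length considered (default 50).
#' @return List with `seq` and `length`.
#' @export
compute_microhomology <- function(flank_seq, cassette_seq,
                                  side = c("left", "right"), max_len = 50L) {
  side <- match.arg(side)
  if (side == "left") {
    a <- flank_seq; b <- cassette_seq  # suffix of a == prefix of b
  } else {
    a <- cassette_seq; b <- flank_seq
  }
  kmax <- min(max_len, nchar(a), nchar(b))
  if (kmax >= 1) {
    for (k in kmax:1) {
      if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k))
        return(list(seq = substr(b, 1L, k), length = as.integer(k)))
    }
  }
  list(seq = "", length = 0L)
}

#' Assemble the final insertion call from two boundary calls
#'
#' The deletion length is the coordinate difference
#' `right$coordinate - left$coordinate` (the arithmetic used to report the
#' loss at the integration site; the inclusive deleted base count is one
#' less). Microhomologies may be supplied per side (e.g. from
#' [compute_microhomology()] against reference flank and cassette
#' sequences).
#'
#' @param left,right `boundary_call` objects on the same contig with
#'   `right$coordinate >= left$coordinate`.
#' @param left_microhomology,right_microhomology Optional
#'   `list(seq, length)`.
#' @return An object of class `insertion_call`.
#' @export
assemble_insertion_call <- function(left, right,
                                    left_microhomology = NULL,
                                    right_microhomology = NULL) {
  stopifnot(inherits(left, "boundary_call"), inherits(right, "boundary_call"))
  if (left$contig != right$contig)
    stop("boundaries lie on different contigs; not a simple insertion",
         call. = FALSE)
  if (right$coordinate < left$coordinate)
    stop("right boundary precedes left boundary", call. = FALSE)
  mh0 <- list(seq = "", length = NA_integer_)
  structure(list(
    contig = left$contig,
    left = left, right = right,
    deletion_length = right$coordinate - left$coordinate,
    left_microhomology = left_microhomology %||% mh0,
    right_microhomology = right_microhomology %||% mh0,
    status = if (left$status == "exact" && right$status == "exact")
      "exact" else "approximate"
  ), class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  cat(sprintf("Insertion call [%s] on %s\n", x$status, x$contig))
  print(x$left); print(x$right)
  cat(sprintf("  deletion length: %d bp (coordinate difference)\n",
              x$deletion_length))
  cat(sprintf("  microhomology: left %s (%s bp), right %s (%s bp)\n",
              ifelse(nzchar(x$left_microhomology$seq),
                     x$left_microhomology$seq, "-"),
              x$left_microhomology$length,
              ifelse(nzchar(x$right_microhomology$seq),
                     x$right_microhomology$seq, "-"),
              x$right_microhomology$length))
  invisible(x)
}
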