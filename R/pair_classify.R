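#' Robust insert-size model
#'
#' Builds concordance bounds for the outer insert size from same-contig,
#' inward-facing read pairs, using the median and the median absolute
#' deviation: `bounds = median +/- k * 1.4826 * MAD` with a 1-bp floor on
#' the scaled MAD so degenerate (constant) inputs still yield a usable
#' window. Deterministic for a fixed input.
#'
#' @param x Either an alignment data.frame (pairs are extracted internally)
#'   or a numeric vector of insert sizes.
#' @param k Number of scaled MADs on each side (default 3).
#' @param min_pairs Minimum number of informative pairs (default 200).
#' @return An object of class `insert_size_model` with fields `median`,
#'   `mad`, `lower`, `upper`.
#' @export
estimate_insert_model <- function(x, k = 3, min_pairs = 200L) {
  if (is.data.frame(x)) {
    pr <- pair_table(x)
    same <- !is.na(pr$contigA) & !is.na(pr$contigB) & pr$contigA == pr$contigB
    inward <- same & inward_facing(pr)
    x <- pr$insert[inward]
  }
  x <- x[is.finite(x)]
  if (length(x) < min_pairs)
    stop("fewer than ", min_pairs, " same-contig inward-facing pairs; ",
         "supply explicit bounds via insert_size_model()", call. = FALSE)
  med <- stats::median(x)
  smad <- max(stats::mad(x), 1)  # mad() applies the 1.4826 constant
  insert_size_model(median = med, mad = smad / 1.4826,
                    lower = med - k * smad, upper = med + k * smad)
}

#' @rdname estimate_insert_model
#' @param median,mad,lower,upper Explicit model values (`lower < median <
#'   upper`).
#' @export
insert_size_model <- function(median, mad, lower, upper) {
  if (!(lower < median && median < upper))
    stop("insert model requires lower < median < upper", call. = FALSE)
  structure(list(median = median, mad = mad, lower = lower, upper = upper),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf("Insert-size model: median %.0f, MAD %.1f, concordant [%.0f, %.0f]\n",
              x$median, x$mad, x$lower, x$upper))
  invisible(x)
}

# Collapse per-mate alignment rows into one row per pair. Pairs missing a
# mate get NA B-side fields (classified one_end_unmapped).
pair_table <- function(aln) {
  aln <- aln[order(aln$read_id, aln$mate), , drop = FALSE]
  a <- aln[aln$mate == 1L, , drop = FALSE]
  b <- aln[aln$mate == 2L, , drop = FALSE]
  ids <- union(a$read_id, b$read_id)
  ia <- match(ids, a$read_id); ib <- match(ids, b$read_id)
  pick <- function(d, i, col, default) {
    out <- d[[col]][i]
    out[is.na(i)] <- default
    out
  }
  pr <- data.frame(
    read_id = ids,
    contigA = pick(a, ia, "contig", NA_character_),
    posA = pick(a, ia, "pos", NA_integer_),
    endA = pick(a, ia, "end", NA_integer_),
    strandA = pick(a, ia, "strand", NA_character_),
    mapqA = pick(a, ia, "mapq", NA_integer_),
    contigB = pick(b, ib, "contig", NA_character_),
    posB = pick(b, ib, "pos", NA_integer_),
    endB = pick(b, ib, "end", NA_integer_),
    strandB = pick(b, ib, "strand", NA_character_),
    mapqB = pick(b, ib, "mapq", NA_integer_),
    stringsAsFactors = FALSE)
  pr$insert <- ifelse(!is.na(pr$contigA) & !is.na(pr$contigB) &
                        pr$contigA == pr$contigB,
                      pmax(pr$endA, pr$endB) - pmin(pr$posA, pr$posB) + 1L,
                      NA_integer_)
  pr
}

# inward orientation: leftmost mate on +, rightmost on -
inward_facing <- function(pr) {
  a_left <- pr$posA <= pr$posB
  ls <- ifelse(a_left, pr$strandA, pr$strandB)
  rs <- ifelse(a_left, pr$strandB, pr$strandA)
  !is.na(ls) & !is.na(rs) & ls == "+" & rs == "-"
}

#' Classify read pairs against an insert-size model
#'
#' Reproduces the capture of read pairs that cannot be aligned concordantly:
#' mates on different contigs are `discordant_interchrom`; same-contig pairs
#' must face inward (`discordant_orientation` otherwise) with an insert
#' within the model bounds (`discordant_size` otherwise) to be `concordant`.
#' Pairs with either mate below `min_mapq` are flagged non-unique
#' (`mapq_pass = FALSE`) and are excluded from downstream structural-variant
#' evidence.
#'
#' @param aln Alignment data.frame (two rows per pair).
#' @param model An `insert_size_model`.
#' @param min_mapq Uniqueness proxy threshold (default 20).
#' @return A pair-level data.frame with footprints, `class` and `mapq_pass`.
#' @export
classify_pairs <- function(aln, model, min_mapq = 20L) {
  stopifnot(inherits(model, "insert_size_model"))
  pr <- pair_table(aln)
  cls <- rep("concordant", nrow(pr))
  unpaired <- is.na(pr$contigA) | is.na(pr$contigB)
  inter <- !unpaired & pr$contigA != pr$contigB
  same <- !unpaired & !inter
  badori <- same & !inward_facing(pr)
  badsize <- same & !badori &
    (pr$insert < model$lower | pr$insert > model$upper)
  cls[unpaired] <- "one_end_unmapped"
  cls[inter] <- "discordant_interchrom"
  cls[badori] <- "discordant_orientation"
  cls[badsize] <- "discordant_size"
  pr$class <- cls
  pr$mapq_pass <- !is.na(pr$mapqA) & !is.na(pr$mapqB) &
    pr$mapqA >= min_mapq & pr$mapqB >= min_mapq
  pr
}

#' Classify a single read pair
#'
#' Scalar interface over [classify_pairs()]; `a` and `b` are one-row
#' alignment records of the two mates and must share a `read_id`.
#'
#' @param a,b One-row alignment data.frames.
#' @inheritParams classify_pairs
#' @return The pair class as a character scalar.
#' @export
classify_pair <- function(a, b, model, min_mapq = 20L) {
  if (a$read_id != b$read_id)
    stop("mates must share a read_id", call. = FALSE)
  a$mate <- 1L; b$mate <- 2L
  classify_pairs(rbind(a, b), model, min_mapq)$class
}

#' Extract soft-clip events from alignments
#'
#' One event per clip of length at least `min_clip`. `boundary_pos` is the
#' reference coordinate of the last aligned base adjacent to the clip: for a
#' right-side clip this is the alignment end; for a left-side clip it is
#' `pos - 1` (the convention used throughout; boundary resolution adds one
#' back for right-side junctions).
#'
#' @param aln Alignment data.frame.
#' @param min_clip Minimum clip length to report (default 10 bp).
#' @return Data.frame of clip events: read_id, contig, boundary_pos, side,
#'   clipped_seq, mapq.
#' @export
extract_clips <- function(aln, min_clip = 10L) {
  ev <- list()
  left <- aln$lclip >= min_clip
  if (any(left)) {
    d <- aln[left, , drop = FALSE]
    ev$left <- data.frame(
      read_id = d$read_id, contig = d$contig,
      boundary_pos = d$pos - 1L, side = "left",
      clipped_seq = substr(d$seq, 1L, d$lclip), mapq = d$mapq,
      stringsAsFactors = FALSE)
  }
  right <- aln$rclip >= min_clip
  if (any(right)) {
    d <- aln[right, , drop = FALSE]
    ev$right <- data.frame(
      read_id = d$read_id, contig = d$contig,
      boundary_pos = d$end, side = "right",
      clipped_seq = substr(d$seq, nchar(d$seq) - d$rclip + 1L, nchar(d$seq)),
      mapq = d$mapq, stringsAsFactors = FALSE)
  }
  if (length(ev) == 0)
    return(data.frame(read_id = character(0), contig = character(0),
                      boundary_pos = integer(0), side = character(0),
                      clipped_seq = character(0), mapq = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out[order(out$contig, out$boundary_pos), , drop = FALSE]
}
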