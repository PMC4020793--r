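# Junction reads that aligned to the cassette (donor) side carry the host
# flank in their soft-clipped tails. Re-anchor them into the resolution
# window by matching the clipped sequence against the insertion-contig
# reference, and emit clip events in insertion-contig coordinates whose
# clipped_seq is the cassette-side (aligned) portion, so they feed boundary
# consensus exactly like natively flank-aligned junction reads.
rescue_junction_clips <- function(aln, locus_contig, w0, w1, refseq,
                                  min_clip = 10L, min_mapq = 20L,
                                  max_mismatch = 2L) {
  empty <- data.frame(read_id = character(0), contig = character(0),
                      boundary_pos = integer(0), side = character(0),
                      clipped_seq = character(0), mapq = integer(0),
                      stringsAsFactors = FALSE)
  cand <- aln[aln$contig != locus_contig & aln$mapq >= min_mapq &
                (aln$lclip >= min_clip | aln$rclip >= min_clip), ,
              drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  win <- Biostrings::DNAString(substr(refseq, w0, w1))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    for (clip_side in c("left", "right")[c(r$lclip >= min_clip,
                                           r$rclip >= min_clip)]) {
      if (clip_side == "left") {
        cseq <- substr(r$seq, 1L, r$lclip)
        aseq <- substr(r$seq, r$lclip + 1L, nchar(r$seq) - r$rclip)
      } else {
        cseq <- substr(r$seq, nchar(r$seq) - r$rclip + 1L, nchar(r$seq))
        aseq <- substr(r$seq, r$lclip + 1L, nchar(r$seq) - r$rclip)
      }
      for (orient in c("fwd", "rc")) {
        pat <- if (orient == "fwd") cseq else revcomp(cseq)
        hits <- Biostrings::matchPattern(pat, win,
                                         max.mismatch = max_mismatch)
        if (length(hits) != 1) next
        s <- Biostrings::start(hits)[1] + w0 - 1L
        e <- Biostrings::end(hits)[1] + w0 - 1L
        # which end of the matched flank abuts the junction decides the
        # boundary side (see extract_clips for the pos-1 convention)
        right_bdy <- (clip_side == "right") == (orient == "fwd")
        out[[length(out) + 1L]] <- data.frame(
          read_id = r$read_id, contig = locus_contig,
          boundary_pos = if (right_bdy) s - 1L else e,
          side = if (right_bdy) "left" else "right",
          clipped_seq = if (orient == "fwd") aseq else revcomp(aseq),
          mapq = r$mapq, stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Locate a transgene integration site from paired-end alignments
#'
#' The central fitting function: runs the full inference chain on a table of
#' alignment records — insert-size model, pair classification, soft-clip
#' extraction, single-linkage clustering of unique discordant pairs,
#' read-depth duplication scanning, rule-based filtering and ranking, and
#' split-read boundary resolution in the window around the top-ranked
#' candidate (both boundaries are resolved there, mirroring the original
#' workflow of nominating one candidate and then inspecting the local
#' alignments) — and estimates cassette copy folds from coverage ratios.
#'
#' @param aln Alignment data.frame (from [read_sam()] or
#'   [emit_oracle_alignments()]).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param reference Optional named character vector of reference contig
#'   sequences; enables microhomology computation against the flanks.
#' @param cassettes Optional named character vector of cassette junction
#'   sequences (see [cassette_seqs()]); enables partner assignment and
#'   cassette-side microhomology.
#' @param cassette_loci Optional data.frame (cassette_id, contig, start,
#'   end) of cassette intervals for copy-fold estimation; defaults to the
#'   detected duplication calls.
#' @param contig_offsets Optional named integer vector added to coordinates
#'   on the named contigs when reporting (offset frame, e.g. to report
#'   positions of a simulated window in real-chromosome coordinates).
#' @param insert_model Optional [insert_size_model()]; estimated from the
#'   data when NULL.
#' @param min_mapq Uniqueness threshold for SV evidence (default 20).
#' @param min_clip Minimum soft-clip length (default 10).
#' @param cluster_window Linkage window; default 2 x insert-model median.
#' @param bin Depth-profile bin width (default 200).
#' @param dup_min_fold Duplication detection threshold (default 1.5).
#' @param filters A [filter_config()].
#' @param dup_window Bridging distance for ranking (default 1000).
#' @param resolve_pad Half-width of the boundary-resolution window around
#'   the top candidate; default 2 x the insert-model upper bound.
#' @param max_mh Maximum microhomology span (default 50).
#' @param edge_trim,bootstrap_n,seed Copy-fold estimation settings (see
#'   [estimate_copy_fold()]).
#' @return An object of class `insertion_fit`; see [print.insertion_fit()],
#'   [summary.insertion_fit()], [coef.insertion_fit()],
#'   [plot.insertion_fit()]. Reported coordinates are in the offset frame.
#' @export
locate_insertion <- function(aln, contig_lengths, reference = NULL,
                             cassettes = NULL, cassette_loci = NULL,
                             contig_offsets = NULL, insert_model = NULL,
                             min_mapq = 20L, min_clip = 10L,
                             cluster_window = NULL, bin = 200L,
                             dup_min_fold = 1.5, filters = filter_config(),
                             dup_window = 1000L, resolve_pad = NULL,
                             max_mh = 50L, edge_trim = 200L,
                             bootstrap_n = 1000L, seed = 1L) {
  model <- insert_model %||% estimate_insert_model(aln)
  window <- as.integer(cluster_window %||% (2 * model$median))
  pad <- as.integer(resolve_pad %||% (2 * model$upper))
  offset_of <- function(contig) {
    if (is.null(contig_offsets) || is.na(contig_offsets[contig])) 0L
    else as.integer(contig_offsets[[contig]])
  }

  pairs <- classify_pairs(aln, model, min_mapq = min_mapq)
  clips <- extract_clips(aln, min_clip = min_clip)
  disc <- pairs[pairs$class %in% c("discordant_interchrom", "discordant_size") &
                  pairs$mapq_pass, , drop = FALSE]
  clusters <- cluster_discordant_pairs(disc, window = window, clips = clips,
                                       min_clip_mapq = min_mapq)
  profile <- compute_depth_profile(aln, contig_lengths, bin = bin)
  dups <- scan_depth_duplications(profile, min_fold = dup_min_fold)
  filtered <- apply_filters(clusters, dups, filters)
  ranked <- rank_candidates(filtered, dups, dup_window = dup_window)

  call <- NULL; top <- NULL; boundaries <- NULL
  if (nrow(ranked) > 0) {
    top <- ranked[1, , drop = FALSE]
    # the candidate side overlapping a duplication is the cassette donor;
    # the other side is the insertion locus
    a_dup <- overlaps_call(top$contigA, top$startA, top$endA, dups,
                           pad = dup_window)
    b_dup <- overlaps_call(top$contigB, top$startB, top$endB, dups,
                           pad = dup_window)
    if (a_dup && !b_dup) {
      locus <- c(top$contigB, top$startB, top$endB)
    } else {
      locus <- c(top$contigA, top$startA, top$endA)
    }
    locus_contig <- locus[1]
    w0 <- as.integer(locus[2]) - pad; w1 <- as.integer(locus[3]) + pad
    inwin <- clips$contig == locus_contig & clips$mapq >= min_mapq &
      clips$boundary_pos >= w0 & clips$boundary_pos <= w1
    cw <- clips[inwin, , drop = FALSE]
    if (!is.null(reference) && locus_contig %in% names(reference)) {
      resc <- rescue_junction_clips(aln, locus_contig, max(1L, w0),
                                    min(nchar(reference[[locus_contig]]), w1),
                                    reference[[locus_contig]],
                                    min_clip = min_clip, min_mapq = min_mapq)
      cw <- rbind(cw[, names(resc)], resc)
    }
    fallback <- c(as.integer(locus[2]), as.integer(locus[3]))
    left_b <- resolve_boundary(cw, "left", cassettes = cassettes,
                               fallback_interval = fallback,
                               contig = locus_contig, max_shift = max_mh)
    right_b <- resolve_boundary(cw, "right", cassettes = cassettes,
                                fallback_interval = fallback,
                                contig = locus_contig, max_shift = max_mh)

    # discordant support per boundary: nearest cluster interval on the locus
    # contig (either side of any cluster)
    support_at <- function(coord) {
      best <- NA_integer_; bestd <- Inf
      for (i in seq_len(nrow(clusters))) {
        for (sd in c("A", "B")) {
          if (clusters[[paste0("contig", sd)]][i] != locus_contig) next
          d <- interval_dist(clusters[[paste0("start", sd)]][i],
                             clusters[[paste0("end", sd)]][i], coord, coord)
          if (d < bestd && d <= pad) { bestd <- d; best <- clusters$support[i] }
        }
      }
      best
    }
    left_b$n_discordant <- support_at(left_b$coordinate)
    right_b$n_discordant <- support_at(right_b$coordinate)

    # microhomology against reference flank + cassette junction sequence
    mh_l <- NULL; mh_r <- NULL
    if (!is.null(reference) && locus_contig %in% names(reference)) {
      ref <- reference[[locus_contig]]
      lf <- substr(ref, max(1L, left_b$coordinate - max_mh + 1L),
                   left_b$coordinate)
      rf <- substr(ref, right_b$coordinate,
                   min(nchar(ref), right_b$coordinate + max_mh - 1L))
      cl <- if (!is.na(left_b$partner_cassette) && !is.null(cassettes))
        cassettes[[left_b$partner_cassette]] else left_b$clip_consensus
      cr <- if (!is.na(right_b$partner_cassette) && !is.null(cassettes))
        cassettes[[right_b$partner_cassette]] else right_b$clip_consensus
      if (nzchar(cl)) mh_l <- compute_microhomology(lf, cl, "left", max_mh)
      if (nzchar(cr)) mh_r <- compute_microhomology(rf, cr, "right", max_mh)
    }

    # report in the offset frame
    off <- offset_of(locus_contig)
    left_b$coordinate_local <- left_b$coordinate
    right_b$coordinate_local <- right_b$coordinate
    left_b$coordinate <- left_b$coordinate + off
    right_b$coordinate <- right_b$coordinate + off
    call <- assemble_insertion_call(left_b, right_b, mh_l, mh_r)
    boundaries <- list(left = left_b, right = right_b)
  }

  # copy folds over cassette intervals (or detected duplications)
  loci <- cassette_loci
  if (is.null(loci) && nrow(dups) > 0)
    loci <- data.frame(cassette_id = sprintf("dup%02d", seq_len(nrow(dups))),
                       contig = dups$contig, start = dups$start,
                       end = dups$end, stringsAsFactors = FALSE)
  folds <- NULL
  if (!is.null(loci) && nrow(loci) > 0) {
    bg <- setdiff(names(contig_lengths), unique(loci$contig))
    if (length(bg) == 0) bg <- NULL
    ests <- lapply(seq_len(nrow(loci)), function(i) {
      tryCatch(
        estimate_copy_fold(profile, loci$contig[i], loci$start[i],
                           loci$end[i], background = bg,
                           cassette_id = loci$cassette_id[i],
                           edge_trim = edge_trim, bootstrap_n = bootstrap_n,
                           seed = seed),
        error = function(e) NULL)
    })
    ests <- ests[!vapply(ests, is.null, TRUE)]
    if (length(ests))
      folds <- do.call(rbind, lapply(ests, function(e)
        data.frame(cassette_id = e$cassette_id, contig = e$contig,
                   start = e$start, end = e$end, mean_depth = e$mean_depth,
                   genome_mean = e$genome_mean, copy_fold = e$copy_fold,
                   ci_low = e$ci_low, ci_high = e$ci_high,
                   stringsAsFactors = FALSE)))
  }

  funnel <- c(pairs_total = nrow(pairs),
              discordant = sum(pairs$class %in%
                                 c("discordant_interchrom", "discordant_size")),
              discordant_unique = nrow(disc),
              clusters = nrow(clusters),
              filtered = sum(filtered$keep),
              ranked = nrow(ranked),
              resolved = as.integer(!is.null(call) && call$status == "exact"))

  structure(list(
    call = call, boundaries = boundaries, top_candidate = top,
    candidates = ranked, clusters = filtered, dup_calls = dups,
    copy_folds = folds, insert_model = model, profile = profile,
    funnel = funnel, clips = clips,
    settings = list(min_mapq = min_mapq, min_clip = min_clip,
                    cluster_window = window, bin = bin,
                    dup_min_fold = dup_min_fold, dup_window = dup_window,
                    resolve_pad = pad, max_mh = max_mh, filters = filters),
    contig_offsets = contig_offsets
  ), class = "insertion_fit")
}

#' @export
print.insertion_fit <- function(x, ...) {
  cat("Transgene integration-site fit\n")
  print(x$insert_model)
  cat(sprintf("  evidence funnel: %s\n",
              paste(sprintf("%s=%d", names(x$funnel), x$funnel),
                    collapse = " > ")))
  if (is.null(x$call)) {
    cat("  no candidate survived filtering; no insertion call\n")
  } else {
    print(x$call)
  }
  if (!is.null(x$copy_folds)) {
    cat("  cassette copy folds (coverage ratio):\n")
    for (i in seq_len(nrow(x$copy_folds)))
      cat(sprintf("    %s %s:%d-%d  %.2fX [%.2f, %.2f]\n",
                  x$copy_folds$cassette_id[i], x$copy_folds$contig[i],
                  x$copy_folds$start[i], x$copy_folds$end[i],
                  x$copy_folds$copy_fold[i], x$copy_folds$ci_low[i],
                  x$copy_folds$ci_high[i]))
  }
  invisible(x)
}

#' @export
#' @method summary insertion_fit
summary.insertion_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.insertion_fit")
}

#' @export
print.summary.insertion_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat("\nRanked candidates:\n")
  if (nrow(f$candidates))
    print(f$candidates[, c("rank", "contigA", "startA", "endA", "contigB",
                           "startB", "endB", "support", "split_support",
                           "bridged")], row.names = FALSE)
  rej <- f$clusters[!f$clusters$keep, , drop = FALSE]
  cat(sprintf("\nRejected clusters: %d\n", nrow(rej)))
  if (nrow(rej))
    print(rej[, c("contigA", "startA", "contigB", "startB", "support",
                  "reason")], row.names = FALSE)
  invisible(x)
}

#' @export
#' @method coef insertion_fit
coef.insertion_fit <- function(object, ...) {
  if (is.null(object$call))
    return(c(left_boundary = NA_real_, right_boundary = NA_real_,
             deletion_length = NA_real_))
  c(left_boundary = object$call$left$coordinate,
    right_boundary = object$call$right$coordinate,
    deletion_length = object$call$deletion_length)
}

#' Plot depth profile and resolved boundaries of an insertion fit
#'
#' One panel per contig: binned depth with duplication calls shaded and, on
#' the insertion contig, the resolved boundaries marked.
#'
#' @param x An `insertion_fit`.
#' @param ... Ignored.
#' @export
#' @method plot insertion_fit
plot.insertion_fit <- function(x, ...) {
  bins <- x$profile$bins
  contigs <- unique(bins$contig)
  op <- graphics::par(mfrow = c(length(contigs), 1),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (ct in contigs) {
    d <- bins[bins$contig == ct, ]
    graphics::plot((d$start + d$end) / 2, d$depth, type = "l",
                   xlab = "", ylab = "depth", main = ct, col = "grey25")
    dc <- x$dup_calls[x$dup_calls$contig == ct, , drop = FALSE]
    if (nrow(dc))
      graphics::rect(dc$start, 0, dc$end, max(d$depth), border = NA,
                     col = grDevices::adjustcolor("steelblue", 0.25))
    if (!is.null(x$boundaries) && x$boundaries$left$contig == ct)
      graphics::abline(v = c(x$boundaries$left$coordinate_local,
                             x$boundaries$right$coordinate_local),
                       col = "firebrick", lty = 2)
  }
  invisible(x)
}
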