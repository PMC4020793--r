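#' Binned read-depth profile from alignments
#'
#' Depth per bin is the aligned-base count divided by the bin width (reads
#' straddling a bin edge are apportioned), computed per contig via run-length
#' coverage. Deterministic.
#'
#' @param aln Alignment data.frame (mapped records; soft-clipped bases do not
#'   contribute).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param bin Bin width in bp (default 200).
#' @return An object of class `depth_profile`: list with `bins`
#'   (contig/start/end/depth), `bin`, and `contig_lengths`.
#' @export
compute_depth_profile <- function(aln, contig_lengths, bin = 200L) {
  if (is.null(aln) || nrow(aln) == 0) stop("no alignments", call. = FALSE)
  bin <- as.integer(bin)
  out <- list()
  for (ct in names(contig_lengths)) {
    len <- as.integer(contig_lengths[[ct]])
    d <- aln[aln$contig == ct, , drop = FALSE]
    cvg <- IRanges::coverage(IRanges::IRanges(start = d$pos, end = d$end),
                             width = len)
    starts <- seq.int(1L, len, by = bin)
    ends <- pmin(starts + bin - 1L, len)
    v <- IRanges::Views(cvg, start = starts, end = ends)
    out[[ct]] <- data.frame(contig = ct, start = starts, end = ends,
                            depth = as.numeric(IRanges::viewMeans(v)),
                            stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  structure(list(bins = bins, bin = bin, contig_lengths = contig_lengths),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  w <- x$bins$end - x$bins$start + 1
  cat(sprintf("Depth profile: %d bins of %d bp over %d contigs; mean depth %.2f\n",
              nrow(x$bins), x$bin, length(unique(x$bins$contig)),
              sum(x$bins$depth * w) / sum(w)))
  invisible(x)
}

profile_mean <- function(profile, bins) {
  w <- bins$end - bins$start + 1
  sum(bins$depth * w) / sum(w)
}

#' Coverage-ratio copy-fold estimate over a cassette interval
#'
#' `copy_fold = mean depth over the (edge-trimmed) cassette interval divided
#' by the genome-wide mean depth` — the "X" arithmetic used to report insert
#' copy numbers from coverage (e.g. 16X alpha and 4X beta over an 8X
#' genome). The confidence interval is a percentile bootstrap over bins.
#' Conversion to a per-haploid biological copy count depends on zygosity and
#' endogenous copies and is left to the user (see the methods vignette).
#'
#' @param profile A `depth_profile`.
#' @param contig,start,end Cassette interval (1-based inclusive).
#' @param background Bins used for the genome-wide mean: a character vector
#'   of contig names, or a data.frame of intervals (contig/start/end), or
#'   `NULL` to use all bins outside the cassette interval. For simulated
#'   genomes without endogenous cassette copies, pass the insertion contig
#'   (donor-contig pads are unsampled and would deflate the mean).
#' @param cassette_id Optional label carried into the result.
#' @param edge_trim Bases trimmed from each interval end before averaging,
#'   avoiding junction soft-clip depth dips (default 200).
#' @param bootstrap_n Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (default 1).
#' @return An object of class `copy_fold_estimate` with fields cassette_id,
#'   contig, start, end, mean_depth, genome_mean, copy_fold, ci_low,
#'   ci_high, n_bins.
#' @export
estimate_copy_fold <- function(profile, contig, start, end,
                               background = NULL, cassette_id = NA_character_,
                               edge_trim = 200L, bootstrap_n = 1000L,
                               seed = 1L) {
  stopifnot(inherits(profile, "depth_profile"))
  if (end - start + 1L <= 2L * edge_trim)
    stop("cassette interval shorter than twice the edge trim", call. = FALSE)
  b <- profile$bins
  inb <- b$contig == contig & b$start >= start + edge_trim &
    b$end <= end - edge_trim
  if (!any(inb))
    stop("no whole bins inside the trimmed cassette interval", call. = FALSE)
  cass <- b[inb, , drop = FALSE]

  if (is.null(background)) {
    bg <- b[!(b$contig == contig & b$start <= end & b$end >= start), ,
            drop = FALSE]
  } else if (is.character(background)) {
    bg <- b[b$contig %in% background, , drop = FALSE]
  } else {
    keep <- rep(FALSE, nrow(b))
    for (i in seq_len(nrow(background)))
      keep <- keep | (b$contig == background$contig[i] &
                        b$start >= background$start[i] &
                        b$end <= background$end[i])
    bg <- b[keep, , drop = FALSE]
  }
  gmean <- profile_mean(profile, bg)
  if (!is.finite(gmean) || gmean <= 0)
    stop("genome-wide mean depth is zero over the background", call. = FALSE)

  mean_depth <- profile_mean(profile, cass)
  fold <- mean_depth / gmean
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(bootstrap_n), function(i) {
    ix <- sample.int(nrow(cass), replace = TRUE)
    profile_mean(profile, cass[ix, , drop = FALSE]) / gmean
  }, 1)
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(cassette_id = cassette_id, contig = contig,
                 start = as.integer(start), end = as.integer(end),
                 mean_depth = mean_depth, genome_mean = gmean,
                 copy_fold = fold, ci_low = ci[1], ci_high = ci[2],
                 n_bins = nrow(cass)),
            class = "copy_fold_estimate")
}

#' @export
print.copy_fold_estimate <- function(x, ...) {
  cat(sprintf("Copy fold %s %s:%d-%d: %.2fX (mean depth %.2f / genome %.2f), 95%% CI [%.2f, %.2f]\n",
              ifelse(is.na(x$cassette_id), "", x$cassette_id), x$contig,
              x$start, x$end, x$copy_fold, x$mean_depth, x$genome_mean,
              x$ci_low, x$ci_high))
  invisible(x)
}
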