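#' Cluster discordant read pairs into candidate rearrangement links
#'
#' Single-linkage clustering of discordant pairs: two pairs join the same
#' cluster when both their A-side and their B-side footprints lie within
#' `window` bp (interval gap) of each other and share contigs on both sides.
#' Sides are canonicalised so that side A is the lexicographically smaller
#' (contig, position). Each cluster records its supporting pair count, mean
#' mapping quality, and split-read support (clip events falling inside
#' either cluster interval).
#'
#' @param pairs Pair-level data.frame (see [classify_pairs()]), already
#'   restricted to `discordant_interchrom`/`discordant_size` pairs passing
#'   the mapq filter.
#' @param window Linkage window in bp (default 800; the pipeline uses
#'   2 x the insert-model median).
#' @param clips Optional clip-event data.frame used to annotate
#'   `split_support`.
#' @param min_clip_mapq Clips below this mapq are not counted (default 20).
#' @param clip_pad Clip events within this distance of a cluster interval
#'   are counted as split support (default 200 bp; junction clips sit at the
#'   breakpoint itself, up to a read length beyond the pair footprints).
#' @return Data.frame of clusters: contigA, startA, endA, contigB, startB,
#'   endB, support, mean_mapq, split_support, members (semicolon-joined
#'   read ids), sorted by (contigA, startA).
#' @export
cluster_discordant_pairs <- function(pairs, window = 800L, clips = NULL,
                                     min_clip_mapq = 20L, clip_pad = 200L) {
  empty <- data.frame(contigA = character(0), startA = integer(0),
                      endA = integer(0), contigB = character(0),
                      startB = integer(0), endB = integer(0),
                      support = integer(0), mean_mapq = numeric(0),
                      split_support = integer(0), members = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)

  # canonical side order
  swap <- paste(pairs$contigA, sprintf("%012d", pairs$posA)) >
    paste(pairs$contigB, sprintf("%012d", pairs$posB))
  can <- pairs
  for (f in c("contig", "pos", "end", "strand", "mapq")) {
    a <- paste0(f, "A"); b <- paste0(f, "B")
    can[[a]] <- ifelse(swap, pairs[[b]], pairs[[a]])
    can[[b]] <- ifelse(swap, pairs[[a]], pairs[[b]])
  }

  n <- nrow(can)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }

  key <- paste(can$contigA, can$contigB)
  ord <- order(key, can$posA)
  for (gi in split(ord, key[ord])) {
    # gi sorted by posA within one contig pair
    for (u in seq_along(gi)) {
      i <- gi[u]
      v <- u + 1L
      while (v <= length(gi)) {
        j <- gi[v]
        if (can$posA[j] - can$endA[i] > window) break
        if (interval_dist(can$posB[i], can$endB[i],
                          can$posB[j], can$endB[j]) <= window)
          unite(i, j)
        v <- v + 1L
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)

  rows <- lapply(split(seq_len(n), comp), function(ix) {
    d <- can[ix, , drop = FALSE]
    data.frame(
      contigA = d$contigA[1], startA = min(d$posA), endA = max(d$endA),
      contigB = d$contigB[1], startB = min(d$posB), endB = max(d$endB),
      support = nrow(d),
      mean_mapq = mean(c(d$mapqA, d$mapqB)),
      split_support = 0L,
      members = paste(sort(d$read_id), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  cl <- do.call(rbind, rows)
  rownames(cl) <- NULL
  if (!is.null(clips) && nrow(clips) > 0) {
    keep <- clips$mapq >= min_clip_mapq
    ck <- clips[keep, , drop = FALSE]
    cl$split_support <- vapply(seq_len(nrow(cl)), function(i) {
      inA <- ck$contig == cl$contigA[i] &
        ck$boundary_pos >= cl$startA[i] - clip_pad &
        ck$boundary_pos <= cl$endA[i] + clip_pad
      inB <- ck$contig == cl$contigB[i] &
        ck$boundary_pos >= cl$startB[i] - clip_pad &
        ck$boundary_pos <= cl$endB[i] + clip_pad
      sum(inA | inB)
    }, 1L)
  }
  cl[order(cl$contigA, cl$startA, cl$contigB, cl$startB), , drop = FALSE]
}

#' Scan a depth profile for read-depth duplications
#'
#' Contiguous runs of bins with depth at least `min_fold` times the
#' genome-wide baseline are merged into duplication calls, scored by
#' `rc = mean run depth / baseline` (normalised read count) and ranked by
#' `rc` descending. The baseline is the median depth of covered (non-zero)
#' bins — robust both to the duplications themselves and to unsampled
#' reference stretches (e.g. donor contigs absent from the sequenced
#' genome).
#'
#' @param profile A `depth_profile` from [compute_depth_profile()].
#' @param min_fold Detection threshold as a multiple of the baseline
#'   (default 1.5).
#' @return Data.frame of calls: contig, start, end, rc; ordered by rc
#'   descending.
#' @export
scan_depth_duplications <- function(profile, min_fold = 1.5) {
  stopifnot(inherits(profile, "depth_profile"))
  bins <- profile$bins
  covered <- bins$depth[bins$depth > 0]
  if (length(covered) == 0) stop("zero genome-wide coverage", call. = FALSE)
  gmean <- stats::median(covered)
  out <- list()
  for (ct in unique(bins$contig)) {
    d <- bins[bins$contig == ct, , drop = FALSE]
    hot <- d$depth >= min_fold * gmean
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      ix <- starts[k]:ends[k]
      ww <- d$end[ix] - d$start[ix] + 1
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, start = d$start[starts[k]], end = d$end[ends[k]],
        rc = sum(d$depth[ix] * ww) / sum(ww) / gmean,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), rc = numeric(0),
                      stringsAsFactors = FALSE))
  calls <- do.call(rbind, out)
  calls <- calls[order(-calls$rc, calls$contig, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Filter configuration for candidate clusters
#'
#' Codifies the manual candidate-review rules this workflow otherwise needs:
#' discard clusters supported by
#' fewer than `min_support` or more than `max_support` pairs, clusters on
#' excluded contigs (mitochondrial/centromeric annotations), intra-
#' chromosomal clusters, clusters crowded by `adjacent_n` or more other
#' clusters within `adjacent_window` bp ("multiple adjacent
#' rearrangements"), and clusters whose both sides lie inside read-depth
#' duplications (intra-array artifacts; the analogue of candidates
#' "associated with repeats").
#'
#' @param min_support,max_support Supporting-pair bounds (defaults 5 and 16).
#' @param excluded_contigs Character vector of contig names to drop.
#' @param drop_intra_chrom Drop same-contig clusters (default TRUE).
#' @param drop_adjacent Drop adjacency-crowded clusters (default TRUE).
#' @param adjacent_n,adjacent_window Crowding definition (defaults 3
#'   clusters within 10 kb).
#' @param adjacent_min_support Only clusters with at least this support
#'   count as crowding neighbours (fixed default 2: stray single pairs are
#'   not rearrangements; kept independent of `min_support` so filtering
#'   stays monotone in the support window).
#' @param drop_double_duplicated Drop clusters with both sides inside
#'   duplication calls (default TRUE).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_support = 5L, max_support = 16L,
                          excluded_contigs = character(0),
                          drop_intra_chrom = TRUE, drop_adjacent = TRUE,
                          adjacent_n = 3L, adjacent_window = 10000L,
                          adjacent_min_support = 2L,
                          drop_double_duplicated = TRUE) {
  if (min_support > max_support)
    stop("min_support must not exceed max_support", call. = FALSE)
  structure(list(min_support = as.integer(min_support),
                 max_support = as.integer(max_support),
                 excluded_contigs = excluded_contigs,
                 drop_intra_chrom = drop_intra_chrom,
                 drop_adjacent = drop_adjacent,
                 adjacent_n = as.integer(adjacent_n),
                 adjacent_window = as.integer(adjacent_window),
                 adjacent_min_support = as.integer(adjacent_min_support),
                 drop_double_duplicated = drop_double_duplicated),
            class = "filter_config")
}

overlaps_call <- function(contig, start, end, calls, pad = 0L) {
  if (is.null(calls) || nrow(calls) == 0) return(rep(FALSE, length(contig)))
  vapply(seq_along(contig), function(i) {
    any(calls$contig == contig[i] &
          calls$start - pad <= end[i] & calls$end + pad >= start[i])
  }, TRUE)
}

#' Apply filter rules to candidate clusters
#'
#' @param clusters Cluster data.frame from [cluster_discordant_pairs()].
#' @param calls Duplication calls from [scan_depth_duplications()] (used by
#'   the double-duplication rule; may be NULL).
#' @param cfg A [filter_config()].
#' @return The cluster data.frame with logical `keep` and character
#'   `reason` columns (`reason` is `NA` for kept clusters).
#' @export
apply_filters <- function(clusters, calls = NULL, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- nrow(clusters)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    low <- clusters$support < cfg$min_support
    high <- clusters$support > cfg$max_support
    reason[low] <- sprintf("support<%d", cfg$min_support)
    reason[high] <- sprintf("support>%d", cfg$max_support)
    excl <- clusters$contigA %in% cfg$excluded_contigs |
      clusters$contigB %in% cfg$excluded_contigs
    reason[is.na(reason) & excl] <- "excluded_contig"
    if (cfg$drop_intra_chrom) {
      intra <- clusters$contigA == clusters$contigB
      reason[is.na(reason) & intra] <- "intra_chromosomal"
    }
    if (cfg$drop_adjacent && n > 1) {
      # crowding counts only plausible candidates: clusters below the fixed
      # floor are stray pairs, not "adjacent rearrangements"
      crowd <- vapply(seq_len(n), function(i) {
        others <- setdiff(which(clusters$support >= cfg$adjacent_min_support),
                          i)
        near <- (clusters$contigA[others] == clusters$contigA[i] &
                   interval_dist(clusters$startA[others], clusters$endA[others],
                                 clusters$startA[i], clusters$endA[i]) <=
                   cfg$adjacent_window) |
          (clusters$contigB[others] == clusters$contigA[i] &
             interval_dist(clusters$startB[others], clusters$endB[others],
                           clusters$startA[i], clusters$endA[i]) <=
             cfg$adjacent_window)
        sum(near) >= cfg$adjacent_n
      }, TRUE)
      reason[is.na(reason) & crowd] <- "adjacent_rearrangements"
    }
    if (cfg$drop_double_duplicated && !is.null(calls) && nrow(calls) > 0) {
      dd <- overlaps_call(clusters$contigA, clusters$startA, clusters$endA,
                          calls) &
        overlaps_call(clusters$contigB, clusters$startB, clusters$endB, calls)
      reason[is.na(reason) & dd] <- "both_sides_in_duplication"
    }
  }
  clusters$keep <- is.na(reason)
  clusters$reason <- reason
  clusters
}

#' Rank filtered candidate clusters
#'
#' Deterministic total order: split-read support (descending), then whether
#' a side of the cluster lies near a read-depth duplication call (bridged
#' candidates outrank unbridged), then pair support (descending), with ties
#' broken by (contig, coordinate) ascending.
#'
#' @param clusters Filtered clusters (rows with `keep == FALSE` are
#'   dropped if a `keep` column is present).
#' @param calls Duplication calls.
#' @param dup_window Proximity (bp) defining "bridged" (default 1000).
#' @return The clusters with `bridged` and `rank` columns, ordered by rank.
#' @export
rank_candidates <- function(clusters, calls = NULL, dup_window = 1000L) {
  if (!is.null(clusters$keep)) clusters <- clusters[clusters$keep, , drop = FALSE]
  if (nrow(clusters) == 0) {
    clusters$bridged <- logical(0); clusters$rank <- integer(0)
    return(clusters)
  }
  clusters$bridged <-
    overlaps_call(clusters$contigA, clusters$startA, clusters$endA, calls,
                  pad = dup_window) |
    overlaps_call(clusters$contigB, clusters$startB, clusters$endB, calls,
                  pad = dup_window)
  o <- order(-clusters$split_support, -clusters$bridged, -clusters$support,
             clusters$contigA, clusters$startA, clusters$contigB,
             clusters$startB)
  clusters <- clusters[o, , drop = FALSE]
  clusters$rank <- seq_len(nrow(clusters))
  rownames(clusters) <- NULL
  clusters
}
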