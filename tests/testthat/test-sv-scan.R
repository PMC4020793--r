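# random discordant pair tables for the clustering oracle
random_pairs <- function(n, seed) {
  set.seed(seed)
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    contigA = sample(c("c1", "c2"), n, replace = TRUE),
    posA = sample.int(20000, n, replace = TRUE),
    strandA = "+", mapqA = 60L,
    contigB = sample(c("c3", "c4"), n, replace = TRUE),
    posB = sample.int(20000, n, replace = TRUE),
    strandB = "-", mapqB = 60L,
    stringsAsFactors = FALSE)
}

finish_pairs <- function(p, span = 101L) {
  p$endA <- p$posA + span - 1L
  p$endB <- p$posB + span - 1L
  p
}

# O(n^2) single-linkage oracle via explicit transitive closure
cluster_oracle <- function(p, window) {
  canon <- function(i) {
    keyA <- paste(p$contigA[i], sprintf("%012d", p$posA[i]))
    keyB <- paste(p$contigB[i], sprintf("%012d", p$posB[i]))
    if (keyA <= keyB)
      list(cA = p$contigA[i], sA = p$posA[i], eA = p$endA[i],
           cB = p$contigB[i], sB = p$posB[i], eB = p$endB[i])
    else
      list(cA = p$contigB[i], sA = p$posB[i], eA = p$endB[i],
           cB = p$contigA[i], sB = p$posA[i], eB = p$endA[i])
  }
  n <- nrow(p)
  cc <- lapply(seq_len(n), canon)
  gap <- function(s1, e1, s2, e2) max(0L, max(s1, s2) - min(e1, e2))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- cc[[i]]$cA == cc[[j]]$cA && cc[[i]]$cB == cc[[j]]$cB &&
      gap(cc[[i]]$sA, cc[[i]]$eA, cc[[j]]$sA, cc[[j]]$eA) <= window &&
      gap(cc[[i]]$sB, cc[[i]]$eB, cc[[j]]$sB, cc[[j]]$eB) <= window
  }
  reach <- adj
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { k <- k + 1L; comp[which(reach[i, ])] <- k; comp[i] <- k }
  }
  unname(split(p$read_id, comp))
}

membership <- function(clusters) {
  lapply(seq_len(nrow(clusters)),
         function(i) sort(strsplit(clusters$members[i], ";")[[1]]))
}

test_that("single-linkage clustering equals the brute-force oracle", {
  for (seed in 1:8) {
    n <- sample(10:50, 1)
    p <- finish_pairs(random_pairs(n, seed))
    window <- sample(c(200L, 800L, 2000L), 1)
    got <- membership(cluster_discordant_pairs(p, window = window))
    want <- lapply(cluster_oracle(p, window), sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    # no loss, no duplication: union of members equals input pairs
    expect_setequal(unlist(got), p$read_id)
  }
})

test_that("junction-bridging pairs form clusters with the expected support", {
  mk <- function(n, contigB, base, prefix) {
    finish_pairs(data.frame(
      read_id = sprintf("%s%02d", prefix, seq_len(n)),
      contigA = "chr2", posA = base + sample.int(300, n, replace = TRUE),
      strandA = "+", mapqA = 60L,
      contigB = contigB, posB = 5000L + sample.int(300, n, replace = TRUE),
      strandB = "-", mapqB = 60L, stringsAsFactors = FALSE))
  }
  set.seed(99)
  p <- rbind(mk(8L, "donor_beta", 10000L, "b"),
             mk(5L, "donor_alpha", 10400L, "a"))
  cl <- cluster_discordant_pairs(p, window = 800L)
  expect_identical(nrow(cl), 2L)
  expect_setequal(cl$support, c(8L, 5L))
  # pairs 10 windows apart on side A split into two clusters
  p2 <- rbind(mk(2L, "donor_beta", 10000L, "x"),
              mk(2L, "donor_beta", 10000L + 10L * 800L, "y"))
  expect_identical(nrow(cluster_discordant_pairs(p2, window = 800L)), 2L)
  expect_identical(nrow(cluster_discordant_pairs(NULL)), 0L)
})

test_that("depth-duplication scan matches a run-length oracle", {
  mk_profile <- function(depths, bin = 100L) {
    n <- length(depths)
    structure(list(
      bins = data.frame(contig = "c", start = seq(1L, by = bin, length.out = n),
                        end = seq(bin, by = bin, length.out = n),
                        depth = depths, stringsAsFactors = FALSE),
      bin = bin, contig_lengths = c(c = n * bin)), class = "depth_profile")
  }
  # uniform depth: no calls
  expect_identical(nrow(scan_depth_duplications(mk_profile(rep(8, 50)))), 0L)

  # one 3x plateau: boundaries match a brute-force run-length scan against
  # the covered-bin median baseline
  depths <- c(rep(8, 20), rep(24, 7), rep(8, 23))
  prof <- mk_profile(depths)
  calls <- scan_depth_duplications(prof, min_fold = 1.5)
  base <- median(depths[depths > 0])
  hot <- which(depths >= 1.5 * base)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start, (min(hot) - 1L) * 100L + 1L)
  expect_identical(calls$end, max(hot) * 100L)
  expect_equal(calls$rc, 24 / base)

  # zero coverage errors
  expect_error(scan_depth_duplications(mk_profile(rep(0, 10))), "zero")
})

test_that("filters mirror the support window and exclusion rules", {
  mk_cluster <- function(contigA, contigB, support, startA = 1000L,
                         startB = 1000L) {
    data.frame(contigA = contigA, startA = startA, endA = startA + 300L,
               contigB = contigB, startB = startB, endB = startB + 300L,
               support = support, mean_mapq = 60, split_support = 0L,
               members = "x", stringsAsFactors = FALSE)
  }
  cl <- rbind(mk_cluster("chr2", "donor_alpha", 4L),
              mk_cluster("chr2", "donor_alpha", 5L, startA = 40000L),
              mk_cluster("chr2", "donor_alpha", 16L, startA = 80000L),
              mk_cluster("chr2", "donor_alpha", 17L, startA = 120000L),
              mk_cluster("chrM", "donor_alpha", 8L, startA = 160000L),
              mk_cluster("chr2", "chr2", 8L, startA = 200000L))
  f <- apply_filters(cl, calls = NULL,
                     filter_config(excluded_contigs = "chrM"))
  expect_identical(f$reason[1], "support<5")
  expect_identical(f$reason[4], "support>16")
  expect_identical(f$reason[5], "excluded_contig")
  expect_identical(f$reason[6], "intra_chromosomal")
  expect_true(all(f$keep[c(2, 3)]))
  expect_error(filter_config(min_support = 10, max_support = 5),
               "min_support")

  # clusters with both sides inside duplications are artifacts of the array
  dup <- data.frame(contig = c("donor_alpha", "donor_beta"),
                    start = c(900L, 900L), end = c(1500L, 1500L), rc = c(9, 3),
                    stringsAsFactors = FALSE)
  cl2 <- rbind(mk_cluster("donor_alpha", "donor_beta", 8L),
               mk_cluster("chr2", "donor_alpha", 8L))
  f2 <- apply_filters(cl2, dup, filter_config())
  expect_identical(f2$reason[1], "both_sides_in_duplication")
  expect_true(f2$keep[2])
})

test_that("tightening the support window never adds candidates (monotone)", {
  set.seed(7)
  cl <- finish_pairs(random_pairs(40, 7))
  clusters <- cluster_discordant_pairs(cl, window = 1500L)
  kept <- function(lo, hi)
    sum(apply_filters(clusters, NULL,
                      filter_config(min_support = lo, max_support = hi,
                                    drop_intra_chrom = FALSE))$keep)
  for (lo in 1:3) for (hi in c(4L, 8L, 16L)) {
    expect_lte(kept(lo + 1L, hi), kept(lo, hi))
    expect_lte(kept(lo, hi - 1L), kept(lo, hi))
  }
})

test_that("candidate ranking matches the documented key", {
  mk <- function(id, split, support, startA, bridged_contig = "chr9") {
    data.frame(contigA = "chr2", startA = startA, endA = startA + 100L,
               contigB = bridged_contig, startB = 1000L, endB = 1100L,
               support = support, mean_mapq = 60, split_support = split,
               members = id, keep = TRUE, reason = NA_character_,
               stringsAsFactors = FALSE)
  }
  dup <- data.frame(contig = "donor_alpha", start = 900L, end = 1500L,
                    rc = 9, stringsAsFactors = FALSE)
  cl <- rbind(mk("a", 0L, 10L, 100L, "donor_alpha"),  # bridged, no splits
              mk("b", 5L, 6L, 200L, "donor_alpha"),   # splits + bridged
              mk("c", 5L, 6L, 150L, "chr9"),          # splits, unbridged
              mk("d", 5L, 6L, 120L, "chr9"))          # tie with c: coordinate
  r <- rank_candidates(cl, dup)
  # expected order by the documented key (split desc, bridged desc,
  # support desc, coordinates asc): b, then d/c by coordinate, then a
  expect_identical(r$members, c("b", "d", "c", "a"))
  # identical evidence resolves by coordinate order
  expect_lt(which(r$members == "d"), which(r$members == "c"))
})
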