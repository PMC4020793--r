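# helper to build minimal alignment rows
aln_row <- function(read_id, mate, contig, pos, strand = "+", mapq = 60L,
                    span = 101L, lclip = 0L, rclip = 0L,
                    seq = strrep("A", span + lclip + rclip)) {
  data.frame(read_id = read_id, mate = mate, contig = contig, pos = pos,
             end = pos + span - 1L, strand = strand, mapq = mapq,
             cigar = sprintf("%dM", span), lclip = lclip, rclip = rclip,
             aligned_span = span, seq = seq, mapped = TRUE,
             mate_contig = contig, mate_pos = pos, mate_strand = strand,
             mate_mapped = TRUE, stringsAsFactors = FALSE)
}

make_pair <- function(read_id, contigA, posA, strandA, contigB, posB, strandB,
                      mapqA = 60L, mapqB = 60L) {
  rbind(aln_row(read_id, 1L, contigA, posA, strandA, mapqA),
        aln_row(read_id, 2L, contigB, posB, strandB, mapqB))
}

test_that("insert model is robust and handles degenerate inputs", {
  # constant inserts: MAD floored at 1 bp so bounds stay usable
  m <- estimate_insert_model(rep(400, 300))
  expect_equal(m$median, 400)
  expect_true(m$lower < 400 && m$upper > 400)
  expect_lte(m$upper - m$lower, 2 * 3 * 1)

  # bimodal multiset {300 x 100, 500 x 100}: brute-force median/MAD
  x <- c(rep(300, 100), rep(500, 100))
  xs <- sort(x)
  med_bf <- (xs[100] + xs[101]) / 2
  mad_bf <- sort(abs(x - med_bf))
  mad_bf <- (mad_bf[100] + mad_bf[101]) / 2 * 1.4826
  m2 <- estimate_insert_model(x)
  expect_equal(m2$median, med_bf)
  expect_equal(m2$lower, med_bf - 3 * mad_bf)
  expect_equal(m2$upper, med_bf + 3 * mad_bf)

  # a wild outlier does not move the bounds (MAD insensitivity)
  m3 <- estimate_insert_model(c(rep(400, 299), 10000))
  expect_equal(m3$lower, m$lower)
  expect_equal(m3$upper, m$upper)

  # too few pairs: instructs explicit bounds
  expect_error(estimate_insert_model(rep(400, 50)), "explicit bounds")
  expect_error(insert_size_model(400, 10, 500, 600), "lower < median")
})

test_that("pair classification follows the concordance rules", {
  m <- insert_size_model(400, 30, 300, 500)

  # inter-chromosomal: mates on the insertion contig and a donor contig
  p <- make_pair("r1", "chr2", 1000L, "+", "donor_alpha", 5000L, "-")
  expect_identical(classify_pair(p[1, ], p[2, ], m), "discordant_interchrom")

  # same contig, inward, insert at the median: concordant
  p <- make_pair("r2", "chr2", 1000L, "+", "chr2", 1299L, "-")
  expect_identical(classify_pair(p[1, ], p[2, ], m), "concordant")

  # boundary case: insert exactly upper + 1
  p <- make_pair("r3", "chr2", 1000L, "+", "chr2", 1000L + 501L - 101L, "-")
  expect_identical(classify_pair(p[1, ], p[2, ], m), "discordant_size")

  # outward-facing mates violate orientation
  p <- make_pair("r4", "chr2", 1000L, "-", "chr2", 1300L, "+")
  expect_identical(classify_pair(p[1, ], p[2, ], m), "discordant_orientation")

  # mismatched read ids are an error
  a <- aln_row("r5", 1L, "chr2", 1L); b <- aln_row("r6", 2L, "chr2", 300L)
  expect_error(classify_pair(a, b, m), "read_id")
})

test_that("classification is symmetric in mate order", {
  m <- insert_size_model(400, 30, 300, 500)
  set.seed(42)
  for (i in 1:40) {
    contigs <- sample(c("chr2", "chr2", "donor_alpha"), 2, replace = TRUE)
    posA <- sample.int(5000, 1); posB <- sample.int(5000, 1)
    strands <- sample(c("+", "-"), 2, replace = TRUE)
    a <- aln_row("r", 1L, contigs[1], posA, strands[1])
    b <- aln_row("r", 2L, contigs[2], posB, strands[2])
    b2 <- a; b2$mate <- 2L
    a2 <- b; a2$mate <- 1L
    expect_identical(classify_pair(a, b, m), classify_pair(a2, b2, m))
  }
})

test_that("mapq gate flags non-unique pairs", {
  m <- insert_size_model(400, 30, 300, 500)
  p <- rbind(make_pair("r1", "chr2", 1000L, "+", "donor_alpha", 500L, "-",
                       mapqA = 60L, mapqB = 0L),
             make_pair("r2", "chr2", 1000L, "+", "donor_alpha", 500L, "-"))
  cls <- classify_pairs(p, m, min_mapq = 20L)
  expect_identical(cls$mapq_pass[cls$read_id == "r1"], FALSE)
  expect_identical(cls$mapq_pass[cls$read_id == "r2"], TRUE)
})

test_that("clip extraction follows length threshold and conventions", {
  r <- aln_row("r1", 1L, "chr2", 1000L, span = 60L, rclip = 41L,
               seq = paste0(strrep("A", 60), strrep("C", 41)))
  ev <- extract_clips(r, min_clip = 10L)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$side, "right")
  expect_identical(ev$boundary_pos, 1059L)  # last aligned base
  expect_identical(ev$clipped_seq, strrep("C", 41))

  # short clip below threshold yields nothing
  r2 <- aln_row("r2", 1L, "chr2", 1000L, span = 96L, rclip = 5L,
                seq = strrep("A", 101))
  expect_identical(nrow(extract_clips(r2, min_clip = 10L)), 0L)

  # clipped at both ends: two events; left clip boundary is pos - 1
  r3 <- aln_row("r3", 1L, "chr2", 1000L, span = 61L, lclip = 20L, rclip = 20L,
                seq = paste0(strrep("G", 20), strrep("A", 61), strrep("C", 20)))
  ev3 <- extract_clips(r3, min_clip = 10L)
  expect_identical(nrow(ev3), 2L)
  expect_setequal(ev3$side, c("left", "right"))
  expect_identical(ev3$boundary_pos[ev3$side == "left"], 999L)
  expect_identical(ev3$clipped_seq[ev3$side == "left"], strrep("G", 20))
})
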