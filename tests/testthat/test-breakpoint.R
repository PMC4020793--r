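test_that("microhomology recovers the pmel-1 junction motifs", {
  set.seed(31)
  flank <- paste0(random_dna_str(60), "CCAGCAG")
  cassette <- paste0("CCAGCAG", random_dna_str(60))
  mh <- compute_microhomology(flank, cassette, side = "left")
  expect_identical(mh$seq, "CCAGCAG")
  expect_identical(mh$length, 7L)

  cassette_r <- paste0(random_dna_str(60), "TGGAT")
  flank_r <- paste0("TGGAT", random_dna_str(60))
  mh_r <- compute_microhomology(flank_r, cassette_r, side = "right")
  expect_identical(mh_r$seq, "TGGAT")
  expect_identical(mh_r$length, 5L)

  # no shared sequence
  expect_identical(compute_microhomology("AAAA", "CCCC", "left")$length, 0L)
})

test_that("microhomology agrees with a brute-force scan on 1000 random cases", {
  set.seed(32)
  for (i in 1:1000) {
    k <- sample(0:12, 1)
    ov <- if (k > 0) random_dna_str(k) else ""
    flank <- paste0(random_dna_str(sample(10:40, 1)), ov)
    cass <- paste0(ov, random_dna_str(sample(10:40, 1)))
    got <- compute_microhomology(flank, cass, side = "left")
    expect_identical(got$seq, mh_oracle(flank, cass))
  }
})

test_that("microhomology is symmetric under reverse-complement with side swap", {
  set.seed(33)
  for (i in 1:50) {
    ov <- random_dna_str(sample(1:8, 1))
    flank <- paste0(random_dna_str(30), ov)
    cass <- paste0(ov, random_dna_str(30))
    a <- compute_microhomology(flank, cass, side = "left")
    b <- compute_microhomology(revcomp(flank), revcomp(cass), side = "right")
    expect_identical(a$length, b$length)
    expect_identical(b$seq, revcomp(a$seq))
  }
})

test_that("boundary resolution takes the modal clip position with ties low", {
  mk_clip <- function(pos, side = "right", seq = "ACGTACGTACGTACGT") {
    data.frame(read_id = "r", contig = "chr2", boundary_pos = pos,
               side = side, clipped_seq = seq, mapq = 60L,
               stringsAsFactors = FALSE)
  }
  clips <- rbind(mk_clip(100L), mk_clip(100L), mk_clip(101L))
  b <- resolve_boundary(clips, "left")
  expect_identical(b$coordinate, 100L)
  expect_identical(b$n_softclip, 2L)
  expect_identical(b$status, "exact")

  # ties break towards the smaller coordinate
  clips2 <- rbind(mk_clip(100L), mk_clip(101L))
  expect_identical(resolve_boundary(clips2, "left")$coordinate, 100L)

  # right boundary: left-side clips, coordinate is one past the stored
  # last-aligned-base position
  clips3 <- rbind(mk_clip(200L, "left"), mk_clip(200L, "left"))
  expect_identical(resolve_boundary(clips3, "right")$coordinate, 201L)

  # no clips: approximate midpoint fallback
  none <- clips[0, ]
  b4 <- resolve_boundary(none, "left", fallback_interval = c(100L, 200L),
                         contig = "chr2")
  expect_identical(b4$status, "approximate")
  expect_identical(b4$coordinate, 150L)
  expect_error(resolve_boundary(none, "left"), "no soft-clip")
})

test_that("clip consensus assigns the partner cassette through the homology shift", {
  set.seed(34)
  beta <- paste0("CCAGCAG", random_dna_str(300))
  alpha <- random_dna_str(300)
  # clipped tails continue into the cassette after its duplicated prefix
  tail7 <- substr(beta, 8L, 47L)
  clips <- data.frame(read_id = c("a", "b", "c"), contig = "chr2",
                      boundary_pos = 5000L, side = "right",
                      clipped_seq = c(tail7, substr(tail7, 1, 30),
                                      substr(tail7, 1, 35)),
                      mapq = 60L, stringsAsFactors = FALSE)
  b <- resolve_boundary(clips, "left",
                        cassettes = c(beta = beta, alpha = alpha))
  expect_identical(b$partner_cassette, "beta")
  expect_identical(b$mh_shift, 7L)
  expect_identical(b$status, "exact")

  # consensus that matches nothing leaves the call approximate
  junk <- data.frame(read_id = "x", contig = "chr2", boundary_pos = 5000L,
                     side = "right", clipped_seq = random_dna_str(40),
                     mapq = 60L, stringsAsFactors = FALSE)
  b2 <- resolve_boundary(junk, "left",
                         cassettes = c(beta = beta, alpha = alpha))
  expect_identical(b2$status, "approximate")
  expect_true(is.na(b2$partner_cassette))
})

test_that("insertion-call assembly reproduces the coordinate arithmetic", {
  mk_b <- function(coord, side) {
    structure(list(contig = "chr2", coordinate = coord, side = side,
                   partner_cassette = NA_character_,
                   n_discordant = 1L, n_softclip = 1L, clip_consensus = "",
                   status = "exact", mh_shift = NA_integer_),
              class = "boundary_call")
  }
  call <- assemble_insertion_call(mk_b(68208872L, "left"),
                                  mk_b(68209029L, "right"))
  expect_identical(call$deletion_length, 157L)
  expect_identical(call$status, "exact")

  expect_identical(
    assemble_insertion_call(mk_b(100L, "left"), mk_b(100L, "right"))$deletion_length,
    0L)

  other <- mk_b(500L, "right"); other$contig <- "chr3"
  expect_error(assemble_insertion_call(mk_b(100L, "left"), other),
               "different contigs")
})

test_that("synthetic runs recover the locus truth exactly across seeds", {
  exact <- 0L; errs <- integer(0)
  for (seed in 1:20) {
    run <- small_run(seed = 100L + seed)
    g <- run$genome
    # condition of the invariant: at least one junction-spanning clipped
    # read per boundary (flank- or donor-aligned)
    clips <- extract_clips(run$aln)
    fit <- locate_insertion(
      run$aln, contig_lengths(g), reference = g$reference_contigs,
      cassettes = cassette_seqs(g), cassette_loci = g$cassette_loci,
      contig_offsets = stats::setNames(g$truth$coordinate_offset,
                                       g$truth$insertion_contig),
      bootstrap_n = 50L)
    expect_false(is.null(fit$call))
    if (fit$call$status == "exact") {
      exact <- exact + 1L
      expect_identical(fit$call$left$coordinate, g$truth$left_frame)
      expect_identical(fit$call$right$coordinate, g$truth$right_frame)
      expect_identical(fit$call$left$partner_cassette, "beta")
      expect_identical(fit$call$right$partner_cassette, "alpha")
      expect_identical(fit$call$left_microhomology$seq, g$truth$left_dup_seq)
      expect_identical(fit$call$right_microhomology$seq, g$truth$right_dup_seq)
    }
    errs <- c(errs, fit$call$deletion_length - g$truth$deletion_length)
  }
  expect_identical(exact, 20L)
  # unbiased deletion-length recovery
  expect_identical(mean(errs), 0)
})
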