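test_that("allele construction matches independent bookkeeping", {
  spec <- small_spec(seed = 3)
  g <- build_alleles(spec, seed = 4)

  # wild-type allele is exactly the reference insertion contig
  expect_identical(g$wildtype_allele,
                   unname(g$reference_contigs[[spec$insertion_chrom_name]]))

  # length bookkeeping: deletion removes (right - left - 1) bases, the array
  # adds its expanded length minus one copy of each duplicated motif
  del_bases <- spec$right_boundary - spec$left_boundary - 1L
  array_len <- sum(nchar(spec$cassette_units$seq) *
                     spec$array_multiplicities[spec$cassette_units$cassette_id])
  expect_identical(nchar(g$transgenic_allele),
                   nchar(g$wildtype_allele) - del_bases + array_len -
                     nchar(spec$left_dup_seq) - nchar(spec$right_dup_seq))

  # junction sequence: flank ends with the left motif, then the first
  # cassette continues past its duplicated prefix (stored once physically)
  bl <- g$truth$left_local
  ldup <- spec$left_dup_seq
  expect_identical(substr(g$transgenic_allele, bl - nchar(ldup) + 1L, bl), ldup)
  beta <- spec$cassette_units$seq[spec$cassette_units$cassette_id == "beta"]
  expect_identical(substr(g$transgenic_allele, bl + 1L, bl + 20L),
                   substr(beta, nchar(ldup) + 1L, nchar(ldup) + 20L))
  # right junction mirror image
  tail_start <- nchar(g$transgenic_allele) -
    (nchar(g$wildtype_allele) - g$truth$right_local)
  expect_identical(substr(g$transgenic_allele, tail_start,
                          tail_start + nchar(spec$right_dup_seq) - 1L),
                   spec$right_dup_seq)
})

test_that("single-cassette allele length agrees with a concatenation oracle", {
  # 1 copy of a 500-bp cassette, 157-bp coordinate-difference deletion,
  # duplicated motifs of 7 and 5 bp
  set.seed(11)
  unit <- paste0("CCAGCAG", random_dna_str(500 - 12), "TGGAT")
  spec <- locus_spec(
    left_boundary = 68208872L, right_boundary = 68209029L,
    cassette_units = data.frame(cassette_id = "u", seq = unit,
                                orientation = "+", stringsAsFactors = FALSE),
    array_multiplicities = c(u = 1L), flank_length = 2000L)
  g <- build_alleles(spec, seed = 12)
  W <- g$wildtype_allele
  bl <- g$truth$left_local; br <- g$truth$right_local
  oracle <- paste0(substr(W, 1L, bl), substr(unit, 8L, 495L),
                   substr(W, br, nchar(W)))
  expect_identical(g$transgenic_allele, oracle)
})

test_that("zero cassette copies with unit deletion reproduce the wild type", {
  spec <- locus_spec(
    left_boundary = 1000L, right_boundary = 1001L,
    left_dup_seq = "", right_dup_seq = "",
    cassette_units = data.frame(cassette_id = "u", seq = "ACGTACGTACGT",
                                orientation = "+", stringsAsFactors = FALSE),
    array_multiplicities = c(u = 0L), flank_length = 800L)
  g <- build_alleles(spec, seed = 5)
  expect_identical(g$transgenic_allele, g$wildtype_allele)
})

test_that("inconsistent duplicated motifs raise an error naming the side", {
  units <- data.frame(cassette_id = "u",
                      seq = paste0("AAAA", random_dna_str(492, seed = 6),
                                   "TGGAT"),
                      orientation = "+", stringsAsFactors = FALSE)
  spec <- locus_spec(cassette_units = units,
                     array_multiplicities = c(u = 2L), flank_length = 2000L)
  expect_error(build_alleles(spec), "left")
  units$seq <- paste0("CCAGCAG", random_dna_str(492, seed = 7), "CCCC")
  spec <- locus_spec(cassette_units = units,
                     array_multiplicities = c(u = 2L), flank_length = 2000L)
  expect_error(build_alleles(spec), "right")
})

test_that("read simulation honours coverage, determinism and purity", {
  spec <- small_spec(seed = 2, flank_length = 50000L,
                     alpha_copies = 0L, beta_copies = 0L,
                     left_dup_seq = "", right_dup_seq = "",
                     left_boundary = 68208872L,
                     right_boundary = 68208873L)
  g <- build_alleles(spec, seed = 2)
  p <- small_params(seed = 21, depth = 8, genotype = "wt")
  sim <- simulate_read_pairs(g, p)

  # expected pair count within 3 Poisson SDs of depth * L / (2 * read_len)
  L <- nchar(g$wildtype_allele)
  lambda <- p$depth * L / (2 * p$read_length)
  expect_lt(abs(nrow(sim$reads) - lambda), 3 * sqrt(lambda))

  # mean depth over the contig within 5% of the target
  aln <- emit_oracle_alignments(g, sim)
  prof <- compute_depth_profile(aln, contig_lengths(g), bin = 500)
  ins <- prof$bins[prof$bins$contig == spec$insertion_chrom_name, ]
  w <- ins$end - ins$start + 1
  expect_lt(abs(sum(ins$depth * w) / sum(w) - p$depth) / p$depth, 0.05)

  # determinism: same seed, byte-identical output
  sim2 <- simulate_read_pairs(g, p)
  expect_identical(sim, sim2)

  # error_rate 0: every read is an exact substring of its source allele
  ok1 <- mapply(function(s, e, rd) substr(g$wildtype_allele, s, s + 100L) == rd,
                sim$truth$frag_start, sim$truth$frag_end,
                sim$reads$seq1)
  expect_true(all(ok1))
  ok2 <- mapply(function(e, rd) substr(g$wildtype_allele, e - 100L, e) ==
                  revcomp(rd),
                sim$truth$frag_end, sim$reads$seq2)
  expect_true(all(ok2))
})

test_that("oracle alignments place clips exactly at true junctions", {
  run <- small_run(seed = 13)
  g <- run$genome
  clips <- extract_clips(run$aln)
  ins <- clips[clips$contig == g$truth$insertion_contig, ]
  # on the insertion contig, every clip marks a true boundary
  expect_true(all(ins$boundary_pos[ins$side == "right"] == g$truth$left_local))
  expect_true(all(ins$boundary_pos[ins$side == "left"] ==
                    g$truth$right_local - 1L))

  # a flank-interior read is concordant with no clips
  interior <- run$aln[run$aln$contig == g$truth$insertion_contig &
                        run$aln$end < g$truth$left_local - 200L, ]
  expect_true(nrow(interior) > 0)
  expect_true(all(interior$lclip == 0L & interior$rclip == 0L))
})

test_that("discordant inter-contig pairs all straddle a junction (no false positives)", {
  run <- small_run(seed = 17)
  g <- run$genome
  model <- estimate_insert_model(run$aln)
  pairs <- classify_pairs(run$aln, model)
  inter <- pairs[pairs$class == "discordant_interchrom", ]
  expect_gt(nrow(inter), 0)

  # brute force from truth tags: a transgenic fragment straddles a junction
  # iff it overlaps two segments assigned to different reference contigs
  segs <- g$segments
  tr <- run$sim$truth
  straddles <- vapply(seq_len(nrow(tr)), function(i) {
    if (tr$kind[i] != "tg") return(FALSE)
    ov <- segs$a_start <= tr$frag_end[i] & segs$a_end >= tr$frag_start[i]
    length(unique(segs$contig[ov])) > 1
  }, TRUE)
  names(straddles) <- tr$read_id
  expect_true(all(straddles[inter$read_id]))
})

test_that("het genotype shows both junction signatures, wt none", {
  run_het <- small_run(seed = 23, param_args = list(genotype = "het"))
  clips <- extract_clips(run_het$aln)
  g <- run_het$genome
  ins <- clips[clips$contig == g$truth$insertion_contig, ]
  expect_true(any(ins$boundary_pos == g$truth$left_local & ins$side == "right") ||
                any(run_het$aln$contig == "donor_beta" & run_het$aln$lclip >= 10))
  model <- estimate_insert_model(run_het$aln)
  pairs <- classify_pairs(run_het$aln, model)
  expect_gt(sum(pairs$class == "discordant_interchrom"), 0)

  run_wt <- small_run(seed = 23, param_args = list(genotype = "wt"))
  model_wt <- estimate_insert_model(run_wt$aln)
  pairs_wt <- classify_pairs(run_wt$aln, model_wt)
  expect_identical(sum(pairs_wt$class == "discordant_interchrom"), 0L)
  expect_identical(nrow(extract_clips(run_wt$aln)), 0L)
})
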