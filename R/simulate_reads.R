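#' Read-simulation parameters
#'
#' @param read_length Read length in bp (default 101, matching 2x101 bp
#'   paired-end sequencing).
#' @param insert_mean,insert_sd Fragment (outer insert) size distribution in
#'   bp; fragments are Normal(`insert_mean`, `insert_sd`) truncated below at
#'   `read_length`.
#' @param depth Target fold coverage of the sampled diploid genome
#'   (default 8).
#' @param error_rate Per-base substitution probability (default 0.002).
#' @param seed Integer seed; all simulation randomness flows from it
#'   (default 8).
#' @param genotype One of `"hom"`, `"het"`, `"wt"`: the diploid genotype of
#'   the sampled animal.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 101L, insert_mean = 400,
                            insert_sd = 40, depth = 8, error_rate = 0.002,
                            seed = 8L, genotype = c("hom", "het", "wt")) {
  genotype <- match.arg(genotype)
  read_length <- as.integer(read_length)
  if (read_length > insert_mean)
    stop("read_length must not exceed insert_mean", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.1)
    stop("error_rate must be in [0, 0.1)", call. = FALSE)
  structure(list(read_length = read_length, insert_mean = insert_mean,
                 insert_sd = insert_sd, depth = depth,
                 error_rate = error_rate, seed = as.integer(seed),
                 genotype = genotype),
            class = "read_sim_params")
}

# substitution errors, applied to forward-strand fragment substrings
apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0)) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(s), n_err[i])
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate paired-end reads from a diploid sample
#'
#' Draws read pairs uniformly from the two haplotypes implied by the
#' genotype (`hom` = two transgenic alleles, `het` = one transgenic + one
#' wild-type, `wt` = two wild-type). When a cassette has
#' `endogenous_copies == 1`, each haplotype additionally contributes its
#' donor contig, emulating an intact endogenous locus. Fragment lengths are
#' Normal(insert_mean, insert_sd) truncated at the read length; substitution
#' errors are i.i.d. per base. Each pair carries a truth tag (source
#' sequence and fragment coordinates) used by the oracle aligner and by
#' tests.
#'
#' @param genome A `sim_genome` from [build_alleles()].
#' @param params A [read_sim_params()].
#' @return Object of class `sim_reads`: list with `reads` (data.frame:
#'   read_id, seq1, seq2 — seq2 is the reverse strand mate as sequenced) and
#'   `truth` (read_id, source, kind, frag_start, frag_end), plus `params`.
#' @export
simulate_read_pairs <- function(genome, params) {
  stopifnot(inherits(genome, "sim_genome"), inherits(params, "read_sim_params"))
  set.seed(params$seed)
  rl <- params$read_length
  haps <- switch(params$genotype,
                 hom = c("tg", "tg"), het = c("tg", "wt"), wt = c("wt", "wt"))
  endo <- genome$truth$spec$endogenous_copies
  sources <- list()
  for (h in seq_along(haps)) {
    kind <- haps[h]
    seq <- if (kind == "tg") genome$transgenic_allele else genome$wildtype_allele
    sources[[paste0("hap", h, ".", kind)]] <- list(kind = kind, seq = seq)
    for (id in names(endo)) {
      if (endo[[id]] == 1L) {
        dn <- paste0("donor_", id)
        sources[[paste0("hap", h, ".", dn)]] <-
          list(kind = dn, seq = genome$reference_contigs[[dn]])
      }
    }
  }
  depth_per_hap <- params$depth / length(haps)

  reads <- list(); truth <- list()
  for (label in names(sources)) {
    src <- sources[[label]]
    len <- nchar(src$seq)
    if (len < params$insert_mean)
      stop("source sequence '", label, "' shorter than the mean insert",
           call. = FALSE)
    n <- stats::rpois(1, depth_per_hap * len / (2 * rl))
    if (n == 0) next
    frag <- as.integer(pmin(pmax(round(stats::rnorm(n, params$insert_mean,
                                                    params$insert_sd)), rl),
                            len))
    start <- as.integer(1L + floor(stats::runif(n) * (len - frag + 1L)))
    end <- start + frag - 1L
    m1 <- substring(src$seq, start, start + rl - 1L)
    m2f <- substring(src$seq, end - rl + 1L, end)  # forward-strand view
    m1 <- apply_errors(m1, params$error_rate)
    m2f <- apply_errors(m2f, params$error_rate)
    ids <- sprintf("%s_%06d", label, seq_len(n))
    reads[[label]] <- data.frame(read_id = ids, seq1 = m1, seq2 = revcomp(m2f),
                                 stringsAsFactors = FALSE)
    truth[[label]] <- data.frame(read_id = ids, source = label,
                                 kind = src$kind, frag_start = start,
                                 frag_end = end, stringsAsFactors = FALSE)
  }
  structure(list(reads = do.call(rbind, c(reads, list(make.row.names = FALSE))),
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 params = params),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("Simulated paired-end reads: %d pairs, %d bp, genotype %s, seed %d\n",
              nrow(x$reads), x$params$read_length, x$params$genotype,
              x$params$seed))
  invisible(x)
}

#' Write simulated pairs as FASTQ mate files
#'
#' @param sim A `sim_reads` object.
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (Phred+33, constant quality) plus a truth sidecar
#'   `<prefix>_truth.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_fastq_pairs <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_reads"))
  paths <- c(paste0(prefix, "_1.fastq"), paste0(prefix, "_2.fastq"),
             paste0(prefix, "_truth.tsv"))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(sim$reads[[paste0("seq", m)]])
    names(seqs) <- paste0(sim$reads$read_id, "/", m)
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, paths[m], format = "fastq",
                                qualities = qual)
  }
  utils::write.table(sim$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
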