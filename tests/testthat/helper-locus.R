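# Shared fixtures, built in code. The "small" locus keeps per-test
# simulations fast (about 500 pairs at 8X); geometry (boundary coordinates,
# duplicated motifs, array order) matches the default world.

small_spec <- function(seed = 8L, alpha_copies = 4L, beta_copies = 2L,
                       alpha_length = 1200L, beta_length = 1300L,
                       flank_length = 3000L, ...) {
  simulate_locus_spec(seed = seed, alpha_copies = alpha_copies,
                      beta_copies = beta_copies, alpha_length = alpha_length,
                      beta_length = beta_length, flank_length = flank_length,
                      ...)
}

small_params <- function(seed = 8L, ...) {
  args <- list(...)
  defaults <- list(read_length = 101L, insert_mean = 300, insert_sd = 30,
                   depth = 8, error_rate = 0, seed = seed)
  do.call(read_sim_params, utils::modifyList(defaults, args))
}

small_run <- function(seed = 8L, spec_args = list(), param_args = list()) {
  spec <- do.call(small_spec, c(list(seed = seed), spec_args))
  genome <- build_alleles(spec, seed = seed + 1000L)
  params <- do.call(small_params, c(list(seed = seed + 2000L), param_args))
  sim <- simulate_read_pairs(genome, params)
  aln <- emit_oracle_alignments(genome, sim)
  list(spec = spec, genome = genome, params = params, sim = sim, aln = aln)
}

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent longest-overlap oracle: enumerate all suffix/prefix pairs
mh_oracle <- function(a, b, max_len = 50L) {
  suff <- vapply(seq_len(min(nchar(a), max_len)),
                 function(k) substr(a, nchar(a) - k + 1L, nchar(a)), "")
  pref <- vapply(seq_len(min(nchar(b), max_len)),
                 function(k) substr(b, 1L, k), "")
  best <- ""
  for (k in seq_along(suff)) {
    if (k <= length(pref) && suff[k] == pref[k]) best <- pref[k]
  }
  best
}
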