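# Small internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence") {
  if (length(x) != 1 || is.na(x) || !is.character(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(x) > 0 && grepl("[^ACGT]", x))
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  invisible(x)
}

# Mode with ties broken towards the smaller value.
stat_mode <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

# Cheap deterministic hash for config provenance lines in output files.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Parse CIGAR strings: returns a data.frame with left/right soft-clip lengths
# and the span on the reference (M/D/N/=/X operations).
parse_cigar <- function(cigar) {
  n <- length(cigar)
  lclip <- integer(n); rclip <- integer(n); span <- integer(n)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) == 0) next
    len <- as.integer(sub("[A-Z=]$", "", tk))
    op <- substr(tk, nchar(tk), nchar(tk))
    if (op[1] == "S") lclip[i] <- len[1]
    if (length(tk) > 1 && op[length(op)] == "S") rclip[i] <- len[length(len)]
    span[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  }
  data.frame(lclip = lclip, rclip = rclip, ref_span = span)
}

# interval distance: 0 when overlapping, else gap size
interval_dist <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
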