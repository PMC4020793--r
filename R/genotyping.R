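#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` in degrees C — the classic rule of thumb, adequate
#' for short (roughly 14-30 nt) primers at standard salt; no
#' nearest-neighbour thermodynamics.
#'
#' @param seq Primer sequence(s), 5'->3'.
#' @return Numeric Tm estimate(s).
#' @export
primer_tm <- function(seq) {
  at <- nchar(gsub("[GC]", "", seq))
  gc <- nchar(seq) - at
  2 * at + 4 * gc
}

#' Locate primer binding sites on a template
#'
#' Finds occurrences of the primer on the plus strand and of its reverse
#' complement on the minus strand, allowing up to `max_mismatch`
#' substitutions except in the 3'-terminal 3 bases, which must match exactly
#' (extension chemistry).
#'
#' @param template Template sequence (character).
#' @param primer Primer sequence 5'->3'.
#' @param max_mismatch Allowed mismatches (default 0).
#' @return Data.frame: start, end (1-based template coordinates of the
#'   site), strand.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 0L) {
  check_dna(toupper(primer), "primer")
  primer <- toupper(primer)
  subj <- Biostrings::DNAString(toupper(template))
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
    if (length(hits) == 0) next
    st <- Biostrings::start(hits); en <- Biostrings::end(hits)
    if (max_mismatch > 0) {
      # 3' terminal 3 bases exact: template end for +, template start for -
      ok <- vapply(seq_along(st), function(i) {
        site <- substr(as.character(subj), st[i], en[i])
        if (strand == "+")
          substr(site, nchar(site) - 2L, nchar(site)) ==
            substr(pat, nchar(pat) - 2L, nchar(pat))
        else substr(site, 1L, 3L) == substr(pat, 1L, 3L)
      }, TRUE)
      st <- st[ok]; en <- en[ok]
    }
    if (length(st))
      out[[strand]] <- data.frame(start = st, end = en, strand = strand,
                                  stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Predict PCR amplicons on a template
#'
#' Every plus-strand site of any primer paired with any downstream
#' minus-strand site of any primer yields a product, provided its length
#' (measured 5' end to 5' end inclusive, the gel-size convention) does not
#' exceed `max_len` and is at least the summed primer lengths.
#'
#' @param template Template sequence.
#' @param primers Named character vector of primer sequences, or a
#'   data.frame with columns `name` and `seq`.
#' @param template_name Label carried into the predictions.
#' @param max_len Maximum product size (default 3000).
#' @param max_mismatch Passed to [find_primer_sites()].
#' @return Data.frame: template_name, forward_primer, reverse_primer, start,
#'   end, length.
#' @export
predict_amplicons <- function(template, primers, template_name = "template",
                              max_len = 3000L, max_mismatch = 0L) {
  if (is.data.frame(primers))
    primers <- stats::setNames(primers$seq, primers$name)
  sites <- lapply(primers, find_primer_sites, template = template,
                  max_mismatch = max_mismatch)
  out <- list()
  for (f in names(primers)) {
    fs <- sites[[f]][sites[[f]]$strand == "+", , drop = FALSE]
    if (nrow(fs) == 0) next
    for (r in names(primers)) {
      rs <- sites[[r]][sites[[r]]$strand == "-", , drop = FALSE]
      if (nrow(rs) == 0) next
      for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
        len <- rs$end[j] - fs$start[i] + 1L
        if (len >= nchar(primers[[f]]) + nchar(primers[[r]]) &&
            len <= max_len) {
          out[[length(out) + 1L]] <- data.frame(
            template_name = template_name, forward_primer = f,
            reverse_primer = r, start = fs$start[i], end = rs$end[j],
            length = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(template_name = character(0),
                      forward_primer = character(0),
                      reverse_primer = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$length), , drop = FALSE]
}

#' Map a band pattern to a zygosity call
#'
#' The transgenic band alone indicates a homozygote, the endogenous
#' (wild-type) band alone a wild-type animal, both a heterozygote; an empty
#' set or any band matching neither expectation is uninterpretable.
#'
#' @param bands Numeric vector of observed product sizes (bp).
#' @param transgenic_band,endogenous_band Expected sizes (defaults 308 and
#'   203, the junction and flank products of the validated assay).
#' @param tol Size-matching tolerance in bp (default 10).
#' @return List of class `genotype_call`: `bands` and `call` in
#'   homozygous/heterozygous/wildtype/uninterpretable.
#' @export
call_zygosity <- function(bands, transgenic_band = 308L,
                          endogenous_band = 203L, tol = 10L) {
  bands <- unique(as.numeric(bands))
  is_tg <- abs(bands - transgenic_band) <= tol
  is_en <- abs(bands - endogenous_band) <= tol
  call <- if (length(bands) == 0 || any(!is_tg & !is_en)) "uninterpretable"
  else if (any(is_tg) && any(is_en)) "heterozygous"
  else if (any(is_tg)) "homozygous"
  else "wildtype"
  structure(list(bands = sort(bands), call = call), class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("Genotype: %s  (bands: %s bp)\n", x$call,
              if (length(x$bands)) paste(x$bands, collapse = ", ") else "none"))
  invisible(x)
}

#' Predict the band set of a diploid genotype
#'
#' Runs [predict_amplicons()] on each allele template of the genotype and
#' unions the product sizes — the in-silico analogue of one PCR lane.
#'
#' @param alleles Named character vector of allele templates (e.g.
#'   `c(transgenic = ..., wildtype = ...)`).
#' @param genotype Character vector of allele names making up the diploid
#'   (e.g. `c("transgenic", "wildtype")` for a heterozygote).
#' @param primers Named primer vector or data.frame (see
#'   [predict_amplicons()]).
#' @param ... Passed to [predict_amplicons()].
#' @return Sorted numeric vector of unique predicted band sizes.
#' @export
predict_genotype_bands <- function(alleles, genotype, primers, ...) {
  preds <- lapply(unique(genotype), function(a)
    predict_amplicons(alleles[[a]], primers, template_name = a, ...))
  sort(unique(unlist(lapply(preds, `[[`, "length"))))
}

# candidate primers at a fixed 3' (for forward) or 5'-anchored site end,
# scanning lengths; returns first sequence meeting the Tm window or NULL
tm_ok <- function(seq, tm_range) {
  tm <- primer_tm(seq)
  tm >= tm_range[1] & tm <= tm_range[2]
}

#' Design the three-primer zygosity assay
#'
#' Designs, from the resolved junction geometry, one forward primer in the
#' retained left flank (shared by both alleles), one reverse primer inside
#' the host segment deleted by the integration (so it amplifies the
#' wild-type allele only), and one reverse primer inside the
#' junction-proximal cassette sequence (transgenic allele only). Together
#' they give a wild-type-only band of `endogenous_product` bp, a
#' transgenic-only band of `transgenic_product` bp, and both bands in a
#' heterozygote.
#'
#' @param wt_template Wild-type allele sequence.
#' @param tg_template Transgenic allele sequence.
#' @param left_boundary Position (local, 1-based) of the last retained
#'   left-flank base; identical in both templates, which share the left
#'   flank.
#' @param endogenous_product,transgenic_product Target product sizes
#'   (defaults 203 and 308 bp, which differ by more than the required 30 bp).
#' @param primer_len Allowed primer lengths, `c(min, max)` (default 18-27).
#' @param tm_range Wallace-rule Tm window in degrees C (default 55-65).
#' @param min_product_gap Minimum size difference between the two products
#'   (default 30 bp).
#' @param max_amp Amplifiable-size cap (default 3000 bp, matching
#'   [predict_amplicons()]): the cassette-side reverse primer necessarily
#'   recurs in every tandem unit copy, so uniqueness is required only within
#'   this window — ladder products from deeper copies must exceed it, as in
#'   a real assay where vector-scale units make them unamplifiable.
#' @return Data.frame of class `primer_set`: name, seq, length, tm, expected
#'   product per primer role, plus attributes `products`.
#' @export
design_primers <- function(wt_template, tg_template, left_boundary,
                           endogenous_product = 203L,
                           transgenic_product = 308L,
                           primer_len = c(18L, 27L), tm_range = c(55, 65),
                           min_product_gap = 30L, max_amp = 3000L) {
  if (tm_range[1] > tm_range[2])
    stop("empty Tm window", call. = FALSE)
  bl <- as.integer(left_boundary)
  if (bl < 400L)
    stop("left flank shorter than 400 bp", call. = FALSE)
  if (nchar(tg_template) - bl < 400L)
    stop("transgenic sequence right of the boundary shorter than 400 bp",
         call. = FALSE)
  if (abs(endogenous_product - transgenic_product) < min_product_gap)
    stop("target products differ by less than ", min_product_gap, " bp",
         call. = FALSE)
  lens <- seq(primer_len[1], primer_len[2])
  # wild-type-only reverse site must sit beyond the boundary (absent from
  # the transgenic allele); find where the templates diverge
  fail <- "no forward primer with Tm in range and unique binding"
  depth <- 1L  # deepest design stage reached, for the error message

  unique_sites <- function(primer, template, strand, n = 1L) {
    s <- find_primer_sites(template, primer)
    sum(s$strand == strand) == n && sum(s$strand != strand) == 0
  }

  # forward start range: primer fits in the shared flank, the wild-type
  # reverse site ends beyond the boundary (inside sequence the transgenic
  # allele lost), and both products fit their templates
  f_lo <- max(1L, bl + primer_len[1] - endogenous_product + 1L)
  f_hi <- min(bl - primer_len[1] + 1L,
              nchar(wt_template) - endogenous_product + 1L,
              nchar(tg_template) - transgenic_product + 1L)
  if (f_hi < f_lo) stop(fail, call. = FALSE)
  f_starts <- seq.int(f_lo, f_hi)
  for (fs in f_starts) {
    fwd <- NULL
    for (L in lens) {
      if (fs + L - 1L > bl) next  # forward primer stays in the shared flank
      cand <- substr(wt_template, fs, fs + L - 1L)
      if (tm_ok(cand, tm_range) && unique_sites(cand, wt_template, "+") &&
          unique_sites(cand, tg_template, "+")) { fwd <- cand; break }
    }
    if (is.null(fwd)) next
    if (depth < 2L) { depth <- 2L
      fail <- "no wild-type-only reverse primer (deleted segment) with Tm in range" }
    r_wt <- NULL
    wt_end <- fs + endogenous_product - 1L
    for (L in lens) {
      st <- wt_end - L + 1L
      if (st <= bl) next  # site must be absent from the transgenic allele
      site <- substr(wt_template, st, wt_end)
      cand <- revcomp(site)
      if (tm_ok(cand, tm_range) && unique_sites(cand, wt_template, "-") &&
          nrow(find_primer_sites(tg_template, cand)) == 0) { r_wt <- cand; break }
    }
    if (is.null(r_wt)) next
    if (depth < 3L) { depth <- 3L
      fail <- "no cassette-side reverse primer with Tm in range and a unique amplifiable product" }
    r_tg <- NULL
    tg_end <- fs + transgenic_product - 1L
    for (L in lens) {
      st <- tg_end - L + 1L
      if (st <= bl) next  # site must lie in cassette sequence
      site <- substr(tg_template, st, tg_end)
      cand <- revcomp(site)
      if (!tm_ok(cand, tm_range)) next
      s <- find_primer_sites(tg_template, cand)
      if (any(s$strand == "+") || !any(s$strand == "-")) next
      # one amplifiable product only; ladder products from deeper tandem
      # copies must exceed the amplifiable window
      prods <- s$end[s$strand == "-"] - fs + 1L
      if (sum(prods <= max_amp) != 1L || prods[which.min(prods)] != transgenic_product) next
      if (nrow(find_primer_sites(wt_template, cand)) > 0) next
      r_tg <- cand; break
    }
    if (is.null(r_tg)) next
    set <- data.frame(
      name = c("flank_F", "flank_R", "cassette_R"),
      seq = c(fwd, r_wt, r_tg),
      length = nchar(c(fwd, r_wt, r_tg)),
      tm = primer_tm(c(fwd, r_wt, r_tg)),
      role = c("forward (shared flank)", "reverse (wild-type only)",
               "reverse (transgenic only)"),
      stringsAsFactors = FALSE)
    attr(set, "products") <- c(endogenous = endogenous_product,
                               transgenic = transgenic_product)
    class(set) <- c("primer_set", "data.frame")
    return(set)
  }
  stop(fail, call. = FALSE)
}
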