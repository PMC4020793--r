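#' Pipeline configuration
#'
#' A single flat configuration document for [run_pipeline()]. By default the
#' run is fully synthetic: a locus is generated, reads simulated and
#' oracle-aligned; alternatively `input_sam` supplies externally aligned
#' reads (the simulate and genotype stages are then skipped).
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed; every stage's randomness derives from it.
#' @param locus Named list of overrides for [simulate_locus_spec()].
#' @param sim Named list of overrides for [read_sim_params()].
#' @param filters A [filter_config()].
#' @param input_sam Optional path to an externally aligned SAM/BAM.
#' @param genotype_stage Run primer design + in-silico genotyping
#'   (default TRUE; synthetic runs only).
#' @param write_fastq Also write the simulated reads as FASTQ (default
#'   FALSE).
#' @param min_mapq,min_clip,bin,dup_min_fold Stage parameters (see
#'   [locate_insertion()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("tgmap_run_"), seed = 8L,
                            locus = list(), sim = list(),
                            filters = filter_config(), input_sam = NULL,
                            genotype_stage = TRUE, write_fastq = FALSE,
                            min_mapq = 20L, min_clip = 10L, bin = 200L,
                            dup_min_fold = 1.5) {
  if (!is.null(input_sam) && !file.exists(input_sam))
    stop("input_sam does not exist: ", input_sam, call. = FALSE)
  structure(list(outdir = outdir, seed = as.integer(seed), locus = locus,
                 sim = sim, filters = filters, input_sam = input_sam,
                 genotype_stage = genotype_stage, write_fastq = write_fastq,
                 min_mapq = min_mapq, min_clip = min_clip, bin = bin,
                 dup_min_fold = dup_min_fold),
            class = "pipeline_config")
}

#' Run the full integration-site pipeline
#'
#' Executes the stages in workflow order — simulate (or ingest), classify,
#' scan, resolve, copy number, genotype — writing standard-format reports
#' into `config$outdir` (SAM, TSVs, VCF, BED, bedGraph) plus a
#' machine-readable JSON summary with the per-stage record counts (the
#' evidence funnel). Every output carries the config hash and seed. A stage
#' failure halts the run with the failing stage named; outputs of completed
#' stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `tgmap_run`: list with `fit`
#'   ([locate_insertion()] result), `summary` (what the JSON contains),
#'   `genome` (synthetic runs), and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hashable <- config[setdiff(names(config), "outdir")]
  meta <- c(config = config_hash(hashable), seed = as.character(config$seed))
  pth <- function(f) file.path(config$outdir, f)
  paths <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  genome <- NULL; truth <- NULL; aln <- NULL; lens <- NULL
  if (is.null(config$input_sam)) {
    stage("simulate", {
      spec <- do.call(simulate_locus_spec,
                      c(list(seed = config$seed), config$locus))
      genome <- build_alleles(spec, seed = config$seed + 1L)
      params <- do.call(read_sim_params,
                        c(list(seed = config$seed + 2L), config$sim))
      sim <- simulate_read_pairs(genome, params)
      aln <- emit_oracle_alignments(genome, sim)
      lens <- contig_lengths(genome)
      write_sam(aln, lens, pth("alignments.sam"), meta = meta)
      paths <- c(paths, pth("alignments.sam"))
      if (config$write_fastq)
        paths <- c(paths, write_fastq_pairs(sim, pth("reads")))
    })
    truth <- genome$truth
  } else {
    stage("ingest", {
      rs <- read_sam(config$input_sam)
      aln <- rs$alignments
      lens <- rs$contig_lengths
    })
  }

  fit <- stage("analyse", locate_insertion(
    aln, lens,
    reference = if (!is.null(genome)) genome$reference_contigs,
    cassettes = if (!is.null(genome)) cassette_seqs(genome),
    cassette_loci = if (!is.null(genome)) genome$cassette_loci,
    contig_offsets = if (!is.null(genome))
      stats::setNames(truth$coordinate_offset, truth$insertion_contig),
    min_mapq = config$min_mapq, min_clip = config$min_clip,
    bin = config$bin, dup_min_fold = config$dup_min_fold,
    filters = config$filters, seed = config$seed + 3L))

  stage("report", {
    pairs <- classify_pairs(aln, fit$insert_model, config$min_mapq)
    write_tgmap_tsv(pairs, pth("pairs.tsv"), meta)
    write_tgmap_tsv(fit$clips, pth("clips.tsv"), meta)
    write_tgmap_tsv(fit$clusters, pth("clusters.tsv"), meta)
    rej <- fit$clusters[!fit$clusters$keep, , drop = FALSE]
    write_tgmap_tsv(rej[, c("contigA", "startA", "endA", "contigB", "startB",
                            "endB", "support", "reason")],
                    pth("rejections.tsv"), meta)
    write_tgmap_tsv(fit$candidates, pth("candidates.tsv"), meta)
    write_tgmap_tsv(fit$dup_calls, pth("duplications.tsv"), meta)
    write_bedgraph(fit$profile, pth("depth.bedGraph"), meta)
    if (!is.null(fit$copy_folds))
      write_tgmap_tsv(fit$copy_folds, pth("copy_folds.tsv"), meta)
    if (!is.null(fit$call)) {
      write_insertion_vcf(fit$call, pth("insertion.vcf"),
                          contig_lengths = lens, meta = meta)
      write_bed(data.frame(contig = fit$call$contig,
                           start = fit$call$left$coordinate + 1L,
                           end = fit$call$right$coordinate - 1L,
                           name = "deleted_interval"),
                pth("deletion.bed"), meta)
    }
    paths <- c(paths, pth(c("pairs.tsv", "clips.tsv", "clusters.tsv",
                             "rejections.tsv", "candidates.tsv",
                             "duplications.tsv", "depth.bedGraph")))
  })

  geno <- NULL
  if (config$genotype_stage && !is.null(genome)) {
    geno <- stage("genotype", {
      primers <- design_primers(genome$wildtype_allele,
                                genome$transgenic_allele,
                                left_boundary = truth$left_local)
      write_tgmap_tsv(primers, pth("primers.tsv"), meta)
      alleles <- c(transgenic = genome$transgenic_allele,
                   wildtype = genome$wildtype_allele)
      pv <- stats::setNames(primers$seq, primers$name)
      genos <- list(hom = c("transgenic", "transgenic"),
                    het = c("transgenic", "wildtype"),
                    wt = c("wildtype", "wildtype"))
      rows <- lapply(names(genos), function(g) {
        bands <- predict_genotype_bands(alleles, genos[[g]], pv)
        zc <- call_zygosity(bands)
        data.frame(genotype = g,
                   bands = paste(bands, collapse = ","),
                   call = zc$call, stringsAsFactors = FALSE)
      })
      gdf <- do.call(rbind, rows)
      write_tgmap_tsv(gdf, pth("genotypes.tsv"), meta)
      paths <- c(paths, pth(c("primers.tsv", "genotypes.tsv")))
      list(primers = primers, genotypes = gdf)
    })
  }

  summary <- list(
    config_hash = unname(meta["config"]),
    seed = config$seed,
    funnel = as.list(fit$funnel),
    insertion = if (is.null(fit$call)) NULL else list(
      contig = fit$call$contig,
      left_boundary = fit$call$left$coordinate,
      right_boundary = fit$call$right$coordinate,
      deletion_length = fit$call$deletion_length,
      status = fit$call$status,
      left_partner = fit$call$left$partner_cassette,
      right_partner = fit$call$right$partner_cassette,
      left_microhomology = fit$call$left_microhomology$seq,
      right_microhomology = fit$call$right_microhomology$seq,
      left_support = c(pairs = fit$call$left$n_discordant,
                       clips = fit$call$left$n_softclip),
      right_support = c(pairs = fit$call$right$n_discordant,
                        clips = fit$call$right$n_softclip)),
    copy_folds = if (is.null(fit$copy_folds)) NULL else
      fit$copy_folds[, c("cassette_id", "copy_fold", "ci_low", "ci_high")],
    genotypes = if (is.null(geno)) NULL else geno$genotypes)
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = 6, pretty = TRUE, na = "null")
  paths <- c(paths, pth("summary.json"))

  structure(list(fit = fit, summary = summary, genome = genome,
                 paths = paths, outdir = config$outdir),
            class = "tgmap_run")
}

#' @export
print.tgmap_run <- function(x, ...) {
  cat(sprintf("tgmap pipeline run (outputs in %s)\n", x$outdir))
  print(x$fit)
  if (!is.null(x$summary$genotypes)) {
    cat("  in-silico genotyping:\n")
    print(x$summary$genotypes, row.names = FALSE)
  }
  invisible(x)
}
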