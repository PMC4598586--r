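#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic run with its standard
#' default: 75 bp retained reads, >5% Q<30 pair filter, 1 mismatch paired
#' alignment, Q20 bases, depth-10 calling, 250-500 bp size selection, 200 kb
#' windows advancing 100 kb, 1 kb flanks, 200 bp promoters, 10 body bins,
#' RPKM classes at 5/50 and the chi-square criterion 6.63 (P < 0.01, 1 df).
#' All parameters are validated at construction.
#'
#' @param genome A [genome_spec()].
#' @param methylation A [methylation_model()].
#' @param expression A [expression_model()].
#' @param sim A [read_sim_params()].
#' @param digest A [digest_params()].
#' @param snp_rate Sample-vs-reference SNP rate.
#' @param ddrad Simulate the ddRAD arm and mask called sites by its SNPs.
#' @param keep_len,max_low_frac,min_q Trimming/filter parameters.
#' @param k,max_mm,max_insert Alignment parameters.
#' @param min_baseq,min_depth Calling parameters.
#' @param win,step Window profile geometry (bp).
#' @param promoter,flank,body_bins,flank_bin Component/metagene geometry.
#' @param rpkm_low,rpkm_high Expression class boundaries.
#' @param chisq_critical Chi-square significance criterion.
#' @param seed Global seed; all stage seeds derive from it.
#' @param outdir Optional output directory for standard-format files.
#' @param mode "full" (align reads) or "truth" (place reads by their recorded
#'   provenance, skipping alignment; a pipeline self-check).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome = genome_spec(),
                            methylation = methylation_model(),
                            expression = expression_model(),
                            sim = read_sim_params(),
                            digest = digest_params(),
                            snp_rate = 1e-4,
                            ddrad = TRUE,
                            keep_len = 75L, max_low_frac = 0.05, min_q = 30L,
                            k = 20L, max_mm = 1L, max_insert = 500L,
                            min_baseq = 20L, min_depth = 10L,
                            win = 200000L, step = 100000L,
                            promoter = 200L, flank = 1000L,
                            body_bins = 10L, flank_bin = 100L,
                            rpkm_low = 5, rpkm_high = 50,
                            chisq_critical = stats::qchisq(0.99, 1),
                            seed = 1L, outdir = NULL,
                            mode = c("full", "truth")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "genome_spec"),
            inherits(methylation, "methylation_model"),
            inherits(expression, "expression_model"),
            inherits(sim, "read_sim_params"),
            inherits(digest, "digest_params"),
            snp_rate >= 0, snp_rate < 1,
            keep_len > 0, max_low_frac >= 0, max_low_frac <= 1, min_q >= 0,
            k >= 10, max_mm >= 0, max_insert > 0,
            min_baseq >= 0, min_depth >= 1,
            win >= step, step > 0, promoter > 0, flank > 0, body_bins >= 1,
            flank_bin > 0, rpkm_low >= 0, rpkm_high > rpkm_low,
            chisq_critical > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

# Alignment records reconstructed from read-name provenance (truth mode).
provenance_alignments <- function(reads, bisulfite = TRUE) {
  if (nrow(reads) == 0) {
    return(align_core(reads, NULL, list(), 0, 0))
  }
  f <- strsplit(reads$name, ":")
  chrom <- vapply(f, `[`, character(1), 1)
  fs <- as.integer(vapply(f, `[`, character(1), 2))
  fe <- as.integer(vapply(f, `[`, character(1), 3))
  bs <- vapply(f, `[`, character(1), 5)
  len1 <- nchar(reads$seq1); len2 <- nchar(reads$seq2)
  t1 <- if (!is.null(reads$trim1)) reads$trim1 else 0L
  t2 <- if (!is.null(reads$trim2)) reads$trim2 else 0L
  r1_left <- bs %in% c("OT", "CTOB", "fwd")
  tibble::tibble(
    name = reads$name, chrom = chrom,
    start1 = ifelse(r1_left, fs + t1, fe - t1 - len1), len1 = len1,
    orient1 = ifelse(r1_left, "fwd", "rc"),
    start2 = ifelse(r1_left, fe - t2 - len2, fs + t2), len2 = len2,
    orient2 = ifelse(r1_left, "rc", "fwd"),
    bs_strand = bs, mm = 0L)
}

#' Run the full synthetic mRRBS pipeline
#'
#' Executes simulate -> digest -> preprocess -> align -> call -> mask ->
#' profiles -> stratify with the configured parameters, recording input and
#' output record counts at every stage. When `config$outdir` is set, every
#' intermediate is written in its standard format (FASTA, GFF3, BED, gzip
#' FASTQ, SAM, TSV, bedGraph, minimal VCF) together with a markdown report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `rrbs_run` with the genome, truth, fragments,
#'   calls, profiles, stratification tables, expression tables, and a
#'   `report` tibble of per-stage counters.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  rep_rows <- list()
  note <- function(stage, metric, value) {
    rep_rows[[length(rep_rows) + 1L]] <<-
      tibble::tibble(stage = stage, metric = metric, value = as.numeric(value))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- config$seed

  genome <- run_stage("simulate_genome", {
    spec <- config$genome
    spec$seed <- child_seed(seed, "genome")
    generate_genome(spec)
  })
  note("simulate_genome", "bases", sum(nchar(genome$ref)))
  note("simulate_genome", "genes", sum(genome$ann$type == "gene"))
  note("simulate_genome", "tes", sum(genome$ann$type == "te"))

  truth <- run_stage("simulate_methylome",
    generate_methylome(genome$ref, genome$ann, config$methylation,
                       seed = child_seed(seed, "methylome"),
                       promoter = config$promoter, flank = config$flank))
  note("simulate_methylome", "cytosines", nrow(truth))

  sample_g <- run_stage("apply_variants",
    apply_variants(genome$ref, config$snp_rate,
                   seed = child_seed(seed, "variants")))
  note("apply_variants", "true_snps", nrow(sample_g$variants))

  fragments <- run_stage("digest", {
    select_representation(double_digest(sample_g$ref), config$digest)
  })
  note("digest", "selected_fragments", nrow(fragments))

  bs_raw <- run_stage("simulate_reads",
    simulate_rrbs_reads(sample_g$ref, truth, config$digest, config$sim,
                        fragments = fragments,
                        seed = child_seed(seed, "rrbs_reads")))
  note("simulate_reads", "bs_pairs", nrow(bs_raw))
  dd_raw <- NULL
  if (config$ddrad) {
    dd_raw <- run_stage("simulate_reads",
      simulate_ddrad_reads(sample_g$ref, config$digest, config$sim,
                           fragments = fragments,
                           seed = child_seed(seed, "ddrad_reads")))
    note("simulate_reads", "ddrad_pairs", nrow(dd_raw))
  }

  preprocess_set <- function(raw, label) {
    tr <- trim_reads(raw, keep_len = config$keep_len)
    qf <- quality_filter(tr, config$max_low_frac, config$min_q)
    note("preprocess", paste0(label, "_input"), nrow(raw))
    note("preprocess", paste0(label, "_discarded"), qf$log$discarded)
    note("preprocess", paste0(label, "_retained"), qf$log$retained)
    qf$reads
  }
  bs_reads <- run_stage("preprocess", preprocess_set(bs_raw, "bs"))
  dd_reads <- if (config$ddrad) {
    run_stage("preprocess", preprocess_set(dd_raw, "ddrad"))
  }

  index <- run_stage("align", build_bs_index(genome$ref, config$k))
  bs_aln <- run_stage("align", {
    if (config$mode == "truth") provenance_alignments(bs_reads)
    else align_bs_reads(bs_reads, index, config$max_mm, config$max_insert)
  })
  cn <- attr(bs_aln, "counts")
  if (!is.null(cn)) {
    for (m in names(cn)) note("align", paste0("bs_", m), cn[[m]])
  } else {
    note("align", "bs_aligned", nrow(bs_aln))
  }
  dd_aln <- NULL
  if (config$ddrad) {
    dd_aln <- run_stage("align", {
      if (config$mode == "truth") provenance_alignments(dd_reads, FALSE)
      else align_plain_reads(dd_reads, index, config$max_mm,
                             config$max_insert)
    })
    note("align", "ddrad_aligned", nrow(dd_aln))
  }

  catalog <- run_stage("call", classify_cytosines(genome$ref))
  counts <- run_stage("call",
    pileup_methylation(bs_aln, bs_reads, catalog, config$min_baseq))
  calls <- run_stage("call", call_levels(counts, config$min_depth))
  note("call", "covered_sites", nrow(counts))
  note("call", "called_sites", nrow(calls))

  snps <- tibble::tibble(chrom = character(), pos = integer(),
                         ref = character(), alt = character())
  if (config$ddrad) {
    snps <- run_stage("call",
      call_snps(dd_aln, dd_reads, genome$ref, config$min_baseq))
    note("call", "candidate_snps", nrow(snps))
  }
  maskres <- run_stage("mask", mask_sites(calls, snps))
  calls_masked <- maskres$calls
  note("mask", "masked_sites", sum(maskres$masked$n_masked))
  note("mask", "retained_sites", nrow(calls_masked))

  chrom_lengths <- chrom_lengths_of(genome$ref)
  comp <- run_stage("profiles",
    component_means(calls_masked, genome$ann, chrom_lengths,
                    config$promoter, config$flank))
  windows <- run_stage("profiles",
    window_profile(calls_masked, chrom_lengths, genome$ann,
                   config$win, config$step))
  histo <- run_stage("profiles", level_histogram(calls_masked))
  metagene <- run_stage("profiles",
    metagene_profile(calls_masked,
                     dplyr::filter(genome$ann, .data$type == "gene"),
                     config$flank, config$body_bins, config$flank_bin))

  strata_sub <- run_stage("stratify",
    stratum_means(calls_masked, genome$ann, "subgenome", chrom_lengths,
                  config$promoter, config$flank))
  strata_copy <- run_stage("stratify",
    stratum_means(calls_masked, genome$ann, "copy_class", chrom_lengths,
                  config$promoter, config$flank))
  tests_sub <- run_stage("stratify",
    tryCatch(stratum_tests(strata_sub, "genic", "CG", config$chisq_critical),
             error = function(e) NULL))

  expr <- run_stage("expression",
    generate_expression(genome$ann, truth, config$expression,
                        seed = child_seed(seed, "expression")))
  classes <- run_stage("expression",
    bin_expression(expr, config$rpkm_low, config$rpkm_high))
  xtab_sub <- run_stage("expression",
    expression_crosstab(classes, genome$ann, "subgenome"))
  xtab_copy <- run_stage("expression",
    expression_crosstab(classes, genome$ann, "copy_class"))
  assoc <- run_stage("expression",
    methylation_expression_association(calls_masked, genome$ann, classes))

  report <- dplyr::bind_rows(rep_rows)
  out <- structure(list(
    config = config, genome = genome, truth = truth,
    sample_ref = sample_g$ref, true_variants = sample_g$variants,
    fragments = fragments, bs_reads = bs_reads, dd_reads = dd_reads,
    bs_alignments = bs_aln, dd_alignments = dd_aln,
    calls = calls, snps = snps, masked = maskres$masked,
    calls_masked = calls_masked,
    component_means = comp, windows = windows, histogram = histo,
    metagene = metagene,
    strata_subgenome = strata_sub, strata_copy = strata_copy,
    tests_subgenome = tests_sub,
    expression = expr, classes = classes,
    crosstab_subgenome = xtab_sub, crosstab_copy = xtab_copy,
    association = assoc,
    report = report), class = "rrbs_run")
  if (!is.null(config$outdir)) write_run(out, config$outdir)
  out
}

# Write every intermediate of a run in its standard format.
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  write_fasta(run$genome$ref, p("reference.fasta"))
  write_fasta(run$sample_ref, p("sample.fasta"))
  write_gff3(run$genome$ann, p("annotation.gff3"))
  write_bed(run$genome$ann, p("annotation.bed"))
  write_bed(run$fragments, p("fragments.bed"))
  write_tsv_table(run$truth, p("methylome_truth.tsv"))
  write_vcf_min(run$true_variants, p("true_variants.vcf"))
  write_vcf_min(run$snps, p("candidate_snps.vcf"))
  write_fastq_pairs(run$bs_reads, p("bs_reads"))
  if (!is.null(run$dd_reads)) write_fastq_pairs(run$dd_reads, p("ddrad_reads"))
  write_sam(run$bs_alignments, run$bs_reads, run$genome$ref,
            p("bs_alignments.sam"))
  write_tsv_table(run$calls_masked, p("site_calls.tsv"))
  write_bedgraph(run$calls_masked, p("levels"))
  write_tsv_table(run$component_means, p("component_means.tsv"))
  write_tsv_table(run$windows, p("window_profile.tsv"))
  write_tsv_table(run$histogram, p("level_histogram.tsv"))
  write_tsv_table(run$metagene, p("metagene.tsv"))
  write_tsv_table(run$strata_subgenome, p("strata_subgenome.tsv"))
  write_tsv_table(run$strata_copy, p("strata_copy.tsv"))
  write_tsv_table(run$expression, p("expression.tsv"))
  write_tsv_table(run$report, p("report.tsv"))
  md <- c("# mRRBS synthetic run report", "",
          "## Stage counters", "",
          knit_simple_table(run$report), "",
          "## Component means", "",
          knit_simple_table(run$component_means), "",
          "## Subgenome strata (genic)", "",
          knit_simple_table(dplyr::filter(run$strata_subgenome,
                                          .data$component == "genic")))
  writeLines(md, p("report.md"))
  invisible(outdir)
}

# Minimal markdown table renderer for the run report.
knit_simple_table <- function(df) {
  df <- tibble::as_tibble(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 5))
  cells <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(df[i, ], as.character, character(1)), collapse = " | ")
  }, character(1))
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    paste("|", cells, "|"))
}

#' @export
print.rrbs_run <- function(x, ...) {
  cat("<rrbs_run>\n")
  print(x$report, n = Inf)
  invisible(x)
}
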