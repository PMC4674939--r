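## Stage orchestration: each stage reads its inputs from the run
## directory, writes TSV/SAM/FASTA outputs and appends a manifest entry.
## Stages: simulate, snps, extract, partition, classify, dmr, integrate,
## run-all.

PIPELINE_STAGES <- c("simulate", "snps", "extract", "partition", "classify",
                     "dmr", "integrate")

#' Read and validate a pipeline configuration
#'
#' YAML with up to three blocks: a global \code{seed}, a
#' \code{simulation} block (fields of \code{\link{sim_config}}) and a
#' \code{thresholds} block (fields of \code{\link{meth_thresholds}}).
#' Every numeric default equals the documented threshold values; any
#' override is recorded in the run manifest.
#'
#' @param path YAML file, or a list already in this shape.
#' @return list with \code{seed}, \code{sim} (a \code{sim_config}),
#'   \code{thresholds} (a \code{meth_thresholds}) and the raw overrides.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop_input("config file '%s' does not exist", path)
    yaml::read_yaml(path)
  } else as.list(path)
  known <- c("seed", "simulation", "thresholds")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_input("unknown config block(s): %s", paste(extra, collapse = ", "))
  seed <- as.integer(raw$seed %||% 1L)
  simargs <- raw$simulation %||% list()
  if ("pattern_mix" %in% names(simargs))
    simargs$pattern_mix <- unlist(simargs$pattern_mix)
  if ("context_level_means" %in% names(simargs))
    simargs$context_level_means <- unlist(simargs$context_level_means)
  bad <- setdiff(names(simargs), names(formals(sim_config)))
  if (length(bad))
    stop_input("unknown simulation field(s): %s", paste(bad, collapse = ", "))
  thargs <- raw$thresholds %||% list()
  bad <- setdiff(names(thargs), names(formals(meth_thresholds)))
  if (length(bad))
    stop_input("unknown threshold field(s): %s", paste(bad, collapse = ", "))
  sim <- do.call(sim_config, c(simargs, list(seed = seed)))
  list(seed = seed, sim = sim,
       thresholds = do.call(meth_thresholds, thargs),
       overrides = list(simulation = simargs, thresholds = thargs))
}

manifest_append <- function(dir, entry) {
  path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  manifest[[length(manifest) + 1L]] <- entry
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

require_inputs <- function(dir, files, stage) {
  for (f in files) {
    p <- file.path(dir, f)
    if (!file.exists(p))
      stop_input("stage '%s' requires missing input file '%s' (run the producing stage first)",
                 stage, p)
  }
}

#' Run one pipeline stage (or all of them)
#'
#' Executes a stage against a run directory, writing its outputs and a
#' manifest entry (stage, parameters, seed, input/output files with row
#' counts, package version). A missing input file or an invalid
#' configuration raises a \code{polymethyl_input_error}; the command-line
#' wrapper turns that into exit status 2.
#'
#' @param stage one of \code{"simulate"}, \code{"snps"}, \code{"extract"},
#'   \code{"partition"}, \code{"classify"}, \code{"dmr"},
#'   \code{"integrate"}, \code{"run-all"}.
#' @param config path to a YAML config or a config list
#'   (\code{\link{read_pipeline_config}}).
#' @param out_dir run directory (created if needed).
#' @param seed optional override of the config seed.
#' @return invisibly, a named list of output file paths.
#' @export
run_stage <- function(stage, config, out_dir = "polymethyl_run",
                      seed = NULL) {
  if (!stage %in% c(PIPELINE_STAGES, "run-all"))
    stop_input("unknown stage '%s'", stage)
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    cfg$sim$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "run-all") {
    outs <- lapply(PIPELINE_STAGES, function(s)
      run_stage(s, config, out_dir, seed = seed))
    return(invisible(stats::setNames(outs, PIPELINE_STAGES)))
  }
  fn <- switch(stage,
               simulate = stage_simulate, snps = stage_snps,
               extract = stage_extract, partition = stage_partition,
               classify = stage_classify, dmr = stage_dmr,
               integrate = stage_integrate)
  t0 <- Sys.time()
  outputs <- fn(cfg, out_dir)
  rowcount <- function(p) {
    if (grepl("\\.(tsv|bed)$", p) && file.exists(p))
      length(readLines(p)) else NA
  }
  manifest_append(out_dir, list(
    stage = stage,
    time = format(t0, "%Y-%m-%dT%H:%M:%S"),
    seed = cfg$seed,
    overrides = cfg$overrides,
    version = as.character(utils::packageVersion("polymethyl")),
    outputs = lapply(outputs, function(p)
      list(file = p, rows = rowcount(p)))))
  message(sprintf("[%s] wrote %s", stage,
                  paste(basename(unlist(outputs)), collapse = ", ")))
  invisible(outputs)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config, out_dir = "polymethyl_run", seed = NULL) {
  run_stage("run-all", config, out_dir, seed)
}

stage_simulate <- function(cfg, dir) {
  sim <- simulate_methylome(cfg$sim)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    snps_truth = file.path(dir, "snps_truth.tsv"),
    truth = file.path(dir, "truth.tsv"),
    reads = file.path(dir, "reads.sam"),
    regions = file.path(dir, "regions.bed"),
    expression = file.path(dir, "expression.tsv"))
  write_reference_fasta(sim$ref$reference, paths$reference)
  for (g in GENOMES)
    write_reference_fasta(sim$ref$genomes[[g]],
                          file.path(dir, sprintf("genome_%s.fa", g)))
  snps <- copy(sim$ref$snps)[, source := "truth"]
  write_snp_catalog(snps, paths$snps_truth)
  write_site_table(sim$truth, paths$truth)
  write_bisulfite_sam(sim$reads, paths$reads, sim$ref$reference)
  write_regions_bed(sim$regions, paths$regions)
  expr <- sim$expression[, .(gene_id, raw_A, raw_B, raw_D)]
  write_tsv_formatted(expr, paths$expression)
  paths
}

stage_snps <- function(cfg, dir) {
  require_inputs(dir, "snps_truth.tsv", "snps")
  snps <- read_snp_catalog(file.path(dir, "snps_truth.tsv"))
  cat <- filter_bisulfite_ambiguous(snps)
  message(sprintf("[snps] %d of %d SNPs bisulfite-safe (%d removed)",
                  nrow(cat), nrow(snps), attr(cat, "removed")))
  paths <- list(catalog = file.path(dir, "snp_catalog.tsv"),
                report = file.path(dir, "snp_filter_report.tsv"))
  write_snp_catalog(cat[, source := "merged"], paths$catalog)
  write_tsv_formatted(data.table(rule = "bisulfite_ambiguous",
                                 removed = attr(cat, "removed"),
                                 retained = nrow(cat)), paths$report)
  paths
}

pipeline_reads <- function(dir) {
  reference <- read_reference_fasta(file.path(dir, "reference.fa"))
  reads <- read_bisulfite_sam(file.path(dir, "reads.sam"), reference)
  list(reference = reference, reads = reads)
}

stage_extract <- function(cfg, dir) {
  require_inputs(dir, c("reads.sam", "reference.fa"), "extract")
  inp <- pipeline_reads(dir)
  calls <- extract_site_calls(inp$reads, inp$reference)
  conv <- estimate_conversion_rate(inp$reads, inp$reference)
  obs <- calls[, .(reads_methylated = sum(methylated), reads_total = .N),
               by = .(contig, pos, strand, context)]
  paths <- list(observations = file.path(dir, "site_observations.tsv"),
                conversion = file.path(dir, "conversion_rate.tsv"))
  write_site_table(obs, paths$observations)
  write_tsv_formatted(data.table(conversion_rate_pct = as.numeric(conv),
                                 n_observations = attr(conv, "n")),
                      paths$conversion)
  message(sprintf("[extract] %d sites observed; conversion rate %.2f%%",
                  nrow(obs), as.numeric(conv)))
  paths
}

stage_partition <- function(cfg, dir) {
  require_inputs(dir, c("reads.sam", "reference.fa", "snp_catalog.tsv"),
                 "partition")
  inp <- pipeline_reads(dir)
  snps <- read_snp_catalog(file.path(dir, "snp_catalog.tsv"))
  assignments <- assign_reads(inp$reads, snps, cfg$thresholds)
  calls <- extract_site_calls(inp$reads, inp$reference)
  tally <- tally_site_counts(calls, assignments, cfg$thresholds)
  un <- attr(assignments, "unassigned")
  message(sprintf("[partition] %d sites tallied; unassigned reads: %s",
                  nrow(tally),
                  paste(sprintf("%s=%d", names(un), un), collapse = ", ")))
  paths <- list(site_counts = file.path(dir, "site_counts.tsv"))
  write_site_table(tally, paths$site_counts)
  paths
}

stage_classify <- function(cfg, dir) {
  require_inputs(dir, "site_counts.tsv", "classify")
  tally <- read_site_table(file.path(dir, "site_counts.tsv"))
  th <- cfg$thresholds
  convfile <- file.path(dir, "conversion_rate.tsv")
  if (th$conversion_background == 0 && file.exists(convfile)) {
    conv <- fread(convfile)
    if (is.finite(conv$conversion_rate_pct[1]))
      th$conversion_background <-
        max(0, 1 - conv$conversion_rate_pct[1] / 100)
  }
  patterns <- classify_site_patterns(tally, th)
  tab <- table(patterns$pattern, useNA = "ifany")
  message(sprintf("[classify] patterns: %s",
                  paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  paths <- list(patterns = file.path(dir, "site_patterns.tsv"))
  write_site_table(patterns, paths$patterns)
  paths
}

stage_dmr <- function(cfg, dir) {
  require_inputs(dir, c("site_counts.tsv", "regions.bed"), "dmr")
  tally <- read_site_table(file.path(dir, "site_counts.tsv"))
  regions <- read_regions_bed(file.path(dir, "regions.bed"))
  summ <- summarize_regions(tally, regions, cfg$thresholds)
  dmrs <- call_genome_specific_dmr(summ, cfg$thresholds)
  message(sprintf("[dmr] %d region(s) summarized, %d genome-specific DMR(s)",
                  nrow(summ), nrow(dmrs)))
  paths <- list(regions = file.path(dir, "region_summaries.tsv"),
                dmrs = file.path(dir, "dmr_genome.tsv"))
  write_region_table(summ, paths$regions)
  write_dmr_table(dmrs, paths$dmrs)
  paths
}

stage_integrate <- function(cfg, dir) {
  require_inputs(dir, c("site_patterns.tsv", "regions.bed",
                        "expression.tsv"), "integrate")
  patterns <- read_site_table(file.path(dir, "site_patterns.tsv"))
  regions <- read_regions_bed(file.path(dir, "regions.bed"))
  expr <- read_expression_table(file.path(dir, "expression.tsv"))
  expr[, coexpression := categorize_coexpression(
    norm_A, norm_B, norm_D, window = cfg$thresholds$expr_conserved_window)]
  corr <- correlate_methylation_expression(patterns, regions, expr)
  paths <- list(expression = file.path(dir, "expression_normalized.tsv"),
                summary = file.path(dir, "expression_summary.tsv"),
                histogram = file.path(dir, "expression_histogram.tsv"))
  write_tsv_formatted(expr, paths$expression)
  write_tsv_formatted(corr$summary, paths$summary)
  write_tsv_formatted(corr$histogram, paths$histogram)
  message(sprintf("[integrate] %d stratum summaries over %d site-genome values",
                  nrow(corr$summary), nrow(corr$values)))
  paths
}
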