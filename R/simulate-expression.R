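#' Simulate region annotations for the synthetic reference
#'
#' Lays out one gene per shared contig: a promoter, an exon and an intron
#' block (the transcribed gene body) and a trailing non-transcribed block.
#' The promoter immediately precedes the transcription start and is linked
#' to its gene, mirroring annotation input in which promoters are the
#' sequence up to 2000 bp upstream of the transcription start site.
#'
#' @param ref a \code{\link{simulate_references}} result.
#' @param config the same \code{\link{sim_config}}.
#' @return \code{data.table} with columns \code{region_id}, \code{contig},
#'   \code{start}, \code{end} (0-based half-open), \code{class},
#'   \code{gene_id}.
#' @export
simulate_regions <- function(ref, config) {
  stopifnot(inherits(ref, "sim_reference"))
  shared <- setdiff(names(ref$reference), ref$control_contig)
  lens <- Biostrings::width(ref$reference[shared])
  fp <- config$promoter_fraction
  out <- lapply(seq_along(shared), function(i) {
    ct <- shared[i]; L <- lens[i]
    cut <- as.integer(round(L * c(fp, 0.6, 0.8)))
    gene <- paste0("gene_", ct)
    data.table(
      region_id = paste(ct, c("promoter", "exon", "intron",
                              "non_transcribed"), sep = "_"),
      contig = ct,
      start = c(0L, cut[1], cut[2], cut[3]),
      end = c(cut[1], cut[2], cut[3], L),
      class = c("promoter", "exon", "intron", "non_transcribed"),
      gene_id = gene)
  })
  rbindlist(out)
}

#' Simulate allelic expression with promoter-methylation suppression
#'
#' Draws a positive baseline expression level per gene and sub-genome from
#' a shared gamma distribution and multiplies the level of any sub-genome
#' whose promoter is uni-methylated in the truth by
#' \code{promoter_suppression}. Levels are then normalized per gene so the
#' three sub-genomes sum to 100 \%.
#'
#' @param regions region table from \code{\link{simulate_regions}} (or any
#'   table with \code{contig}, \code{start}, \code{end}, \code{class},
#'   \code{gene_id}).
#' @param truth methylation truth from
#'   \code{\link{simulate_methylation_truth}}; a sub-genome is suppressed
#'   when its promoter is dominated by genome-specific methylation (more
#'   than 25 \% of the promoter's methylation-assigned sites are uni_X).
#'   May also be \code{NULL} together with an explicit \code{suppressed}
#'   matrix.
#' @param config the same \code{\link{sim_config}}.
#' @param suppressed optional logical matrix (genes x 3, columns A/B/D)
#'   overriding the truth-derived suppression labels.
#' @return \code{data.table} with one row per gene: raw and normalized
#'   levels and the suppression truth labels per sub-genome.
#' @export
simulate_allelic_expression <- function(regions, truth, config,
                                        suppressed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  regions <- as.data.table(regions)
  genes <- unique(regions[, .(gene_id, contig)])
  setkey(genes, gene_id)
  n <- nrow(genes)
  set.seed(derive_seed(config$seed, 4L))

  if (is.null(suppressed)) {
    suppressed <- matrix(FALSE, n, 3, dimnames = list(genes$gene_id, GENOMES))
    if (!is.null(truth)) {
      truth <- as.data.table(truth)
      prom <- regions[class == "promoter"]
      for (i in seq_len(nrow(prom))) {
        tt <- truth[contig == prom$contig[i] & pos >= prom$start[i] &
                      pos < prom$end[i] & pattern != "unmethylated"]
        if (nrow(tt) == 0L) next
        for (g in GENOMES)
          if (mean(tt$pattern == paste0("uni_", g)) > 0.25)
            suppressed[prom$gene_id[i], g] <- TRUE
      }
    }
  } else {
    suppressed <- suppressed[genes$gene_id, , drop = FALSE]
  }

  out <- copy(genes)
  for (g in GENOMES) {
    raw <- rgamma(n, shape = 4, rate = 4 / 100)
    raw[suppressed[, g]] <- raw[suppressed[, g]] * config$promoter_suppression
    set(out, j = paste0("raw_", g), value = raw)
    set(out, j = paste0("suppressed_", g), value = unname(suppressed[, g]))
  }
  norm <- normalize_allelic_expression(out$raw_A, out$raw_B, out$raw_D)
  out[, `:=`(norm_A = norm$norm_A, norm_B = norm$norm_B,
             norm_D = norm$norm_D, expressed = norm$expressed)]
  out[]
}

#' One-call synthetic methylome
#'
#' Convenience wrapper running the whole generator: references, methylation
#' truth, bisulfite reads (including the unmethylated control), region
#' annotations and allelic expression.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{config}, \code{ref}, \code{truth},
#'   \code{reads}, \code{regions}, \code{expression}.
#' @export
simulate_methylome <- function(config = sim_config()) {
  ref <- simulate_references(config)
  truth <- simulate_methylation_truth(ref, config)
  reads <- simulate_reads(ref, truth, config)
  regions <- simulate_regions(ref, config)
  expr <- simulate_allelic_expression(regions, truth, config)
  list(config = config, ref = ref, truth = truth, reads = reads,
       regions = regions, expression = expr)
}
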