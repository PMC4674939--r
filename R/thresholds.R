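#' Classification thresholds for polyploid methylation analysis
#'
#' Bundles every tunable cutoff used by the pipeline. The defaults are the
#' thresholds developed for targeted methyl-seq of hexaploid wheat, where a
#' site seen through a biallelic homoeologous SNP is an average of two
#' sub-genomes and can only be called confidently when both genomes are
#' likely methylated or both likely unmethylated:
#' \itemize{
#'   \item CpG sites: methylated at \eqn{\ge} 75 \% and unmethylated at
#'     \eqn{\le} 25 \%, the band in between being intermediate;
#'   \item CHG/CHH sites: methylated when strictly exceeding 10 \%,
#'     unmethylated at a (background-corrected) level of 0 \%;
#'   \item within-sample sub-genome differences require \eqn{\ge} 50 \%
#'     difference at q < 0.01; between-sample and per-region (DMR)
#'     differences require \eqn{\ge} 25 \% after replicate pooling;
#'   \item coverage gates of 5x for a single genome and 10x for a genome
#'     pair; mapping quality must exceed 20.
#' }
#'
#' @param cpg_meth,cpg_unmeth CpG methylated/unmethylated cutoffs (percent).
#' @param non_cpg_meth CHG/CHH methylated cutoff (percent, strict).
#' @param within_sample_diff minimum difference for sub-genome comparisons
#'   within a sample (percent).
#' @param between_sample_diff minimum difference for between-sample
#'   comparisons (percent).
#' @param dmr_diff minimum per-region difference for DMR calls (percent).
#' @param diploid_compare_diff minimum difference for diploid-progenitor
#'   versus sub-genome comparisons (percent; 50 due to lower coverage).
#' @param q_cutoff q-value cutoff for all Fisher tests.
#' @param single_depth,pair_depth minimum read depth for a single genome and
#'   for a genome pair.
#' @param mapq_min reads at or below this mapping quality are excluded from
#'   sub-genome assignment.
#' @param promoter_bp maximum promoter extent upstream of a transcription
#'   start (bp).
#' @param expr_conserved_window window (percentage points of normalized
#'   expression) within which sub-genome expression counts as conserved.
#' @param pplr_de_low,pplr_de_high PPLR cutoffs for differential expression
#'   (at or beyond 0.4/0.6).
#' @param pplr_highde_low,pplr_highde_high PPLR cutoffs for high-confidence
#'   differential expression (strictly beyond 0.10/0.90).
#' @param conversion_background expected apparent methylation fraction at a
#'   truly unmethylated cytosine due to incomplete bisulfite conversion
#'   (1 - conversion rate, as a fraction). 0 disables background correction;
#'   the pipeline sets it from the control-contig estimate.
#' @param background_alpha significance level of the one-sided binomial test
#'   that decides whether a site's methylated counts exceed the conversion
#'   background.
#' @return object of class \code{meth_thresholds} (a named list).
#' @export
meth_thresholds <- function(cpg_meth = 75, cpg_unmeth = 25,
                            non_cpg_meth = 10,
                            within_sample_diff = 50,
                            between_sample_diff = 25,
                            dmr_diff = 25,
                            diploid_compare_diff = 50,
                            q_cutoff = 0.01,
                            single_depth = 5L, pair_depth = 10L,
                            mapq_min = 20L,
                            promoter_bp = 2000L,
                            expr_conserved_window = 5,
                            pplr_de_low = 0.4, pplr_de_high = 0.6,
                            pplr_highde_low = 0.10, pplr_highde_high = 0.90,
                            conversion_background = 0,
                            background_alpha = 0.05) {
  th <- list(cpg_meth = cpg_meth, cpg_unmeth = cpg_unmeth,
             non_cpg_meth = non_cpg_meth,
             within_sample_diff = within_sample_diff,
             between_sample_diff = between_sample_diff,
             dmr_diff = dmr_diff,
             diploid_compare_diff = diploid_compare_diff,
             q_cutoff = q_cutoff,
             single_depth = as.integer(single_depth),
             pair_depth = as.integer(pair_depth),
             mapq_min = as.integer(mapq_min),
             promoter_bp = as.integer(promoter_bp),
             expr_conserved_window = expr_conserved_window,
             pplr_de_low = pplr_de_low, pplr_de_high = pplr_de_high,
             pplr_highde_low = pplr_highde_low,
             pplr_highde_high = pplr_highde_high,
             conversion_background = conversion_background,
             background_alpha = background_alpha)
  pct <- c("cpg_meth", "cpg_unmeth", "non_cpg_meth", "within_sample_diff",
           "between_sample_diff", "dmr_diff", "diploid_compare_diff",
           "expr_conserved_window")
  for (f in pct)
    if (!is.numeric(th[[f]]) || th[[f]] < 0 || th[[f]] > 100)
      stop_input("threshold '%s' must be a percentage in [0, 100]", f)
  if (th$q_cutoff <= 0 || th$q_cutoff >= 1)
    stop_input("q_cutoff must lie in (0, 1)")
  if (th$single_depth < 1L || th$pair_depth < 1L)
    stop_input("depth gates must be positive")
  if (th$conversion_background < 0 || th$conversion_background >= 1)
    stop_input("conversion_background must lie in [0, 1)")
  structure(th, class = "meth_thresholds")
}

#' @export
print.meth_thresholds <- function(x, ...) {
  cat("Polyploid methylation thresholds:\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
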