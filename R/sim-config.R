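#' Configuration for the synthetic methyl-seq generator
#'
#' Defines the study conditions emulated by the synthetic data generator:
#' three homoeologous sub-genome sequences (A, B, D) that differ at
#' catalogued SNP positions, per-cytosine methylation truth drawn from a mix
#' of uni-/bi-/tri-genome and intermediate patterns, bisulfite reads with
#' incomplete conversion and sequencing error, an unmethylated control
#' contig, and allelic expression with a promoter-methylation suppression
#' effect.
#'
#' The default \code{pattern_mix} reproduces the proportions observed among
#' methylated wheat cytosines: 45 \% tri-genome, 20 \% differential (12 \%
#' uni-genome split evenly over A/B/D and 8 \% bi-genome split evenly over
#' the pairs) and 35 \% intermediate. The default \code{conversion_rate} is
#' the 98.92 \% measured on the chloroplast control.
#'
#' @param n_contigs number of shared reference contigs.
#' @param contig_length length of each contig (bp).
#' @param snp_rate per-bp probability that a position is divergent between
#'   the sub-genomes; must lie in \[0, 0.2) with \code{contig_length *
#'   snp_rate >= 1} when positive (0 yields identical sub-genomes).
#' @param triallelic_prob probability that a divergent position carries
#'   three distinct alleles rather than one differing genome (default
#'   heavily biallelic).
#' @param pattern_mix named proportions over
#'   \code{c("tri","uni_A","uni_B","uni_D","bi_AB","bi_AD","bi_BD",
#'   "intermediate","unmethylated")}; must sum to 1.
#' @param context_level_means named per-context mean methylation level
#'   (fractions) for genomes that are "methylated" in the truth.
#' @param read_length read length (bp).
#' @param paired emit paired-end fragments (two mates sharing a fragment
#'   name, so SNP evidence combines across the insert during read
#'   assignment, as in the 2 x 100 bp libraries the design emulates);
#'   contigs shorter than the insert fall back to single-end.
#' @param insert_mean,insert_sd fragment insert size distribution (bp).
#' @param depth mean fold-coverage per sub-genome.
#' @param conversion_rate probability that an unmethylated cytosine is
#'   converted (reads as thymine).
#' @param error_rate per-base sequencing error probability.
#' @param directional if \code{TRUE} only the two original strand products
#'   (OT/OB) are sequenced; otherwise all four (OT/OB/CTOT/CTOB).
#' @param mapq mapping quality attached to simulated reads.
#' @param control_length length of the unmethylated control contig (bp);
#'   it always hosts at least 1000 cytosines.
#' @param gc_content GC fraction of the generated sequence.
#' @param promoter_suppression multiplicative factor applied to the raw
#'   expression of a sub-genome whose promoter is uni-methylated.
#' @param promoter_fraction fraction of each contig annotated as promoter by
#'   the synthetic region annotation (the remainder is split over
#'   exon/intron/non-transcribed).
#' @param seed integer seed governing all generator randomness.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_contigs = 10L,
                       contig_length = 2000L,
                       snp_rate = 0.04,
                       triallelic_prob = 0.1,
                       pattern_mix = c(tri = 0.45,
                                       uni_A = 0.04, uni_B = 0.04, uni_D = 0.04,
                                       bi_AB = 0.08 / 3, bi_AD = 0.08 / 3,
                                       bi_BD = 0.08 / 3,
                                       intermediate = 0.35,
                                       unmethylated = 0),
                       context_level_means = c(CpG = 0.90, CHG = 0.80,
                                               CHH = 0.75),
                       read_length = 100L,
                       paired = TRUE,
                       insert_mean = 300L,
                       insert_sd = 30,
                       depth = 30,
                       conversion_rate = 0.9892,
                       error_rate = 0.001,
                       directional = FALSE,
                       mapq = 40L,
                       control_length = 5000L,
                       gc_content = 0.46,
                       promoter_suppression = 0.8,
                       promoter_fraction = 0.25,
                       seed = 1L) {
  cfg <- list(n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              snp_rate = snp_rate, triallelic_prob = triallelic_prob,
              pattern_mix = pattern_mix,
              context_level_means = context_level_means,
              read_length = as.integer(read_length),
              paired = isTRUE(paired),
              insert_mean = as.integer(insert_mean),
              insert_sd = insert_sd,
              depth = depth,
              conversion_rate = conversion_rate, error_rate = error_rate,
              directional = isTRUE(directional), mapq = as.integer(mapq),
              control_length = as.integer(control_length),
              gc_content = gc_content,
              promoter_suppression = promoter_suppression,
              promoter_fraction = promoter_fraction,
              seed = as.integer(seed))
  if (cfg$n_contigs < 1L) stop_input("n_contigs must be >= 1")
  if (cfg$snp_rate < 0 || cfg$snp_rate >= 0.2)
    stop_input("snp_rate must lie in [0, 0.2)")
  if (cfg$snp_rate > 0 && cfg$contig_length * cfg$snp_rate < 1)
    stop_input(paste("contig_length %d too short to host >= 1 expected SNP",
                     "at snp_rate %g"), cfg$contig_length, cfg$snp_rate)
  if (is.null(names(cfg$pattern_mix)) ||
      !setequal(names(cfg$pattern_mix), PATTERNS))
    stop_input("pattern_mix must be named over the nine pattern classes")
  cfg$pattern_mix <- cfg$pattern_mix[PATTERNS]
  if (abs(sum(cfg$pattern_mix) - 1) > 1e-9)
    stop_input("pattern_mix must sum to 1 (got %.12f)", sum(cfg$pattern_mix))
  if (any(cfg$pattern_mix < 0)) stop_input("pattern_mix must be non-negative")
  if (!setequal(names(cfg$context_level_means), CONTEXTS))
    stop_input("context_level_means must be named CpG/CHG/CHH")
  cfg$context_level_means <- cfg$context_level_means[CONTEXTS]
  if (cfg$conversion_rate < 0 || cfg$conversion_rate > 1)
    stop_input("conversion_rate must lie in [0, 1]")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop_input("error_rate must lie in [0, 1]")
  if (cfg$depth < 0) stop_input("depth must be >= 0")
  if (cfg$read_length < 10L) stop_input("read_length must be >= 10")
  if (cfg$paired && cfg$insert_mean < 2L * cfg$read_length + 10L)
    stop_input("insert_mean must exceed twice the read length")
  if (cfg$promoter_suppression < 0 || cfg$promoter_suppression > 1)
    stop_input("promoter_suppression must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic methyl-seq config: %d contig(s) x %d bp, snp_rate %g, depth %gx\n",
    x$n_contigs, x$contig_length, x$snp_rate, x$depth))
  cat(sprintf("  conversion %.4f, error %g, %s library, seed %d\n",
              x$conversion_rate, x$error_rate,
              if (x$directional) "directional" else "non-directional", x$seed))
  mix <- paste(sprintf("%s=%.3g", names(x$pattern_mix), x$pattern_mix),
               collapse = " ")
  cat("  pattern mix:", mix, "\n")
  invisible(x)
}
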