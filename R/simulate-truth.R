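#' Assign ground-truth methylation states to cytosine sites
#'
#' Every cytosine of the shared contigs (both strands) whose base and
#' two-base downstream context are identical across the three sub-genomes
#' receives a pattern drawn from \code{pattern_mix} and per-genome
#' methylation probabilities:
#' \itemize{
#'   \item \code{tri}: all three genomes methylated at a level jittered
#'     around the context mean;
#'   \item \code{uni_X}: genome X methylated, the other two at exactly 0;
#'   \item \code{bi_XY}: genomes X and Y methylated, the third at 0;
#'   \item \code{intermediate}: each genome drawn independently inside the
#'     context's intermediate band (CpG: 0.35-0.65; CHG/CHH: 0.05-0.10,
#'     the band between "0 \%" and the 10 \% cutoff);
#'   \item \code{unmethylated}: all three at 0.
#' }
#' Cytosines adjacent to a divergent position (which therefore differ in
#' presence or context between genomes) are not comparable across
#' sub-genomes and carry no truth record; reads over them are simulated as
#' unmethylated.
#'
#' @param ref a \code{\link{simulate_references}} result.
#' @param config the same \code{\link{sim_config}}.
#' @return \code{data.table} with columns \code{contig}, \code{pos},
#'   \code{strand}, \code{context}, \code{pattern}, \code{p_A}, \code{p_B},
#'   \code{p_D}.
#' @export
simulate_methylation_truth <- function(ref, config) {
  stopifnot(inherits(ref, "sim_reference"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  shared <- setdiff(names(ref$reference), ref$control_contig)
  sites <- cytosine_sites(ref$reference[shared])

  ## a site is comparable when neither it nor its two context bases (on its
  ## own strand) nor the two bases defining the opposite orientation overlap
  ## a divergent position; conservatively exclude pos-2..pos+2
  if (nrow(ref$snps)) {
    excl <- ref$snps[, .(contig, pos)]
    near <- rbindlist(lapply(-2:2, function(d) excl[, .(contig, pos = pos + d)]))
    sites <- sites[!near, on = c("contig", "pos")]
  }

  n <- nrow(sites)
  sites[, pattern := sample(PATTERNS, n, replace = TRUE,
                            prob = config$pattern_mix)]
  means <- config$context_level_means[sites$context]
  jitter <- function() pmin(1, pmax(0, means + runif(n, -0.05, 0.05)))
  inter_band <- function() {
    lo <- ifelse(sites$context == "CpG", 0.35, 0.05)
    hi <- ifelse(sites$context == "CpG", 0.65, 0.10)
    runif(n, lo, hi)
  }
  for (g in GENOMES) {
    p <- numeric(n)
    lev <- jitter()
    methylated_in <- sites$pattern %in%
      c("tri", paste0("uni_", g), paste0("bi_", PAIRS[grepl(g, PAIRS)]))
    p[methylated_in] <- lev[methylated_in]
    inter <- sites$pattern == "intermediate"
    p[inter] <- inter_band()[inter]
    set(sites, j = paste0("p_", g), value = p)
  }
  setkey(sites, contig, pos, strand)
  sites[]
}
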