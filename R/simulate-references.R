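#' Simulate homoeologous sub-genome references
#'
#' Draws an ancestral reference sequence per contig and derives the three
#' sub-genome sequences (A, B, D) by substituting alleles at divergent
#' positions. Divergent positions arise at rate \code{snp_rate}; each is
#' biallelic (one genome carries a different base) with probability
#' \code{1 - triallelic_prob}, otherwise all three genomes differ. An extra
#' SNP-free control contig emulates the unmethylated chloroplast and always
#' contains at least 1000 cytosines.
#'
#' The shared ancestral sequence doubles as the mapping reference: simulated
#' reads are reported in its coordinates, exactly as captured bisulfite
#' reads of an allopolyploid are mapped to a single extended-bait reference.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{sim_reference} with elements
#'   \code{reference} (named \code{DNAStringSet}, ancestral contigs plus the
#'   control), \code{genomes} (list of per-genome \code{DNAStringSet}s over
#'   the shared contigs), \code{snps} (\code{data.table}: \code{contig},
#'   \code{pos} 0-based, \code{ref}, \code{allele_A}, \code{allele_B},
#'   \code{allele_D}), and \code{control_contig}.
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  gc <- config$gc_content
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  contigs <- sprintf("contig_%02d", seq_len(config$n_contigs))

  ref <- list(); gen <- list(A = list(), B = list(), D = list())
  snps <- vector("list", config$n_contigs)
  for (i in seq_len(config$n_contigs)) {
    L <- config$contig_length
    anc <- sample(BASES, L, replace = TRUE, prob = base_prob)
    div <- which(runif(L) < config$snp_rate)
    gA <- gB <- gD <- anc
    if (length(div)) {
      tri <- runif(length(div)) < config$triallelic_prob
      aA <- aB <- aD <- anc[div]
      ## biallelic: one genome (uniformly chosen) carries an alternative base
      nbi <- sum(!tri)
      if (nbi) {
        who <- sample(GENOMES, nbi, replace = TRUE)
        alt <- vapply(anc[div][!tri],
                      function(b) sample(setdiff(BASES, b), 1L), character(1))
        aA[!tri][who == "A"] <- alt[who == "A"]
        aB[!tri][who == "B"] <- alt[who == "B"]
        aD[!tri][who == "D"] <- alt[who == "D"]
      }
      ## triallelic: three distinct alleles (the ancestral base plus two
      ## alternatives) shuffled over the genomes
      if (any(tri)) {
        for (j in which(tri)) {
          alleles <- sample(c(anc[div][j],
                              sample(setdiff(BASES, anc[div][j]), 2L)))
          aA[j] <- alleles[1]; aB[j] <- alleles[2]; aD[j] <- alleles[3]
        }
      }
      gA[div] <- aA; gB[div] <- aB; gD[div] <- aD
      snps[[i]] <- data.table(contig = contigs[i], pos = div - 1L,
                              ref = anc[div], allele_A = aA, allele_B = aB,
                              allele_D = aD)
    }
    ref[[contigs[i]]] <- paste(anc, collapse = "")
    gen$A[[contigs[i]]] <- paste(gA, collapse = "")
    gen$B[[contigs[i]]] <- paste(gB, collapse = "")
    gen$D[[contigs[i]]] <- paste(gD, collapse = "")
  }
  snps <- rbindlist(snps)
  if (nrow(snps) == 0L)
    snps <- data.table(contig = character(), pos = integer(),
                       ref = character(), allele_A = character(),
                       allele_B = character(), allele_D = character())
  ## drop rows where, by chance, no genome actually differs (cannot happen
  ## by construction, but keep the invariant explicit)
  snps <- snps[allele_A != ref | allele_B != ref | allele_D != ref]

  ## SNP-free control contig with >= 1000 cytosines
  repeat {
    ctl <- sample(BASES, config$control_length, replace = TRUE,
                  prob = base_prob)
    if (sum(ctl == "C") >= 1000L) break
  }
  ref[["control"]] <- paste(ctl, collapse = "")

  out <- list(reference = Biostrings::DNAStringSet(unlist(ref)),
              genomes = lapply(gen, function(g)
                Biostrings::DNAStringSet(unlist(g))),
              snps = snps,
              control_contig = "control")
  structure(out, class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf(
    "Homoeologous reference: %d shared contig(s) + control, %d divergent position(s)\n",
    length(x$genomes$A), nrow(x$snps)))
  invisible(x)
}
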