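## Building, filtering and merging the homoeologous SNP catalogue that
## drives sub-genome discrimination.

#' Is an allele triple safe for bisulfite data?
#'
#' A catalogued SNP is unusable on bisulfite-converted reads when any pair
#' of its distinct alleles is \{C,T\} or \{G,A\}: conversion makes the two
#' indistinguishable on one strand. Note that any three distinct bases
#' necessarily contain one of those pairs, so every usable SNP is
#' biallelic.
#'
#' @param allele_A,allele_B,allele_D allele vectors.
#' @return logical vector.
#' @export
is_bisulfite_safe <- function(allele_A, allele_B, allele_D) {
  mapply(function(a, b, d) {
    al <- unique(c(a, b, d))
    if (length(al) < 2L) return(TRUE)
    pairs <- utils::combn(al, 2L, simplify = FALSE)
    !any(vapply(pairs, function(p)
      setequal(p, c("C", "T")) || setequal(p, c("G", "A")), logical(1)))
  }, allele_A, allele_B, allele_D, USE.NAMES = FALSE)
}

#' Remove bisulfite-ambiguous SNPs from a catalogue
#'
#' Drops every SNP whose distinct alleles include a \{C,T\} or \{G,A\}
#' pair, to avoid confusing genuine SNP alleles with C-to-T conversions of
#' unmethylated cytosines. Idempotent; the number removed is attached as
#' attribute \code{"removed"}.
#'
#' @param snps catalogue table with \code{allele_A/B/D}.
#' @return filtered catalogue with \code{bisulfite_safe = TRUE} everywhere.
#' @export
filter_bisulfite_ambiguous <- function(snps) {
  snps <- as.data.table(snps)
  safe <- is_bisulfite_safe(snps$allele_A, snps$allele_B, snps$allele_D)
  out <- copy(snps[safe])
  out[, bisulfite_safe := TRUE]
  setattr(out, "removed", sum(!safe))
  out[]
}

## consensus base of a count vector: the dominant base when it reaches the
## consensus fraction, else NA
consensus_base <- function(bases, counts, consensus) {
  tot <- sum(counts)
  if (tot == 0L) return(NA_character_)
  i <- which.max(counts)
  if (counts[i] / tot >= consensus) bases[i] else NA_character_
}

#' Derive homoeologous SNPs from per-progenitor pileups
#'
#' Emits a SNP at every position where each sub-genome's pileup yields
#' exactly one unambiguous allele at sufficient depth and at least one
#' allele differs, subject to a pooled minor-allele-frequency filter.
#' Positions with a heterozygous (non-consensus) call in any sub-genome
#' are excluded and counted.
#'
#' @param pileup \code{data.table} with columns \code{contig}, \code{pos}
#'   (0-based), \code{genome} (A/B/D), \code{base}, \code{count}.
#' @param min_depth minimum per-genome depth (default 5).
#' @param min_maf pooled minor allele frequency must exceed this (default
#'   0.1).
#' @param consensus fraction of a genome's bases that must agree for an
#'   unambiguous call (default 0.9).
#' @return catalogue \code{data.table} (\code{source = "progenitor"});
#'   attribute \code{"excluded"} counts positions dropped by reason.
#' @export
derive_snps_from_progenitors <- function(pileup, min_depth = 5L,
                                         min_maf = 0.1, consensus = 0.9) {
  pileup <- as.data.table(pileup)
  excluded <- c(low_depth = 0L, heterozygous = 0L, no_divergence = 0L,
                low_maf = 0L)
  out <- pileup[, {
    res <- list(allele_A = NA_character_, allele_B = NA_character_,
                allele_D = NA_character_, keep = FALSE,
                reason = NA_character_)
    depths <- sapply(GENOMES, function(g) sum(count[genome == g]))
    if (any(depths < min_depth)) {
      res$reason <- "low_depth"
    } else {
      al <- sapply(GENOMES, function(g)
        consensus_base(base[genome == g], count[genome == g], consensus))
      if (anyNA(al)) {
        res$reason <- "heterozygous"
      } else if (length(unique(al)) < 2L) {
        res$reason <- "no_divergence"
      } else {
        pooled <- tapply(count, base, sum)
        maf <- if (length(pooled) < 2L) 0 else
          sort(pooled, decreasing = TRUE)[2] / sum(pooled)
        if (maf <= min_maf) {
          res$reason <- "low_maf"
        } else {
          res$allele_A <- al[["A"]]; res$allele_B <- al[["B"]]
          res$allele_D <- al[["D"]]; res$keep <- TRUE
        }
      }
    }
    res
  }, by = .(contig, pos)]
  for (r in names(excluded))
    excluded[r] <- sum(out$reason == r, na.rm = TRUE)
  out <- out[keep == TRUE,
             .(contig, pos, allele_A, allele_B, allele_D,
               source = "progenitor")]
  out[, bisulfite_safe := is_bisulfite_safe(allele_A, allele_B, allele_D)]
  setkey(out, contig, pos)
  setattr(out, "excluded", excluded)
  out[]
}

#' Derive homoeologous SNPs from genome-assigned untreated reads
#'
#' Uses unconverted reads that already carry a sub-genome (or genome-pair)
#' label to call per-genome alleles: at each position where the pooled
#' reads show an alternative allele (MAF above \code{min_maf}, total depth
#' at least \code{min_depth}), the consensus base over the reads whose
#' label includes a genome defines that genome's allele. Positions where
#' any genome lacks labelled coverage, or where a label has no consensus,
#' are skipped.
#'
#' @param reads read table with columns \code{contig}, \code{pos},
#'   \code{seq} and \code{label} (subsets of "A"/"B"/"D", e.g. "A", "BD").
#' @param reference named \code{DNAStringSet} (defines positions).
#' @param min_depth,min_maf,consensus as in
#'   \code{\link{derive_snps_from_progenitors}}.
#' @return catalogue \code{data.table} (\code{source = "assigned_reads"}).
#' @export
derive_snps_from_assigned_reads <- function(reads, reference, min_depth = 5L,
                                            min_maf = 0.1, consensus = 0.9) {
  reads <- as.data.table(reads)
  ## expand reads into per-base observations
  sp <- strsplit(reads$seq, "", fixed = TRUE)
  lens <- lengths(sp)
  obs <- data.table(contig = rep(reads$contig, lens),
                    pos = rep(reads$pos, lens) + (sequence(lens) - 1L),
                    label = rep(reads$label, lens),
                    base = unlist(sp, use.names = FALSE))
  obs <- obs[base %in% BASES]
  counts <- obs[, .(count = .N), by = .(contig, pos, label, base)]
  out <- counts[, {
    pooled <- tapply(count, base, sum)
    tot <- sum(pooled)
    maf <- if (length(pooled) < 2L) 0 else
      sort(pooled, decreasing = TRUE)[2] / tot
    res <- list(allele_A = NA_character_, allele_B = NA_character_,
                allele_D = NA_character_, keep = FALSE)
    if (tot >= min_depth && maf > min_maf) {
      al <- sapply(GENOMES, function(g) {
        sel <- grepl(g, label)
        if (sum(count[sel]) < min_depth) return(NA_character_)
        agg <- tapply(count[sel], base[sel], sum)
        consensus_base(names(agg), as.integer(agg), consensus)
      })
      if (!anyNA(al) && length(unique(al)) >= 2L) {
        res$allele_A <- al[["A"]]; res$allele_B <- al[["B"]]
        res$allele_D <- al[["D"]]; res$keep <- TRUE
      }
    }
    res
  }, by = .(contig, pos)]
  out <- out[keep == TRUE,
             .(contig, pos, allele_A, allele_B, allele_D,
               source = "assigned_reads")]
  out[, bisulfite_safe := is_bisulfite_safe(allele_A, allele_B, allele_D)]
  setkey(out, contig, pos)
  out[]
}

#' Merge two homoeologous SNP catalogues
#'
#' Takes the union keyed on (contig, position). At shared positions the
#' allele triples are compared: the fraction of shared positions with
#' identical alleles is the conservation statistic (reported as attribute
#' \code{"conservation"}; \code{NA} when nothing is shared). Conflicting
#' positions are resolved by policy — the default keeps the primary
#' (progenitor-derived) alleles, treating the secondary source as
#' gap-filling only. Shared positions get \code{source = "merged"}.
#'
#' @param primary,secondary catalogue tables.
#' @param policy \code{"prefer_primary"} (default) or \code{"drop"}
#'   (conflicting positions removed).
#' @return merged catalogue with attributes \code{"conservation"},
#'   \code{"n_shared"}, \code{"n_conflict"}.
#' @export
merge_snp_sources <- function(primary, secondary,
                              policy = c("prefer_primary", "drop")) {
  policy <- match.arg(policy)
  primary <- as.data.table(primary); secondary <- as.data.table(secondary)
  key <- c("contig", "pos")
  shared <- merge(primary, secondary, by = key, suffixes = c("", ".2"))
  agree <- shared[, allele_A == allele_A.2 & allele_B == allele_B.2 &
                    allele_D == allele_D.2]
  n_shared <- nrow(shared); n_conflict <- sum(!agree)
  conservation <- if (n_shared == 0L) NA_real_ else mean(agree)
  only1 <- primary[!secondary, on = key]
  only2 <- secondary[!primary, on = key]
  kept <- shared[, .(contig, pos, allele_A, allele_B, allele_D,
                     source = "merged")]
  if (policy == "drop") kept <- kept[agree]
  out <- rbindlist(list(
    only1[, .(contig, pos, allele_A, allele_B, allele_D, source)],
    only2[, .(contig, pos, allele_A, allele_B, allele_D, source)],
    kept), use.names = TRUE)
  out[, bisulfite_safe := is_bisulfite_safe(allele_A, allele_B, allele_D)]
  setkey(out, contig, pos)
  setattr(out, "conservation", conservation)
  setattr(out, "n_shared", n_shared)
  setattr(out, "n_conflict", n_conflict)
  out[]
}
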