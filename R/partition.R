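## Assignment of SNP-overlapping bisulfite reads to sub-genomes (or genome
## pairs) and per-site methylation tallies with coverage gates.

MASK_LABEL <- c("UNASSIGNED", "A", "B", "AB", "D", "AD", "BD", "ABD")

label_to_mask <- function(label) {
  m <- match(label, MASK_LABEL) - 1L
  if (anyNA(m)) stop_input("unknown genome label '%s'",
                           label[which(is.na(m))[1]])
  m
}

#' Combine genome labels observed at multiple SNPs of one read
#'
#' Labels are subsets of \{A, B, D\}; combining is set intersection, so a
#' single-genome label contained in a pair refines it (A and AB give A)
#' while contradictory labels (A and BD) give \code{UNASSIGNED}. The
#' uninformative full set ABD never constrains the result.
#'
#' @param labels character vector of labels
#'   (\code{A/B/D/AB/AD/BD/ABD/UNASSIGNED}).
#' @return a single combined label.
#' @examples
#' combine_genome_labels(c("A", "AB"))  # "A"
#' combine_genome_labels(c("A", "BD"))  # "UNASSIGNED"
#' @export
combine_genome_labels <- function(labels) {
  if (length(labels) == 0L) return("UNASSIGNED")
  MASK_LABEL[Reduce(bitwAnd, label_to_mask(labels), accumulate = FALSE) + 1L]
}

## conversion-compatibility: on a CT strand product a read T also matches
## allele C (possibly-converted), on a GA product a read A also matches
## allele G; catalogue filtering guarantees this never makes two alleles
## of one SNP indistinguishable
base_matches_allele <- function(base, allele, xg) {
  base == allele |
    (xg == "CT" & base == "T" & allele == "C") |
    (xg == "GA" & base == "A" & allele == "G")
}

#' Assign reads to sub-genomes via homoeologous SNPs
#'
#' Compares each read's base at every overlapping catalogue SNP with the
#' three sub-genome alleles under the conversion-compatibility rule and
#' intersects the per-SNP matches. A unique surviving genome gives a
#' single-genome label, two genomes a pair label; reads with no overlapping
#' SNP, contradictory SNPs, a non-matching base (sequencing error) or a
#' mapping quality at or below \code{mapq_min} are \code{UNASSIGNED} and
#' counted by reason.
#'
#' @param reads read table (\code{\link{read_bisulfite_sam}} /
#'   \code{\link{simulate_reads}} format).
#' @param snps bisulfite-safe SNP catalogue
#'   (\code{\link{filter_bisulfite_ambiguous}} output); unsafe entries are
#'   rejected.
#' @param thresholds a \code{\link{meth_thresholds}} (for
#'   \code{mapq_min}).
#' @return \code{data.table} with \code{qname}, \code{label},
#'   \code{n_snps}; attribute \code{"unassigned"} counts reads by reason.
#' @export
assign_reads <- function(reads, snps, thresholds = meth_thresholds()) {
  reads <- as.data.table(reads)
  snps <- as.data.table(snps)
  if ("bisulfite_safe" %in% names(snps) && any(!snps$bisulfite_safe))
    stop_input("catalogue contains bisulfite-ambiguous SNPs; run filter_bisulfite_ambiguous() first")
  rd <- reads[, .(qname, contig, start = pos, end = pos + nchar(seq) - 1L,
                  xg, mapq, seq)]
  sn <- snps[, .(contig, start = pos, end = pos, allele_A, allele_B,
                 allele_D)]
  setkey(rd, contig, start, end)
  setkey(sn, contig, start, end)
  ov <- foverlaps(sn, rd, type = "within", nomatch = NULL)
  ## read base at the SNP position
  ov[, base := substring(seq, i.start - start + 1L, i.start - start + 1L)]
  ov[, mask := 1L * base_matches_allele(base, allele_A, xg) +
       2L * base_matches_allele(base, allele_B, xg) +
       4L * base_matches_allele(base, allele_D, xg)]
  agg <- ov[, .(mask = Reduce(bitwAnd, mask), n_snps = .N), by = qname]
  ## one row per fragment: paired mates share the qname and combine
  out <- merge(reads[, .(mapq = max(mapq)), by = qname], agg,
               by = "qname", all.x = TRUE)
  out[is.na(mask), `:=`(mask = 0L, n_snps = 0L)]
  out[, label := MASK_LABEL[mask + 1L]]
  counts <- c(low_mapq = sum(out$mapq <= thresholds$mapq_min),
              no_snp = sum(out$n_snps == 0L & out$mapq > thresholds$mapq_min),
              conflict_or_mismatch = sum(out$n_snps > 0L & out$mask == 0L &
                                           out$mapq > thresholds$mapq_min),
              uninformative = sum(out$label == "ABD" &
                                    out$mapq > thresholds$mapq_min))
  out[mapq <= thresholds$mapq_min, label := "UNASSIGNED"]
  out[label == "ABD", label := "UNASSIGNED"]
  out[, mask := NULL]
  setattr(out, "unassigned", counts)
  out[]
}

## the three biallelic partitions: the resolved single genome vs the pair
PARTITIONS <- list(single = c("A", "B", "D"), pair = c("BD", "AD", "AB"))

finalize_tally <- function(wide, thresholds) {
  if (nrow(wide) == 0L) {
    wide[, `:=`(mode = character(), partition = character(),
                passes_coverage = logical())]
    return(wide)
  }
  sd <- thresholds$single_depth; pd <- thresholds$pair_depth
  wide[, mode := ifelse(t_A >= sd & t_B >= sd & t_D >= sd,
                        "tri_resolved", "biallelic_pair")]
  ## dominant biallelic partition: single + pair coverage, pair counts
  ## absorbing the member genomes' single-labelled reads
  pt <- lapply(seq_along(PARTITIONS$single), function(i) {
    s <- PARTITIONS$single[i]; p <- PARTITIONS$pair[i]
    members <- strsplit(p, "")[[1]]
    list(single_t = wide[[paste0("t_", s)]],
         pair_t = wide[[paste0("t_", p)]] +
           Reduce(`+`, lapply(members, function(m) wide[[paste0("t_", m)]])))
  })
  cov <- vapply(pt, function(x) x$single_t + x$pair_t,
                numeric(nrow(wide)))
  cov <- matrix(cov, nrow = nrow(wide))
  best <- max.col(cov, ties.method = "first")
  wide[, partition := ifelse(mode == "tri_resolved", NA_character_,
                             paste0(PARTITIONS$single[best], "|",
                                    PARTITIONS$pair[best]))]
  singles <- vapply(seq_len(nrow(wide)), function(i)
    pt[[best[i]]]$single_t[i], numeric(1))
  pairs <- vapply(seq_len(nrow(wide)), function(i)
    pt[[best[i]]]$pair_t[i], numeric(1))
  wide[, passes_coverage := mode == "tri_resolved" |
         (singles >= sd & pairs >= pd)]
  wide
}

#' Tally per-site, per-genome methylation counts
#'
#' Joins site observations with read genome labels and accumulates
#' methylated/total counts per label (A, B, D, AB, AD, BD). A site is
#' \code{tri_resolved} when all three single genomes individually reach the
#' single-genome depth gate (5x by default); otherwise it is
#' \code{biallelic_pair} with the dominant partition (e.g. A|BD), whose
#' pair counts absorb single-labelled reads of the member genomes, and
#' passes coverage when the single genome reaches 5x and the pair 10x.
#' Observations from reads at or below the mapping-quality cutoff or
#' without a genome label do not contribute.
#'
#' @param calls site observations from \code{\link{extract_site_calls}}.
#' @param assignments read labels from \code{\link{assign_reads}}.
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return \code{data.table} keyed by site with count columns
#'   \code{m_A/t_A ... m_BD/t_BD}, \code{mode}, \code{partition},
#'   \code{passes_coverage}.
#' @export
tally_site_counts <- function(calls, assignments,
                              thresholds = meth_thresholds()) {
  calls <- as.data.table(calls)
  obs <- merge(calls[mapq > thresholds$mapq_min],
               as.data.table(assignments)[, .(qname, label)],
               by = "qname")
  obs <- obs[label %in% c(GENOMES, PAIRS)]
  cnt <- obs[, .(m = sum(methylated), t = .N),
             by = .(contig, pos, strand, context, label)]
  if (nrow(cnt) == 0L) {
    wide <- data.table(contig = character(), pos = integer(),
                       strand = character(), context = character())
  } else {
    wide <- dcast(cnt, contig + pos + strand + context ~ label,
                  value.var = c("m", "t"), fill = 0L)
  }
  for (lab in c(GENOMES, PAIRS)) {
    for (pref in c("m_", "t_")) {
      col <- paste0(pref, lab)
      if (!col %in% names(wide)) set(wide, j = col, value = 0L)
    }
  }
  setcolorder(wide, c("contig", "pos", "strand", "context",
                      as.vector(t(outer(c("m_", "t_"), c(GENOMES, PAIRS),
                                        paste0)))))
  finalize_tally(wide, thresholds)
  setkey(wide, contig, pos, strand)
  wide[]
}

#' Pool replicate site tallies
#'
#' Sums the per-label counts of the same site across replicates and
#' re-evaluates resolution mode and coverage gates on the pooled counts,
#' which is equivalent to tallying the concatenated reads.
#'
#' @param tallies list of \code{\link{tally_site_counts}} outputs.
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return pooled tally table.
#' @export
pool_site_counts <- function(tallies, thresholds = meth_thresholds()) {
  stopifnot(length(tallies) >= 1L)
  all <- rbindlist(lapply(tallies, as.data.table), use.names = TRUE,
                   fill = TRUE)
  countcols <- as.vector(t(outer(c("m_", "t_"), c(GENOMES, PAIRS), paste0)))
  for (col in countcols) {
    if (!col %in% names(all)) set(all, j = col, value = 0L)
    nas <- which(is.na(all[[col]]))
    if (length(nas)) set(all, nas, col, 0L)
  }
  pooled <- all[, lapply(.SD, sum), by = .(contig, pos, strand, context),
                .SDcols = countcols]
  finalize_tally(pooled, thresholds)
  setkey(pooled, contig, pos, strand)
  pooled[]
}
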