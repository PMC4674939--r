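## Per-region methylation summaries and DMR calling. Regions are the
## analysis units supplied in the annotation (extended bait probes in the
## targeted design); there is no sliding window.

#' Summarize methylation per region and sub-genome
#'
#' Pools the single-genome read counts of all coverage-passing sites
#' inside each region (read-weighted: summed methylated reads over summed
#' total reads per genome).
#'
#' @param tally site counts (\code{\link{tally_site_counts}} /
#'   \code{\link{pool_site_counts}}).
#' @param regions region annotation table.
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return \code{data.table} per region: \code{n_sites}, pooled
#'   \code{m_X}/\code{t_X} and percentage \code{pct_X} per genome.
#' @export
summarize_regions <- function(tally, regions,
                              thresholds = meth_thresholds()) {
  tally <- as.data.table(tally)[passes_coverage == TRUE]
  regions <- as.data.table(regions)
  hits <- region_overlaps(tally, regions)
  if (!length(hits$site_idx))
    return(data.table(region_id = character(), class = character(),
                      n_sites = integer()))
  dt <- tally[hits$site_idx]
  dt[, `:=`(region_id = regions$region_id[hits$region_idx],
            class = regions$class[hits$region_idx])]
  out <- dt[, c(list(n_sites = .N),
                unlist(lapply(GENOMES, function(g)
                  stats::setNames(list(sum(.SD[[paste0("m_", g)]]),
                                       sum(.SD[[paste0("t_", g)]])),
                                  paste0(c("m_", "t_"), g))),
                       recursive = FALSE)),
            by = .(region_id, class)]
  for (g in GENOMES)
    out[, (paste0("pct_", g)) :=
          ifelse(get(paste0("t_", g)) > 0,
                 100 * get(paste0("m_", g)) / get(paste0("t_", g)),
                 NA_real_)]
  setkey(out, region_id)
  out[]
}

#' Call sub-genome-specific differentially methylated regions
#'
#' A region is a DMR for genome X when X is at least 25 percentage points
#' more methylated than each of the other two genomes and both X-versus-Y
#' Fisher tests on the pooled regional counts reach q < 0.01
#' (Benjamini-Hochberg within each genome pairing across regions). At most
#' one genome can qualify per region. Regions missing counts for any
#' genome are skipped and counted.
#'
#' @param summaries \code{\link{summarize_regions}} output.
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return \code{data.table} of DMRs (\code{region_id}, \code{class},
#'   \code{dmr_genome}, per-genome percentages, \code{min_diff},
#'   \code{max_q}); attribute \code{"n_skipped"} counts regions without
#'   full genome data.
#' @export
call_genome_specific_dmr <- function(summaries,
                                     thresholds = meth_thresholds()) {
  s <- as.data.table(summaries)
  full <- s[t_A > 0 & t_B > 0 & t_D > 0]
  n_skipped <- nrow(s) - nrow(full)
  cmp <- list(AB = c("A", "B"), AD = c("A", "D"), BD = c("B", "D"))
  tests <- lapply(cmp, function(pr)
    test_differential(full[[paste0("m_", pr[1])]],
                      full[[paste0("t_", pr[1])]],
                      full[[paste0("m_", pr[2])]],
                      full[[paste0("t_", pr[2])]],
                      min_diff = thresholds$dmr_diff,
                      q_cutoff = thresholds$q_cutoff))
  defining <- list(A = c("AB", "AD"), B = c("AB", "BD"), D = c("AD", "BD"))
  rows <- list()
  for (g in GENOMES) {
    others <- setdiff(GENOMES, g)
    d1 <- full[[paste0("pct_", g)]] - full[[paste0("pct_", others[1])]]
    d2 <- full[[paste0("pct_", g)]] - full[[paste0("pct_", others[2])]]
    q1 <- tests[[defining[[g]][1]]]$q
    q2 <- tests[[defining[[g]][2]]]$q
    hit <- which(d1 >= thresholds$dmr_diff & d2 >= thresholds$dmr_diff &
                   !is.na(q1) & q1 < thresholds$q_cutoff &
                   !is.na(q2) & q2 < thresholds$q_cutoff)
    if (length(hit))
      rows[[g]] <- full[hit, .(region_id, class, dmr_genome = g,
                               pct_A, pct_B, pct_D,
                               min_diff = pmin(d1[hit], d2[hit]),
                               max_q = pmax(q1[hit], q2[hit]))]
  }
  out <- if (length(rows)) rbindlist(rows) else
    data.table(region_id = character(), class = character(),
               dmr_genome = character(), pct_A = numeric(),
               pct_B = numeric(), pct_D = numeric(),
               min_diff = numeric(), max_q = numeric())
  setkey(out, region_id)
  setattr(out, "n_skipped", n_skipped)
  out[]
}

#' Call between-sample differentially methylated regions
#'
#' Compares the pooled regional counts of the two samples per sub-genome
#' (Fisher exact, difference \eqn{\ge} 25 \%, q < 0.01 per genome family).
#'
#' @param summaries1,summaries2 \code{\link{summarize_regions}} outputs of
#'   the two samples.
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return \code{data.table} of DMRs with \code{genome}, per-sample
#'   percentages, \code{diff}, \code{q}.
#' @export
call_between_sample_dmr <- function(summaries1, summaries2,
                                    thresholds = meth_thresholds()) {
  mg <- merge(as.data.table(summaries1), as.data.table(summaries2),
              by = c("region_id", "class"), suffixes = c(".1", ".2"))
  rows <- list()
  for (g in GENOMES) {
    t1 <- mg[[paste0("t_", g, ".1")]]; t2 <- mg[[paste0("t_", g, ".2")]]
    ok <- which(t1 > 0 & t2 > 0)
    if (!length(ok)) next
    tst <- test_differential(mg[[paste0("m_", g, ".1")]][ok], t1[ok],
                             mg[[paste0("m_", g, ".2")]][ok], t2[ok],
                             min_diff = thresholds$dmr_diff,
                             q_cutoff = thresholds$q_cutoff)
    hit <- ok[tst$significant]
    if (length(hit))
      rows[[g]] <- data.table(
        region_id = mg$region_id[hit], class = mg$class[hit], genome = g,
        pct_1 = 100 * mg[[paste0("m_", g, ".1")]][hit] / t1[hit],
        pct_2 = 100 * mg[[paste0("m_", g, ".2")]][hit] / t2[hit],
        diff = tst$diff[tst$significant], q = tst$q[tst$significant])
  }
  out <- if (length(rows)) rbindlist(rows) else
    data.table(region_id = character(), class = character(),
               genome = character(), pct_1 = numeric(), pct_2 = numeric(),
               diff = numeric(), q = numeric())
  setkey(out, region_id)
  out[]
}
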