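## Methylation state calling with polyploid-specific thresholds, and
## uni-/bi-/tri-genome pattern classification.

#' Call the methylation state of count data
#'
#' Applies the context-specific thresholds: CpG sites are methylated at
#' \eqn{\ge} 75 \% and unmethylated at \eqn{\le} 25 \%; CHG/CHH sites are
#' methylated above 10 \% and unmethylated at 0 \%, anything in between
#' being intermediate. When \code{conversion_background > 0} the level is
#' first corrected for incomplete bisulfite conversion: methylated counts
#' consistent with the background failure rate (one-sided binomial test at
#' \code{background_alpha}) are treated as 0 \%, otherwise the
#' background-subtracted rescaled level \eqn{(\ell - b)/(1 - b)} is used.
#' Sites with zero coverage give \code{NoCall}.
#'
#' @param m,t methylated and total read counts (vectors).
#' @param context \code{"CpG"}, \code{"CHG"} or \code{"CHH"} (recycled).
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return \code{data.table} with \code{state} in
#'   \code{c("Methylated","Unmethylated","Intermediate","NoCall")} and the
#'   (corrected) \code{level} in percent.
#' @examples
#' call_methylation_state(8, 10, "CpG")   # 80 % -> Methylated
#' call_methylation_state(5, 10, "CpG")   # 50 % -> Intermediate
#' call_methylation_state(2, 16, "CHH")   # 12.5 % -> Methylated
#' @export
call_methylation_state <- function(m, t, context,
                                   thresholds = meth_thresholds()) {
  n <- max(length(m), length(t), length(context))
  m <- rep_len(m, n); t <- rep_len(t, n); context <- rep_len(context, n)
  level <- ifelse(t > 0, 100 * m / t, NA_real_)
  bg <- thresholds$conversion_background
  if (bg > 0) {
    above <- pbinom(m - 1, t, bg, lower.tail = FALSE) <=
      thresholds$background_alpha
    level <- ifelse(t > 0,
                    ifelse(above,
                           pmax(0, 100 * (m / t - bg) / (1 - bg)), 0),
                    NA_real_)
  }
  state <- rep("NoCall", n)
  cpg <- context == "CpG" & t > 0
  state[cpg & level >= thresholds$cpg_meth] <- "Methylated"
  state[cpg & level <= thresholds$cpg_unmeth] <- "Unmethylated"
  state[cpg & state == "NoCall"] <- "Intermediate"
  non <- context != "CpG" & t > 0
  state[non & level > thresholds$non_cpg_meth] <- "Methylated"
  state[non & level == 0] <- "Unmethylated"
  state[non & state == "NoCall"] <- "Intermediate"
  data.table(state = state, level = level)
}

## pair-mode counts of the dominant partition
partition_counts <- function(tally) {
  single <- sub("\\|.*", "", tally$partition)
  pairlab <- sub(".*\\|", "", tally$partition)
  g1 <- substring(pairlab, 1, 1); g2 <- substring(pairlab, 2, 2)
  pick <- function(pref, lab) {
    cols <- paste0(pref, c(GENOMES, PAIRS))
    mat <- as.matrix(tally[, cols, with = FALSE])
    mat[cbind(seq_len(nrow(tally)), match(paste0(pref, lab), cols))]
  }
  list(single = single, pair = pairlab,
       m_s = pick("m_", single), t_s = pick("t_", single),
       m_p = pick("m_", pairlab) + pick("m_", g1) + pick("m_", g2),
       t_p = pick("t_", pairlab) + pick("t_", g1) + pick("t_", g2))
}

#' Classify uni-/bi-/tri-genome methylation patterns per site
#'
#' Combines the per-genome methylation states with Fisher exact
#' differential tests:
#' \itemize{
#'   \item tri-resolved sites use the three single-genome counts; a site
#'     is \code{tri} when all three are methylated, \code{uni_X} when only
#'     X is methylated and both X-versus-other comparisons are significant
#'     (difference \eqn{\ge} 50 \%, q < 0.01), \code{bi_XY} when X and Y
#'     are methylated and both comparisons against the third genome are
#'     significant, \code{none} when all are unmethylated;
#'   \item biallelic sites use the single genome against the pooled pair
#'     under the same logic, the pair state standing for "both genomes
#'     share the state";
#'   \item any intermediate state — including a methylation difference
#'     that fails the significance test — makes the site
#'     \code{intermediate}.
#' }
#' q-values are Benjamini-Hochberg within each comparison family (one
#' family per genome pairing across all sites of the call).
#'
#' @param tally site counts from \code{\link{tally_site_counts}} or
#'   \code{\link{pool_site_counts}}.
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @param exclude optional site keys (\code{contig}, \code{pos},
#'   \code{strand}) to drop before classification, e.g. from
#'   \code{\link{filter_replicate_noise}}.
#' @return \code{data.table} with site columns, per-genome corrected
#'   levels, the \code{pattern} and the weakest defining comparison's
#'   \code{diff}, \code{p}, \code{q} (NA where no test defines the
#'   pattern). Sites failing the coverage gate carry pattern \code{NA}.
#' @export
classify_site_patterns <- function(tally, thresholds = meth_thresholds(),
                                   exclude = NULL) {
  tally <- as.data.table(tally)
  if (!is.null(exclude) && nrow(as.data.table(exclude)))
    tally <- tally[!as.data.table(exclude), on = c("contig", "pos", "strand")]
  out <- tally[, .(contig, pos, strand, context, mode, partition,
                   passes_coverage)]
  out[, `:=`(pattern = NA_character_, level_A = NA_real_,
             level_B = NA_real_, level_D = NA_real_, level_pair = NA_real_,
             diff = NA_real_, p = NA_real_, q = NA_real_)]
  if (nrow(tally) == 0L) return(out[])

  ## ---- tri-resolved sites ----
  tri <- which(tally$mode == "tri_resolved" & tally$passes_coverage)
  if (length(tri)) {
    tt <- tally[tri]
    st <- lapply(GENOMES, function(g)
      call_methylation_state(tt[[paste0("m_", g)]], tt[[paste0("t_", g)]],
                             tt$context, thresholds))
    names(st) <- GENOMES
    cmp <- list(AB = c("A", "B"), AD = c("A", "D"), BD = c("B", "D"))
    tests <- lapply(cmp, function(pr)
      test_differential(tt[[paste0("m_", pr[1])]], tt[[paste0("t_", pr[1])]],
                        tt[[paste0("m_", pr[2])]], tt[[paste0("t_", pr[2])]],
                        min_diff = thresholds$within_sample_diff,
                        q_cutoff = thresholds$q_cutoff))
    states <- cbind(A = st$A$state, B = st$B$state, D = st$D$state)
    nM <- rowSums(states == "Methylated")
    anyI <- rowSums(states == "Intermediate") > 0
    pat <- rep("intermediate", length(tri))
    pat[!anyI & nM == 3] <- "tri"
    pat[!anyI & nM == 0] <- "none"
    ## comparisons defining each uni/bi candidate
    defining <- list(
      uni_A = c("AB", "AD"), uni_B = c("AB", "BD"), uni_D = c("AD", "BD"),
      bi_AB = c("AD", "BD"), bi_AD = c("AB", "BD"), bi_BD = c("AB", "AD"))
    cand <- rep(NA_character_, length(tri))
    one <- !anyI & nM == 1
    cand[one] <- paste0("uni_", GENOMES[max.col(
      1 * (states[one, , drop = FALSE] == "Methylated"))])
    two <- !anyI & nM == 2
    if (any(two)) {
      unm <- GENOMES[max.col(1 * (states[two, , drop = FALSE] ==
                                    "Unmethylated"))]
      cand[two] <- paste0("bi_", vapply(unm, function(g)
        paste(setdiff(GENOMES, g), collapse = ""), character(1)))
    }
    for (i in which(!is.na(cand))) {
      df <- defining[[cand[i]]]
      t1 <- tests[[df[1]]][i]; t2 <- tests[[df[2]]][i]
      ok <- isTRUE(t1$significant) && isTRUE(t2$significant)
      pat[i] <- if (ok) cand[i] else "intermediate"
      set(out, tri[i], c("diff", "p", "q"),
          list(min(t1$diff, t2$diff), max(t1$p, t2$p), max(t1$q, t2$q)))
    }
    set(out, tri, "pattern", pat)
    set(out, tri, "level_A", st$A$level)
    set(out, tri, "level_B", st$B$level)
    set(out, tri, "level_D", st$D$level)
  }

  ## ---- biallelic-pair sites ----
  bi <- which(tally$mode == "biallelic_pair" & tally$passes_coverage)
  if (length(bi)) {
    bt <- tally[bi]
    pc <- partition_counts(bt)
    st_s <- call_methylation_state(pc$m_s, pc$t_s, bt$context, thresholds)
    st_p <- call_methylation_state(pc$m_p, pc$t_p, bt$context, thresholds)
    tst <- test_differential(pc$m_s, pc$t_s, pc$m_p, pc$t_p,
                             min_diff = thresholds$within_sample_diff,
                             q_cutoff = thresholds$q_cutoff)
    sM <- st_s$state == "Methylated"; sU <- st_s$state == "Unmethylated"
    pM <- st_p$state == "Methylated"; pU <- st_p$state == "Unmethylated"
    pat <- rep("intermediate", length(bi))
    pat[sM & pM] <- "tri"
    pat[sU & pU] <- "none"
    uni <- sM & pU
    pat[uni] <- ifelse(tst$significant[uni],
                       paste0("uni_", pc$single[uni]), "intermediate")
    biM <- sU & pM
    pat[biM] <- ifelse(tst$significant[biM],
                       paste0("bi_", pc$pair[biM]), "intermediate")
    set(out, bi, "pattern", pat)
    for (g in GENOMES) {
      sel <- pc$single == g
      if (any(sel))
        set(out, bi[sel], paste0("level_", g), st_s$level[sel])
    }
    set(out, bi, "level_pair", st_p$level)
    used <- uni | biM
    set(out, bi[used], c("diff", "p", "q"),
        list(tst$diff[used], tst$p[used], tst$q[used]))
  }
  setkey(out, contig, pos, strand)
  out[]
}

#' Exclude sites with replicate-to-replicate methylation noise
#'
#' Runs every within-condition pairwise replicate comparison per genome
#' label (Fisher exact, difference \eqn{\ge} 50 \%, q < 0.01 within each
#' replicate-pair/label family) and returns the sites where any comparison
#' is significant — "background methylation" to be removed before all
#' sample-wise comparisons.
#'
#' @param tallies list of per-replicate \code{\link{tally_site_counts}}
#'   outputs (one condition).
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return \code{data.table} of excluded site keys (\code{contig},
#'   \code{pos}, \code{strand}); empty for a single replicate.
#' @export
filter_replicate_noise <- function(tallies, thresholds = meth_thresholds()) {
  empty <- data.table(contig = character(), pos = integer(),
                      strand = character())
  if (length(tallies) < 2L) return(empty)
  labs <- c(GENOMES, PAIRS)
  excl <- list()
  for (i in seq_len(length(tallies) - 1L)) {
    for (j in seq(i + 1L, length(tallies))) {
      mg <- merge(as.data.table(tallies[[i]]), as.data.table(tallies[[j]]),
                  by = c("contig", "pos", "strand", "context"),
                  suffixes = c(".1", ".2"))
      for (lab in labs) {
        t1 <- mg[[paste0("t_", lab, ".1")]]
        t2 <- mg[[paste0("t_", lab, ".2")]]
        sel <- which(t1 > 0 & t2 > 0)
        if (!length(sel)) next
        tst <- test_differential(mg[[paste0("m_", lab, ".1")]][sel], t1[sel],
                                 mg[[paste0("m_", lab, ".2")]][sel], t2[sel],
                                 min_diff = thresholds$within_sample_diff,
                                 q_cutoff = thresholds$q_cutoff)
        hit <- sel[tst$significant]
        if (length(hit))
          excl[[length(excl) + 1L]] <- mg[hit, .(contig, pos, strand)]
      }
    }
  }
  if (!length(excl)) return(empty)
  unique(rbindlist(excl))
}

#' Compare pooled samples per sub-genome
#'
#' Between-sample comparisons are within a genome (A against A, B against
#' B, D against D) on pooled replicate counts, with the relaxed 25 \%
#' minimum difference enabled by the higher pooled coverage. Sites flagged
#' by replicate noise should be excluded beforehand (pass \code{exclude}).
#'
#' @param tally1,tally2 pooled site tallies of the two samples.
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @param exclude optional site keys to drop (replicate noise).
#' @return \code{data.table} of sites where at least one genome changes
#'   significantly, with per-genome diff/q columns, \code{n_changed} and
#'   \code{change_class} (\code{uni}/\code{bi}/\code{tri}); attribute
#'   \code{"n_tested"} gives the number of comparable sites.
#' @export
compare_between_samples <- function(tally1, tally2,
                                    thresholds = meth_thresholds(),
                                    exclude = NULL) {
  t1 <- as.data.table(tally1); t2 <- as.data.table(tally2)
  if (!is.null(exclude) && nrow(as.data.table(exclude))) {
    t1 <- t1[!as.data.table(exclude), on = c("contig", "pos", "strand")]
    t2 <- t2[!as.data.table(exclude), on = c("contig", "pos", "strand")]
  }
  mg <- merge(t1, t2, by = c("contig", "pos", "strand", "context"),
              suffixes = c(".1", ".2"))
  out <- mg[, .(contig, pos, strand, context)]
  for (g in GENOMES) {
    ok <- mg[[paste0("t_", g, ".1")]] >= thresholds$single_depth &
      mg[[paste0("t_", g, ".2")]] >= thresholds$single_depth
    res <- data.table(diff = NA_real_, q = NA_real_,
                      sig = rep(FALSE, nrow(mg)))
    if (any(ok)) {
      tst <- test_differential(
        mg[[paste0("m_", g, ".1")]][ok], mg[[paste0("t_", g, ".1")]][ok],
        mg[[paste0("m_", g, ".2")]][ok], mg[[paste0("t_", g, ".2")]][ok],
        min_diff = thresholds$between_sample_diff,
        q_cutoff = thresholds$q_cutoff)
      res[which(ok), `:=`(diff = tst$diff, q = tst$q, sig = tst$significant)]
    }
    out[, (paste0(c("diff_", "q_", "sig_"), g)) :=
          .(res$diff, res$q, res$sig)]
  }
  out[, n_changed := sig_A + sig_B + sig_D]
  res <- out[n_changed > 0]
  res[, change_class := c("uni", "bi", "tri")[n_changed]]
  setattr(res, "n_tested", nrow(out))
  res[]
}

#' Compare a diploid progenitor with one sub-genome
#'
#' Fisher exact comparison of diploid site counts against the
#' corresponding sub-genome's counts in the polyploid, at the stricter
#' 50 \% difference cutoff used for the lower-coverage diploid data. Each
#' significant site is labelled a \code{gain} (sub-genome more methylated
#' than the diploid) or \code{loss}.
#'
#' @param diploid \code{data.table} with \code{contig}, \code{pos},
#'   \code{strand}, \code{context}, \code{m}, \code{t}.
#' @param tally polyploid site tally.
#' @param genome which sub-genome to compare (default \code{"D"}).
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return significant sites with \code{direction} in
#'   \code{c("gain","loss")}; attribute \code{"n_tested"}.
#' @export
compare_diploid_to_subgenome <- function(diploid, tally, genome = "D",
                                         thresholds = meth_thresholds()) {
  diploid <- as.data.table(diploid)
  tally <- as.data.table(tally)
  mg <- merge(diploid, tally, by = c("contig", "pos", "strand", "context"))
  ms <- mg[[paste0("m_", genome)]]; ts <- mg[[paste0("t_", genome)]]
  ok <- mg$t >= thresholds$single_depth & ts >= thresholds$single_depth
  mg <- mg[ok]; ms <- ms[ok]; ts <- ts[ok]
  tst <- test_differential(ms, ts, mg$m, mg$t,
                           min_diff = thresholds$diploid_compare_diff,
                           q_cutoff = thresholds$q_cutoff)
  out <- mg[, .(contig, pos, strand, context,
                level_subgenome = 100 * ms / ts,
                level_diploid = 100 * m / t)]
  out[, `:=`(diff = tst$diff, p = tst$p, q = tst$q)]
  out <- out[tst$significant]
  out[, direction := ifelse(level_subgenome > level_diploid, "gain", "loss")]
  setattr(out, "n_tested", length(ms))
  out[]
}

#' Simple per-site counts without sub-genome partitioning
#'
#' Pools all observations of a site regardless of read labels — the form
#' needed for a diploid sample, which has no homoeologous partitioning.
#'
#' @param calls \code{\link{extract_site_calls}} output.
#' @param thresholds a \code{\link{meth_thresholds}} (mapping-quality
#'   filter).
#' @return \code{data.table} with \code{contig}, \code{pos}, \code{strand},
#'   \code{context}, \code{m}, \code{t}.
#' @export
site_counts_simple <- function(calls, thresholds = meth_thresholds()) {
  as.data.table(calls)[mapq > thresholds$mapq_min,
                       .(m = sum(methylated), t = .N),
                       by = .(contig, pos, strand, context)]
}
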