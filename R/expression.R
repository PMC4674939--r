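#' Normalize allelic expression to a 100 % sum per region
#'
#' Rescales raw per-sub-genome expression so the three sub-genomes of each
#' region sum to 100 \% (0 \% = the genome contributes nothing, 100 \% = all
#' expression of the region comes from one sub-genome). Regions with zero
#' raw sum are flagged not-expressed and carry \code{NA} normalized values.
#'
#' @param raw_A,raw_B,raw_D non-negative raw expression levels (vectors).
#' @return \code{data.table} with \code{norm_A}, \code{norm_B},
#'   \code{norm_D}, \code{expressed}.
#' @examples
#' normalize_allelic_expression(2, 2, 2)    # 33.33 each
#' normalize_allelic_expression(1, 2, 7)    # 10 / 20 / 70
#' @export
normalize_allelic_expression <- function(raw_A, raw_B, raw_D) {
  if (any(c(raw_A, raw_B, raw_D) < 0, na.rm = TRUE))
    stop_input("raw expression levels must be non-negative")
  tot <- raw_A + raw_B + raw_D
  expressed <- !is.na(tot) & tot > 0
  f <- function(x) ifelse(expressed, 100 * x / tot, NA_real_)
  data.table(norm_A = f(raw_A), norm_B = f(raw_B), norm_D = f(raw_D),
             expressed = expressed)
}

#' Categorize co-expression of a homoeologous triad
#'
#' Classifies normalized expression of the three sub-genomes as
#' \code{conserved} (all within the window of each other),
#' \code{uni_dominant_X} (one genome at least a window above the other two,
#' which are within a window of each other), \code{bi_dominant_XY} (two
#' genomes each at least a window above the third and within a window of
#' each other) or \code{all_differ}.
#'
#' @param norm_A,norm_B,norm_D normalized percentages (vectors).
#' @param window dominance window in percentage points (default 5).
#' @return character vector of categories.
#' @examples
#' categorize_coexpression(34, 33, 33)  # conserved
#' categorize_coexpression(45, 30, 25)  # uni_dominant_A
#' categorize_coexpression(40, 40, 20)  # bi_dominant_AB
#' @export
categorize_coexpression <- function(norm_A, norm_B, norm_D, window = 5) {
  x <- cbind(A = norm_A, B = norm_B, D = norm_D)
  apply(x, 1L, function(v) {
    if (anyNA(v)) return(NA_character_)
    if (max(v) - min(v) <= window) return("conserved")
    ord <- order(v, decreasing = TRUE)
    g <- names(v)[ord]; v <- v[ord]
    if (v[1] >= v[2] + window && v[1] >= v[3] + window &&
        v[2] - v[3] <= window)
      return(paste0("uni_dominant_", g[1]))
    if (v[1] >= v[3] + window && v[2] >= v[3] + window &&
        v[1] - v[2] <= window)
      return(paste0("bi_dominant_", paste(sort(g[1:2]), collapse = "")))
    "all_differ"
  })
}

#' Histogram bin index over [0, 100] in 5 % intervals
#'
#' Twenty right-open bins \code{[0,5), [5,10), ...} with the final bin
#' \code{[95,100]} closed.
#' @param x values in \[0, 100\].
#' @return integer bin index in 1..20.
#' @export
expression_bin <- function(x) {
  if (any(x < 0 | x > 100, na.rm = TRUE))
    stop_input("expression percentages must lie in [0, 100]")
  pmin(as.integer(floor(x / 5)) + 1L, 20L)
}

#' Correlate methylation patterns with allelic expression
#'
#' For every methylated site, takes the normalized expression of each
#' sub-genome that the site's pattern marks as methylated (all three for
#' \code{tri}, the pair for \code{bi_XY}, the single genome for
#' \code{uni_X}) in the region the site falls in. Promoter and
#' non-transcribed regions are assigned the expression of their neighboring
#' gene: promoters via their linked gene id, non-transcribed regions via
#' the nearest gene on the same contig (ties resolved downstream). Each
#' (pattern class x annotation class) stratum is summarised by a 20-bin
#' histogram over \[0, 100\], the mean, the 75th percentile and the excess
#' kurtosis.
#'
#' @param patterns classified site patterns
#'   (\code{\link{classify_site_patterns}} output) or any table with
#'   \code{contig}, \code{pos}, \code{pattern}.
#' @param regions region annotation table (\code{region_id}, \code{contig},
#'   \code{start}, \code{end}, \code{class}, \code{gene_id}).
#' @param expression table with \code{gene_id}, \code{norm_A},
#'   \code{norm_B}, \code{norm_D} (e.g.
#'   \code{\link{simulate_allelic_expression}} output, or
#'   \code{\link{normalize_allelic_expression}} applied to measured
#'   levels).
#' @return list with \code{values} (one row per site x methylated genome:
#'   stratum columns and the expression value), \code{summary} (per
#'   stratum: n, mean, 75th percentile, excess kurtosis) and
#'   \code{histogram} (per stratum x bin counts and percentages).
#' @export
correlate_methylation_expression <- function(patterns, regions, expression) {
  patterns <- as.data.table(patterns)
  regions <- as.data.table(regions)
  expression <- as.data.table(expression)
  meth <- patterns[!is.na(pattern) & grepl("^(tri|uni_|bi_)", pattern)]
  if (nrow(meth) == 0L)
    stop_input("no methylated site patterns to correlate")

  regions <- link_regions_to_genes(regions)
  ## locate each site's region
  hits <- region_overlaps(meth, regions)
  meth <- meth[hits$site_idx]
  meth[, `:=`(region_class = regions$class[hits$region_idx],
              linked_gene = regions$linked_gene[hits$region_idx])]
  meth[, region_class := ifelse(region_class %in% c("exon", "intron"),
                                "transcribed", region_class)]
  ## methylated genomes per pattern
  glist <- lapply(meth$pattern, function(p) {
    if (p == "tri") GENOMES
    else if (startsWith(p, "uni_")) sub("uni_", "", p)
    else strsplit(sub("bi_", "", p), "")[[1]]
  })
  vals <- data.table(
    contig = rep(meth$contig, lengths(glist)),
    pos = rep(meth$pos, lengths(glist)),
    pattern_class = rep(sub("_.*", "", meth$pattern), lengths(glist)),
    region_class = rep(meth$region_class, lengths(glist)),
    gene_id = rep(meth$linked_gene, lengths(glist)),
    genome = unlist(glist))
  vals <- merge(vals, expression[, .(gene_id, norm_A, norm_B, norm_D)],
                by = "gene_id", sort = FALSE)
  vals[, value := fifelse(genome == "A", norm_A,
                          fifelse(genome == "B", norm_B, norm_D))]
  vals <- vals[!is.na(value)]
  vals[, c("norm_A", "norm_B", "norm_D") := NULL]
  vals[, bin := expression_bin(value)]

  summary <- vals[, .(
    n = .N, mean = mean(value),
    p75 = as.numeric(stats::quantile(value, 0.75)),
    kurtosis = if (.N >= 4) e1071::kurtosis(value, type = 2) else NA_real_
  ), by = .(pattern_class, region_class)]
  histogram <- vals[, .N, by = .(pattern_class, region_class, bin)]
  grid <- CJ(pattern_class = unique(vals$pattern_class),
             region_class = unique(vals$region_class), bin = 1:20)
  histogram <- histogram[grid, on = names(grid)]
  histogram[is.na(N), N := 0L]
  histogram[, pct := 100 * N / sum(N), by = .(pattern_class, region_class)]
  list(values = vals[], summary = summary[], histogram = histogram[])
}

## promoter -> linked gene id; non-transcribed -> nearest gene on the
## contig by midpoint distance, ties resolved towards the downstream gene;
## transcribed regions link to their own gene
link_regions_to_genes <- function(regions) {
  regions <- copy(as.data.table(regions))
  if (!"gene_id" %in% names(regions)) regions[, gene_id := NA_character_]
  regions[, linked_gene := gene_id]
  miss <- which(is.na(regions$linked_gene) | regions$linked_gene == ".")
  if (length(miss)) {
    genes <- regions[!is.na(gene_id) & gene_id != "." &
                       class %in% c("exon", "intron"),
                     .(gstart = min(start), gend = max(end)),
                     by = .(contig, gene_id)]
    genes[, gmid := (gstart + gend) / 2]
    for (i in miss) {
      cand <- genes[contig == regions$contig[i]]
      if (nrow(cand) == 0L) next
      mid <- (regions$start[i] + regions$end[i]) / 2
      d <- abs(cand$gmid - mid)
      best <- which(d == min(d))
      if (length(best) > 1L) best <- best[which.max(cand$gstart[best])]
      regions[i, linked_gene := cand$gene_id[best]]
    }
  }
  regions
}

## indices of (site, region) containment pairs
region_overlaps <- function(sites, regions) {
  ir_site <- IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  ir_reg <- IRanges::IRanges(start = regions$start + 1L,
                             end = pmax(regions$end, regions$start + 1L))
  hits <- IRanges::findOverlaps(ir_site, ir_reg)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same <- sites$contig[qh] == regions$contig[sh]
  list(site_idx = qh[same], region_idx = sh[same])
}

#' Compare mean expression between two site categories
#'
#' Pooled-variance two-sample t test (two-tailed), reported in the
#' conventional t / df / p form.
#'
#' @param values_1,values_2 numeric vectors (n >= 2 each).
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_1},
#'   \code{mean_2}.
#' @export
compare_category_means <- function(values_1, values_2) {
  if (length(values_1) < 2L || length(values_2) < 2L)
    stop_input("both groups need at least two values")
  if (sd(values_1) == 0 && sd(values_2) == 0) {
    ## zero-variance guard: identical groups give t = 0 / p = 1, fully
    ## separated constant groups give +/-Inf / p = 0
    same <- mean(values_1) == mean(values_2)
    return(list(t = if (same) 0 else sign(mean(values_1) - mean(values_2)) * Inf,
                df = length(values_1) + length(values_2) - 2L,
                p = if (same) 1 else 0,
                mean_1 = mean(values_1), mean_2 = mean(values_2)))
  }
  tt <- t.test(values_1, values_2, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_1 = mean(values_1), mean_2 = mean(values_2))
}

#' Kolmogorov-Smirnov check against a fitted normal
#'
#' Tests whether values are consistent with a normal distribution with the
#' sample mean and standard deviation.
#'
#' @param values numeric vector.
#' @return p-value.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop_input("need at least three values")
  suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values))$p.value)
}

#' Flag differential expression from PPLR values
#'
#' The probability of positive log ratio (PPLR) is 0.5 under no change.
#' Values at or below 0.4 / at or above 0.6 flag differential expression
#' (down/up); values below 0.10 / above 0.90 flag high-confidence
#' differential expression, subsuming the plain flags.
#'
#' @param pplr numeric vector in \[0, 1\] (NA allowed).
#' @param thresholds a \code{\link{meth_thresholds}}.
#' @return character vector over \code{c("not_DE","DE_down","DE_up",
#'   "highly_DE_down","highly_DE_up")}.
#' @examples
#' flag_differential_expression(c(0.5, 0.35, 0.95))
#' @export
flag_differential_expression <- function(pplr, thresholds = meth_thresholds()) {
  if (any(pplr < 0 | pplr > 1, na.rm = TRUE))
    stop_input("PPLR values must lie in [0, 1]")
  out <- rep(NA_character_, length(pplr))
  ok <- !is.na(pplr)
  out[ok] <- "not_DE"
  out[ok & pplr <= thresholds$pplr_de_low] <- "DE_down"
  out[ok & pplr >= thresholds$pplr_de_high] <- "DE_up"
  out[ok & pplr < thresholds$pplr_highde_low] <- "highly_DE_down"
  out[ok & pplr > thresholds$pplr_highde_high] <- "highly_DE_up"
  out
}
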