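#' Two-sided Fisher's exact test for 2x2 tables, vectorised
#'
#' Computes the two-sided Fisher exact p-value for tables
#' \code{[[m1, n1 - m1], [m2, n2 - m2]]}: the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table (the same definition as
#' \code{stats::fisher.test}). Implemented directly on the hypergeometric
#' mass function so that tens of thousands of per-site tests run in
#' vectorised batches.
#'
#' @param m1,n1 methylated and total read counts in group 1.
#' @param m2,n2 methylated and total read counts in group 2.
#' @return numeric vector of two-sided p-values; \code{NA} where a group has
#'   zero total.
#' @examples
#' fisher_exact_2x2(5, 10, 5, 10)   # identical proportions -> 1
#' fisher_exact_2x2(10, 10, 0, 10)  # fully separated margins
#' @export
fisher_exact_2x2 <- function(m1, n1, m2, n2) {
  n <- max(length(m1), length(n1), length(m2), length(n2))
  m1 <- rep_len(as.integer(m1), n); n1 <- rep_len(as.integer(n1), n)
  m2 <- rep_len(as.integer(m2), n); n2 <- rep_len(as.integer(n2), n)
  stopifnot(all(m1 <= n1, na.rm = TRUE), all(m2 <= n2, na.rm = TRUE))
  p <- rep(NA_real_, n)
  ok <- !is.na(m1) & !is.na(m2) & n1 > 0L & n2 > 0L
  if (!any(ok)) return(p)
  k <- m1 + m2                       # first-column margin
  lo <- pmax(0L, k - n2)
  hi <- pmin(k, n1)
  ## relative tolerance, as in stats::fisher.test
  eps <- 1 + 1e-7
  p[ok] <- vapply(which(ok), function(i) {
    supp <- lo[i]:hi[i]
    d <- dhyper(supp, n1[i], n2[i], k[i])
    sum(d[d <= d[supp == m1[i]] * eps])
  }, numeric(1))
  pmin(p, 1)
}

#' Differential methylation test between two count groups
#'
#' Two-sided Fisher's exact test on the 2x2 methylated/unmethylated table,
#' with the absolute difference in percentage methylation, and
#' Benjamini-Hochberg q-values computed over the whole vector (one call = one
#' comparison family). A comparison is significant when \code{q < q_cutoff}
#' and the difference is at least \code{min_diff} percentage points.
#'
#' @param m1,n1,m2,n2 methylated/total counts per group (vectorised).
#' @param min_diff minimum absolute methylation difference in percentage
#'   points (50 for within-sample sub-genome comparisons, 25 for
#'   between-sample and regional comparisons).
#' @param q_cutoff q-value cutoff (default 0.01).
#' @return \code{data.table} with columns \code{diff}, \code{p}, \code{q},
#'   \code{significant}.
#' @export
test_differential <- function(m1, n1, m2, n2, min_diff = 50, q_cutoff = 0.01) {
  p <- fisher_exact_2x2(m1, n1, m2, n2)
  diff <- abs(100 * m1 / n1 - 100 * m2 / n2)
  q <- p.adjust(p, method = "BH")
  data.table(diff = diff, p = p, q = q,
             significant = !is.na(q) & q < q_cutoff & diff >= min_diff)
}
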