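## Shared fixtures and independent oracles for the test suite.

library(data.table)

## small, fast generator configuration
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_contigs = 2L, contig_length = 1200L, depth = 40,
                   error_rate = 0, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

## independent Fisher oracle: explicit enumeration of all 2x2 tables with
## the observed margins, hypergeometric masses from choose() directly
fisher_enum_oracle <- function(m1, n1, m2, n2) {
  k <- m1 + m2
  supp <- max(0, k - n2):min(k, n1)
  mass <- choose(n1, supp) * choose(n2, k - supp) / choose(n1 + n2, k)
  obs <- mass[supp == m1]
  sum(mass[mass <= obs * (1 + 1e-7)])
}

## independent Benjamini-Hochberg step-up implementation
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

## one-row read table for hand-built alignment scenarios
make_read <- function(contig, pos, seq, xm, xg = "CT", qname = "r1",
                      mapq = 40L, strand_origin = NULL, genome = NULL) {
  dt <- data.table(qname = qname, contig = contig, pos = as.integer(pos),
                   mapq = as.integer(mapq),
                   strand_origin = strand_origin %||%
                     (if (xg == "CT") "OT" else "OB"),
                   xg = xg, seq = seq, xm = xm)
  if (!is.null(genome)) dt[, genome := genome]
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## single-SNP catalogue row
make_snp <- function(contig, pos, a, b, d, source = "test") {
  data.table(contig = contig, pos = as.integer(pos), allele_A = a,
             allele_B = b, allele_D = d, source = source,
             bisulfite_safe = polymethyl::is_bisulfite_safe(a, b, d))
}

## synthetic tally row with explicit per-label counts (defaults zero)
make_tally <- function(contig = "c1", pos = 10L, strand = "+",
                       context = "CpG", ..., thresholds = meth_thresholds()) {
  counts <- list(...)
  row <- data.table(contig = contig, pos = as.integer(pos), strand = strand,
                    context = context)
  for (lab in c("A", "B", "D", "AB", "AD", "BD"))
    for (pre in c("m_", "t_")) {
      col <- paste0(pre, lab)
      set(row, j = col, value = as.integer(counts[[col]] %||% 0L))
    }
  polymethyl:::finalize_tally(row, thresholds)
  row
}

## shared full-pipeline run used by several acceptance checks; cached so
## the simulation only runs once per test session
acceptance_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_contigs = 5L, contig_length = 6000L, depth = 100,
                      conversion_rate = 0.99, error_rate = 0, seed = 20260901L)
    sim <- simulate_methylome(cfg)
    catalog <- filter_bisulfite_ambiguous(
      cbind(sim$ref$snps, source = "truth"))
    assignments <- assign_reads(sim$reads, catalog)
    calls <- extract_site_calls(sim$reads, sim$ref$reference)
    conv <- estimate_conversion_rate(sim$reads, sim$ref$reference)
    tally <- tally_site_counts(calls, assignments)
    th <- meth_thresholds(
      conversion_background = max(0, 1 - as.numeric(conv) / 100))
    patterns <- classify_site_patterns(tally, th)
    cache <<- list(sim = sim, tally = tally, patterns = patterns,
                   conversion = conv, thresholds = th)
    cache
  }
})
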