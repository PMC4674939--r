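test_that("normalization rescales triads to a 100 % sum", {
  expect_equal(unlist(normalize_allelic_expression(2, 2, 2)[, 1:3]),
               c(norm_A = 100 / 3, norm_B = 100 / 3, norm_D = 100 / 3),
               tolerance = 1e-9)
  expect_equal(unlist(normalize_allelic_expression(10, 0, 0)[, 1:3]),
               c(norm_A = 100, norm_B = 0, norm_D = 0))
  expect_equal(unlist(normalize_allelic_expression(1, 2, 7)[, 1:3]),
               c(norm_A = 10, norm_B = 20, norm_D = 70))
  z <- normalize_allelic_expression(0, 0, 0)
  expect_false(z$expressed)
  expect_true(is.na(z$norm_A))
  expect_error(normalize_allelic_expression(-1, 2, 2), "non-negative")
  ## sums are exactly 100 for every expressed region
  set.seed(2)
  r <- normalize_allelic_expression(runif(500), runif(500), runif(500))
  expect_equal(r$norm_A + r$norm_B + r$norm_D, rep(100, 500),
               tolerance = 1e-9)
})

test_that("grand mean of normalized expression is 33.33 % by construction", {
  set.seed(4)
  r <- normalize_allelic_expression(rgamma(2000, 4), rgamma(2000, 4),
                                    rgamma(2000, 4))
  expect_equal(mean(unlist(r[, 1:3])), 100 / 3, tolerance = 1e-9)
})

test_that("co-expression categories follow the 5 % window rules", {
  expect_equal(categorize_coexpression(34, 33, 33), "conserved")
  expect_equal(categorize_coexpression(45, 30, 25), "uni_dominant_A")
  expect_equal(categorize_coexpression(40, 40, 20), "bi_dominant_AB")
  expect_equal(categorize_coexpression(25, 30, 45), "uni_dominant_D")
  expect_equal(categorize_coexpression(20, 40, 40), "bi_dominant_BD")
  expect_equal(categorize_coexpression(50, 38, 12), "all_differ")
  ## exactly at the window edge: conserved wins (<= window)
  expect_equal(categorize_coexpression(38, 33, 33), "conserved")
  expect_true(is.na(categorize_coexpression(NA, 50, 50)))
})

test_that("co-expression categories are mutually exclusive and exhaustive", {
  set.seed(19)
  raw <- matrix(rgamma(3 * 500, 2), ncol = 3)
  norm <- 100 * raw / rowSums(raw)
  cats <- categorize_coexpression(norm[, 1], norm[, 2], norm[, 3])
  expect_false(anyNA(cats))
  expect_true(all(cats %in% c("conserved", "all_differ",
                              paste0("uni_dominant_", c("A", "B", "D")),
                              paste0("bi_dominant_", c("AB", "AD", "BD")))))
})

test_that("histogram bins are right-open with a closed final bin", {
  expect_equal(expression_bin(c(0, 4.999, 5, 33.33, 95, 100)),
               c(1L, 1L, 2L, 7L, 20L, 20L))
  expect_error(expression_bin(101), "\\[0, 100\\]")
})

test_that("methylation-expression correlation stratifies and summarizes", {
  patterns <- data.table(
    contig = "c1", pos = c(10L, 50L, 150L, 250L), strand = "+",
    context = "CpG",
    pattern = c("tri", "uni_A", "bi_BD", "tri"))
  regions <- data.table(
    region_id = c("exon1", "prom1", "nt1"),
    contig = "c1", start = c(0L, 100L, 200L), end = c(100L, 200L, 300L),
    class = c("exon", "promoter", "non_transcribed"),
    gene_id = c("g1", "g1", NA))
  expression <- data.table(gene_id = "g1", norm_A = 50, norm_B = 30,
                           norm_D = 20)
  out <- correlate_methylation_expression(patterns, regions, expression)
  ## tri site in the exon contributes all three genomes
  tr <- out$values[pattern_class == "tri" & region_class == "transcribed"]
  expect_equal(sort(tr$value), c(20, 30, 50))
  ## uni_A contributes only genome A
  expect_equal(out$values[pattern_class == "uni", value], 50)
  ## bi_BD in the promoter contributes B and D via the linked gene
  bi <- out$values[pattern_class == "bi"]
  expect_equal(bi$region_class, c("promoter", "promoter"))
  expect_equal(sort(bi$value), c(20, 30))
  ## the non-transcribed tri site inherits g1, the only gene on the contig
  nt <- out$values[region_class == "non_transcribed"]
  expect_equal(nrow(nt), 3L)
  ## summaries carry mean / 75th percentile per stratum
  s <- out$summary[pattern_class == "tri" & region_class == "transcribed"]
  expect_equal(s$mean, mean(c(20, 30, 50)))
  expect_equal(s$p75, as.numeric(quantile(c(20, 30, 50), 0.75)))
  ## histogram percentages sum to 100 within a stratum
  h <- out$histogram[pattern_class == "tri" & region_class == "transcribed"]
  expect_equal(sum(h$pct), 100)
  expect_equal(sum(h$N), 3L)
})

test_that("a degenerate distribution lands in a single bin", {
  patterns <- data.table(contig = "c1", pos = 1:50, strand = "+",
                         context = "CpG", pattern = "tri")
  regions <- data.table(region_id = "exon1", contig = "c1", start = 0L,
                        end = 100L, class = "exon", gene_id = "g1")
  expression <- data.table(gene_id = "g1", norm_A = 100 / 3,
                           norm_B = 100 / 3, norm_D = 100 / 3)
  out <- correlate_methylation_expression(patterns, regions, expression)
  expect_equal(out$summary$mean, 100 / 3, tolerance = 1e-9)
  expect_equal(out$summary$p75, 100 / 3, tolerance = 1e-9)
  h <- out$histogram[N > 0]
  expect_equal(h$bin, 7L)               # [30, 35)
  expect_equal(h$pct, 100)
})

test_that("category mean comparison reports pooled-variance t statistics", {
  x <- c(30, 32, 28, 35, 31)
  y <- c(40, 38, 44, 41, 39, 42)
  got <- compare_category_means(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, length(x) + length(y) - 2)
  expect_equal(got$p, ref$p.value)
  ## identical groups
  same <- compare_category_means(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ## zero-variance separated groups: sign follows argument order
  sep <- compare_category_means(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_lt(sep$p, 0.001)
  expect_lt(sep$t, 0)
})

test_that("KS normality is calibrated on normal draws", {
  set.seed(123)
  hits <- vapply(1:100, function(i) ks_normality(rnorm(1000)) > 0.01,
                 logical(1))
  expect_gte(mean(hits), 0.95)
  ## clearly non-normal data is rejected
  set.seed(5)
  expect_lt(ks_normality(rexp(2000)), 0.01)
})

test_that("PPLR flags honour both the 0.4/0.6 and 0.10/0.90 cutoffs", {
  th <- meth_thresholds()
  expect_equal(flag_differential_expression(0.5, th), "not_DE")
  expect_equal(flag_differential_expression(0.35, th), "DE_down")
  expect_equal(flag_differential_expression(0.95, th), "highly_DE_up")
  ## boundaries: 0.4/0.6 inclusive, 0.10/0.90 strict
  expect_equal(flag_differential_expression(c(0.4, 0.6, 0.10, 0.90), th),
               c("DE_down", "DE_up", "DE_down", "DE_up"))
  expect_equal(flag_differential_expression(c(0.0999, 0.9001), th),
               c("highly_DE_down", "highly_DE_up"))
  expect_true(is.na(flag_differential_expression(NA, th)))
  expect_error(flag_differential_expression(1.2, th), "PPLR")
})

test_that("uni-dominated promoter truth reduces that genome's expression", {
  ## build truth where half the genes carry a genome-B-dominated promoter
  n <- 400L
  regions <- rbindlist(lapply(1:n, function(i) data.table(
    region_id = c(sprintf("p%03d", i), sprintf("e%03d", i)),
    contig = sprintf("c%03d", i), start = c(0L, 100L), end = c(100L, 300L),
    class = c("promoter", "exon"), gene_id = sprintf("g%03d", i))))
  hit <- seq_len(n) <= n / 2
  truth <- data.table(contig = sprintf("c%03d", 1:n), pos = 50L,
                      strand = "+", context = "CpG",
                      pattern = ifelse(hit, "uni_B", "tri"),
                      p_A = 0.9, p_B = 0.9, p_D = 0.9)
  cfg <- tiny_config(promoter_suppression = 0.5)
  expr <- simulate_allelic_expression(regions, truth, cfg)
  expect_identical(unname(expr$suppressed_B),
                   hit[match(expr$gene_id, sprintf("g%03d", 1:n))])
  expect_lt(mean(expr[suppressed_B == TRUE, norm_B]),
            mean(expr[suppressed_B == FALSE, norm_B]))
})
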