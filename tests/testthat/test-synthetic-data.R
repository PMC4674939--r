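test_that("configuration invariants are enforced", {
  expect_error(sim_config(pattern_mix = c(tri = 0.5)), "pattern_mix")
  expect_error(sim_config(snp_rate = 0.5), "snp_rate")
  expect_error(sim_config(contig_length = 20, snp_rate = 0.01),
               "too short")
  expect_error(sim_config(conversion_rate = 1.2), "conversion_rate")
  expect_error(sim_config(depth = -1), "depth")
  mix <- c(tri = 0.5, uni_A = 0.5, uni_B = 0, uni_D = 0, bi_AB = 0,
           bi_AD = 0, bi_BD = 0, intermediate = 0, unmethylated = 0)
  expect_s3_class(sim_config(pattern_mix = mix), "sim_config")
})

test_that("zero SNP rate yields identical sub-genomes and empty SNP truth", {
  ref <- simulate_references(tiny_config(snp_rate = 0))
  expect_equal(nrow(ref$snps), 0L)
  for (g in c("A", "B", "D")) {
    shared <- setdiff(names(ref$reference), "control")
    expect_identical(as.character(ref$genomes[[g]]),
                     as.character(ref$reference[shared]))
  }
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- tiny_config()
  a <- simulate_methylome(cfg)
  b <- simulate_methylome(cfg)
  expect_identical(as.character(a$ref$reference),
                   as.character(b$ref$reference))
  expect_identical(a$ref$snps, b$ref$snps)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
  expect_identical(a$expression, b$expression)
  c <- simulate_references(tiny_config(seed = 43L))
  expect_false(identical(as.character(c$reference),
                         as.character(a$ref$reference)))
})

test_that("divergent position count matches the binomial expectation", {
  cfg <- sim_config(n_contigs = 10L, contig_length = 2000L, snp_rate = 0.01,
                    seed = 7L)
  ref <- simulate_references(cfg)
  n <- 10 * 2000
  expectation <- n * 0.01
  tol <- 3 * sqrt(n * 0.01 * 0.99)
  expect_lt(abs(nrow(ref$snps) - expectation), tol)
  ## every listed position genuinely diverges and alleles are bases
  with(ref$snps, {
    expect_true(all(allele_A != ref | allele_B != ref | allele_D != ref))
    expect_true(all(c(allele_A, allele_B, allele_D) %in%
                      c("A", "C", "G", "T")))
  })
})

test_that("control contig is SNP-free and cytosine-rich", {
  ref <- simulate_references(tiny_config())
  expect_false("control" %in% ref$snps$contig)
  ctl <- strsplit(as.character(ref$reference[["control"]]), "")[[1]]
  expect_gte(sum(ctl == "C"), 1000L)
})

test_that("methylation truth respects the pattern definitions", {
  cfg <- tiny_config(n_contigs = 4L, contig_length = 2500L)
  ref <- simulate_references(cfg)
  truth <- simulate_methylation_truth(ref, cfg)
  uniA <- truth[pattern == "uni_A"]
  expect_true(all(uniA$p_A > 0 & uniA$p_B == 0 & uniA$p_D == 0))
  biBD <- truth[pattern == "bi_BD"]
  expect_true(all(biBD$p_A == 0 & biBD$p_B > 0 & biBD$p_D > 0))
  expect_true(all(truth[, c(p_A, p_B, p_D)] >= 0))
  expect_true(all(truth[, c(p_A, p_B, p_D)] <= 1))
  ## 100 % tri mix degenerate case
  mix <- c(tri = 1, uni_A = 0, uni_B = 0, uni_D = 0, bi_AB = 0, bi_AD = 0,
           bi_BD = 0, intermediate = 0, unmethylated = 0)
  t2 <- simulate_methylation_truth(ref, tiny_config(pattern_mix = mix))
  expect_true(all(t2$p_A > 0 & t2$p_B > 0 & t2$p_D > 0))
})

test_that("empirical tri fraction converges to the configured 45 %", {
  cfg <- sim_config(n_contigs = 6L, contig_length = 3000L, seed = 5L)
  ref <- simulate_references(cfg)
  truth <- simulate_methylation_truth(ref, cfg)
  n <- nrow(truth)
  expect_gt(n, 5000)
  se <- sqrt(0.45 * 0.55 / n)
  expect_lt(abs(mean(truth$pattern == "tri") - 0.45), 3 * se)
})

test_that("truth context agrees with the reference sequence", {
  cfg <- tiny_config()
  ref <- simulate_references(cfg)
  truth <- simulate_methylation_truth(ref, cfg)
  idx <- sample(nrow(truth), 200)
  for (i in idx) {
    ct <- truth$contig[i]
    expect_identical(
      classify_context(as.character(ref$reference[[ct]]), truth$pos[i],
                       truth$strand[i]),
      truth$context[i])
  }
})

test_that("complete and absent conversion produce all-T / all-C readouts", {
  mix <- c(tri = 0, uni_A = 0, uni_B = 0, uni_D = 0, bi_AB = 0, bi_AD = 0,
           bi_BD = 0, intermediate = 0, unmethylated = 1)
  cfg <- tiny_config(pattern_mix = mix, conversion_rate = 1)
  sim <- simulate_methylome(cfg)
  ## no methylated (uppercase) symbols anywhere
  expect_false(any(grepl("[ZXHU]", sim$reads$xm)))
  expect_equal(as.numeric(
    estimate_conversion_rate(sim$reads, sim$ref$reference)), 100)

  cfg0 <- tiny_config(pattern_mix = mix, conversion_rate = 0)
  sim0 <- simulate_methylome(cfg0)
  expect_false(any(grepl("[zxhu]", sim0$reads$xm)))
  expect_equal(as.numeric(
    estimate_conversion_rate(sim0$reads, sim0$ref$reference)), 0)
})

test_that("read conservation: every position is a call or a dot", {
  sim <- simulate_methylome(tiny_config())
  expect_true(all(nchar(sim$reads$xm) == nchar(sim$reads$seq)))
  sym <- strsplit(paste(sim$reads$xm, collapse = ""), "")[[1]]
  expect_true(all(sym %in% c("Z", "z", "X", "x", "H", "h", "U", "u", ".")))
})

test_that("mean interior coverage approximates the configured depth", {
  cfg <- sim_config(n_contigs = 1L, contig_length = 3000L, depth = 100,
                    seed = 9L)
  sim <- simulate_methylome(cfg)
  rd <- sim$reads[contig == "contig_01" & genome == "A"]
  cov <- integer(3000)
  for (i in seq_len(nrow(rd))) {
    sp <- rd$pos[i] + 1L
    cov[sp:(sp + nchar(rd$seq[i]) - 1L)] <- cov[sp:(sp + 99L)] + 1L
  }
  interior <- cov[400:2600]
  expect_lt(abs(mean(interior) - 100) / 100, 0.1)
})

test_that("depth zero warns and returns no reads", {
  cfg <- tiny_config(depth = 0)
  ref <- simulate_references(cfg)
  truth <- simulate_methylation_truth(ref, cfg)
  expect_warning(rd <- simulate_reads(ref, truth, cfg), "depth")
  expect_equal(nrow(rd), 0L)
})

test_that("directional libraries use only original strand products", {
  sim <- simulate_methylome(tiny_config(directional = TRUE))
  expect_true(all(sim$reads$strand_origin %in% c("OT", "OB")))
  sim2 <- simulate_methylome(tiny_config(directional = FALSE))
  expect_setequal(unique(sim2$reads$strand_origin),
                  c("OT", "OB", "CTOT", "CTOB"))
})

test_that("promoter suppression scales normalized expression as expected", {
  ## explicit one-suppressed-genome-per-region truth; closed form for the
  ## suppressed genome's mean share is 100*s/(s+2) under equal baseline
  ## means, approached closely by the gamma baseline model
  n <- 5000L
  regions <- data.table(region_id = sprintf("r%04d", 1:n),
                        contig = sprintf("c%04d", 1:n),
                        start = 0L, end = 100L, class = "promoter",
                        gene_id = sprintf("g%04d", 1:n))
  sup <- matrix(FALSE, n, 3, dimnames = list(regions$gene_id,
                                             c("A", "B", "D")))
  sup[, "B"] <- TRUE
  cfg <- tiny_config(promoter_suppression = 0.8)
  expr <- simulate_allelic_expression(regions, NULL, cfg, suppressed = sup)
  expect_true(all(expr$suppressed_B))
  closed_form <- 100 * 0.8 / (0.8 + 2)
  expect_lt(abs(mean(expr$norm_B) - closed_form), 1)
  expect_lt(mean(expr$norm_B), 100 / 3)

  expr0 <- simulate_allelic_expression(
    regions, NULL, tiny_config(promoter_suppression = 0), suppressed = sup)
  expect_true(all(expr0$norm_B == 0))

  expr1 <- simulate_allelic_expression(
    regions, NULL, tiny_config(promoter_suppression = 1), suppressed = sup)
  expect_lt(abs(mean(expr1$norm_B) - 100 / 3), 0.75)
})

test_that("suppression labels require uni-dominated promoter truth", {
  ## a mix dominated by genome-A-specific methylation marks every promoter
  mixA <- c(tri = 0.2, uni_A = 0.6, uni_B = 0.05, uni_D = 0.05, bi_AB = 0,
            bi_AD = 0, bi_BD = 0, intermediate = 0.1, unmethylated = 0)
  cfg <- tiny_config(pattern_mix = mixA, depth = 0)
  ref <- simulate_references(cfg)
  truth <- simulate_methylation_truth(ref, cfg)
  regions <- simulate_regions(ref, cfg)
  expr <- simulate_allelic_expression(regions, truth, cfg)
  expect_true(all(expr$suppressed_A))
  expect_false(any(expr$suppressed_B | expr$suppressed_D))

  ## with the default site-wise mix no genome dominates any promoter
  cfg2 <- tiny_config(depth = 0)
  truth2 <- simulate_methylation_truth(ref, cfg2)
  expr2 <- simulate_allelic_expression(regions, truth2, cfg2)
  expect_false(any(expr2$suppressed_A | expr2$suppressed_B |
                     expr2$suppressed_D))
})
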