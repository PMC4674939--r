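test_that("state calls follow the CpG 75/25 and non-CpG 10/0 thresholds", {
  expect_equal(call_methylation_state(8, 10, "CpG")$state, "Methylated")
  expect_equal(call_methylation_state(5, 10, "CpG")$state, "Intermediate")
  expect_equal(call_methylation_state(2, 10, "CpG")$state, "Unmethylated")
  ## boundary inclusiveness exactly as printed
  expect_equal(call_methylation_state(75, 100, "CpG")$state, "Methylated")
  expect_equal(call_methylation_state(25, 100, "CpG")$state, "Unmethylated")
  expect_equal(call_methylation_state(2, 16, "CHH")$state, "Methylated")
  expect_equal(call_methylation_state(10, 100, "CHG")$state, "Intermediate")
  expect_equal(call_methylation_state(11, 100, "CHG")$state, "Methylated")
  expect_equal(call_methylation_state(0, 20, "CHH")$state, "Unmethylated")
  expect_equal(call_methylation_state(1, 20, "CHH")$state, "Intermediate")
  expect_equal(call_methylation_state(0, 0, "CpG")$state, "NoCall")
})

test_that("conversion background correction zeroes counts consistent with it", {
  th <- meth_thresholds(conversion_background = 0.011)
  ## 1 methylated of 60 is what incomplete conversion alone produces
  r1 <- call_methylation_state(1, 60, "CHH", th)
  expect_equal(r1$state, "Unmethylated")
  expect_equal(r1$level, 0)
  ## far above background: corrected level, not raw
  r2 <- call_methylation_state(30, 60, "CHH", th)
  expect_equal(r2$state, "Methylated")
  expect_lt(r2$level, 50)
  expect_equal(r2$level, 100 * (0.5 - 0.011) / (1 - 0.011), tolerance = 1e-9)
  ## CpG calls are effectively unchanged by a ~1 % background
  expect_equal(call_methylation_state(48, 60, "CpG", th)$state, "Methylated")
})

test_that("pattern classification handles the canonical biallelic cases", {
  th <- meth_thresholds()
  ## A 80 % CpG vs BD pair 0 %, well-powered -> uni_A
  t1 <- make_tally(m_A = 16, t_A = 20, m_BD = 0, t_BD = 40)
  p1 <- classify_site_patterns(t1, th)
  expect_equal(p1$pattern, "uni_A")
  expect_lt(p1$q, 0.01)
  ## A and BD both methylated -> tri
  t2 <- make_tally(m_A = 16, t_A = 20, m_BD = 35, t_BD = 40)
  expect_equal(classify_site_patterns(t2, th)$pattern, "tri")
  ## pair at 50 % is an intermediate call -> site intermediate
  t3 <- make_tally(m_A = 16, t_A = 20, m_BD = 20, t_BD = 40)
  expect_equal(classify_site_patterns(t3, th)$pattern, "intermediate")
  ## pair methylated, single unmethylated -> bi of the pair
  t4 <- make_tally(m_A = 0, t_A = 20, m_BD = 36, t_BD = 40)
  expect_equal(classify_site_patterns(t4, th)$pattern, "bi_BD")
  ## both unmethylated -> none
  t5 <- make_tally(m_A = 0, t_A = 20, m_BD = 0, t_BD = 40)
  expect_equal(classify_site_patterns(t5, th)$pattern, "none")
  ## a real 60 % difference that cannot reach significance at 5/10 reads
  t6 <- make_tally(m_A = 3, t_A = 5, m_BD = 0, t_BD = 10, context = "CHH")
  p6 <- classify_site_patterns(t6, th)
  expect_equal(p6$pattern, "intermediate")
})

test_that("tri-resolved sites classify from three single-genome calls", {
  th <- meth_thresholds()
  tri <- make_tally(m_A = 18, t_A = 20, m_B = 17, t_B = 20, m_D = 19,
                    t_D = 20)
  expect_equal(classify_site_patterns(tri, th)$pattern, "tri")
  uniB <- make_tally(m_A = 0, t_A = 20, m_B = 17, t_B = 20, m_D = 0,
                     t_D = 20)
  expect_equal(classify_site_patterns(uniB, th)$pattern, "uni_B")
  biAD <- make_tally(m_A = 17, t_A = 20, m_B = 1, t_B = 20, m_D = 18,
                     t_D = 20)
  expect_equal(classify_site_patterns(biAD, th)$pattern, "bi_AD")
  inter <- make_tally(m_A = 10, t_A = 20, m_B = 17, t_B = 20, m_D = 18,
                      t_D = 20)
  expect_equal(classify_site_patterns(inter, th)$pattern, "intermediate")
  ## failed coverage gate -> no pattern
  nocall <- make_tally(t_A = 4, t_BD = 5)
  expect_true(is.na(classify_site_patterns(nocall, th)$pattern))
})

test_that("classification is symmetric under genome relabelling", {
  th <- meth_thresholds()
  set.seed(8)
  perms <- list(c("A", "B", "D"), c("B", "A", "D"), c("D", "B", "A"),
                c("B", "D", "A"))
  for (rep in 1:20) {
    m <- sample(0:20, 3, replace = TRUE)
    base_args <- list(m_A = m[1], t_A = 20, m_B = m[2], t_B = 20,
                      m_D = m[3], t_D = 20,
                      context = sample(c("CpG", "CHH"), 1))
    base_pat <- classify_site_patterns(do.call(make_tally, base_args),
                                       th)$pattern
    for (pm in perms) {
      args <- base_args
      names(args)[1:6] <- c(paste0(c("m_", "t_"), rep(pm, each = 2)))
      pat <- classify_site_patterns(do.call(make_tally, args), th)$pattern
      ## map the base pattern through the permutation
      relab <- setNames(pm, c("A", "B", "D"))
      expected <- base_pat
      if (grepl("^uni_", base_pat))
        expected <- paste0("uni_", relab[sub("uni_", "", base_pat)])
      if (grepl("^bi_", base_pat)) {
        gs <- strsplit(sub("bi_", "", base_pat), "")[[1]]
        expected <- paste0("bi_", paste(sort(relab[gs]), collapse = ""))
      }
      expect_identical(pat, expected)
    }
  }
})

test_that("replicate noise filtering excludes discordant sites", {
  th <- meth_thresholds()
  ## concordant replicates: 9/10 vs 9/10
  r1 <- make_tally(m_A = 9, t_A = 10, m_BD = 0, t_BD = 12)
  r2 <- make_tally(m_A = 9, t_A = 10, m_BD = 0, t_BD = 12)
  expect_equal(nrow(filter_replicate_noise(list(r1, r2), th)), 0L)
  ## discordant: 10/10 vs 0/10 (difference 100, Fisher p ~ 1e-5)
  d1 <- make_tally(m_A = 10, t_A = 10, m_BD = 0, t_BD = 12)
  d2 <- make_tally(m_A = 0, t_A = 10, m_BD = 0, t_BD = 12)
  excl <- filter_replicate_noise(list(d1, d2), th)
  expect_equal(nrow(excl), 1L)
  expect_equal(excl$pos, 10L)
  ## single replicate: nothing to compare
  expect_equal(nrow(filter_replicate_noise(list(d1), th)), 0L)
  ## excluded sites drop out of classification
  pat <- classify_site_patterns(d1, th, exclude = excl)
  expect_equal(nrow(pat), 0L)
})

test_that("between-sample comparisons test within each genome", {
  th <- meth_thresholds()
  s1 <- make_tally(m_A = 0, t_A = 10, m_B = 0, t_B = 10, m_D = 0, t_D = 10)
  s2 <- make_tally(m_A = 0, t_A = 10, m_B = 8, t_B = 10, m_D = 0, t_D = 10)
  res <- compare_between_samples(s1, s2, th)
  expect_equal(nrow(res), 1L)
  expect_true(res$sig_B)
  expect_false(res$sig_A || res$sig_D)
  expect_equal(res$change_class, "uni")
  ## identical samples -> nothing reported
  res0 <- compare_between_samples(s1, s1, th)
  expect_equal(nrow(res0), 0L)
  expect_equal(attr(res0, "n_tested"), 1L)
})

test_that("injected between-sample changes are recovered at depth 100", {
  th <- meth_thresholds()
  set.seed(91)
  n <- 4000L
  base <- data.table(contig = "c1", pos = seq_len(n), strand = "+",
                     context = "CpG")
  mk <- function(p) {
    dt <- copy(base)
    dt[, `:=`(m_A = rbinom(n, 100, p), t_A = 100L,
              m_B = rbinom(n, 100, p), t_B = 100L,
              m_D = rbinom(n, 100, p), t_D = 100L,
              m_AB = 0L, t_AB = 0L, m_AD = 0L, t_AD = 0L,
              m_BD = 0L, t_BD = 0L)]
    polymethyl:::finalize_tally(dt, th)
    dt
  }
  s1 <- mk(0.05)
  s2 <- mk(0.05)
  changed <- sample(n, 40)
  s2[changed, `:=`(m_B = rbinom(40, 100, 0.85))]
  res <- compare_between_samples(s1, s2, th)
  hits <- res[sig_B == TRUE, pos]
  expect_gte(length(intersect(hits, changed)), 36)   # >= 90 % recovered
  expect_equal(length(setdiff(hits, changed)), 0L)   # no false genomes
})

test_that("diploid-versus-sub-genome comparison labels gains and losses", {
  th <- meth_thresholds()
  tal <- rbind(make_tally(pos = 1, m_D = 16, t_D = 20, m_A = 0, t_A = 20,
                          m_B = 0, t_B = 20),
               make_tally(pos = 2, m_D = 0, t_D = 20, m_A = 0, t_A = 20,
                          m_B = 0, t_B = 20))
  dip <- data.table(contig = "c1", pos = c(1L, 2L), strand = "+",
                    context = "CpG", m = c(0L, 16L), t = c(20L, 20L))
  res <- compare_diploid_to_subgenome(dip, tal, "D", th)
  expect_equal(nrow(res), 2L)
  expect_equal(res[pos == 1, direction], "gain")
  expect_equal(res[pos == 2, direction], "loss")
  expect_equal(attr(res, "n_tested"), 2L)
  ## gains + losses partition the significant set
  expect_equal(sum(res$direction %in% c("gain", "loss")), nrow(res))
})
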