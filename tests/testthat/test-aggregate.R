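test_that("Fisher combination: identities and oracle agreement", {
  expect_equal(fisher_combine(c(1, 1, 1, 1)), 1)
  # k = 1: Fisher with df 2 returns the input p-value
  expect_equal(fisher_combine(0.037), 0.037, tolerance = 1e-12)
  expect_true(is.na(fisher_combine(numeric(0))))
  expect_true(is.na(fisher_combine(c(NA_real_, NA_real_))))
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
  # worked example against the closed-form chi-square series oracle
  p <- c(0.01, 0.02, 0.5, 0.9)
  x2 <- -2 * sum(log(p))
  expect_equal(fisher_combine(p), oracle_chisq_sf_even(x2, 8),
               tolerance = 1e-10)
  # NA entries are dropped with reduced df
  expect_equal(fisher_combine(c(0.01, NA, 0.02)),
               oracle_chisq_sf_even(-2 * (log(0.01) + log(0.02)), 4),
               tolerance = 1e-10)
})

test_that("Fisher combination is exchangeable and monotone", {
  set.seed(33)
  for (i in 1:25) {
    p <- stats::runif(4)
    expect_equal(fisher_combine(p), fisher_combine(sample(p)))
    p2 <- p
    p2[1] <- p2[1] / 2
    expect_lte(fisher_combine(p2), fisher_combine(p))
  }
})

test_that("combined p-values match the series oracle on random inputs", {
  set.seed(44)
  for (i in 1:100) {
    k <- sample(1:4, 1)
    p <- stats::runif(k, 1e-8, 1)
    x2 <- -2 * sum(log(p))
    want <- oracle_chisq_sf_even(x2, 2 * k)
    expect_lt(abs(fisher_combine(p) - want) / max(want, 1e-300), 1e-10)
  }
})

test_that("BH adjustment equals step-up enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(55)
  for (i in 1:200) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # monotone in raw values; permutation-consistent
  p <- stats::runif(30)
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-15))
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
})

test_that("confidence tiers follow the support rules", {
  # FDR significant, 2 concordant negative guides -> medium
  t1 <- classify_tier(c(0.01, 0.03, 0.2, 0.6), c(-1, -0.5, 0.1, -0.2),
                      fdr_value = 0.001)
  expect_equal(t1$tier, "medium")
  expect_equal(t1$support, 2L)
  # 4 significant concordant -> high
  t2 <- classify_tier(rep(0.01, 4), rep(-0.4, 4), fdr_value = 0.001)
  expect_equal(t2$tier, "high")
  expect_equal(t2$support, 4L)
  # 3 of 4 -> high; 1 -> low
  expect_equal(classify_tier(c(0.01, 0.01, 0.01, 0.5),
                             c(-1, -1, -1, 1), 0.001)$tier, "high")
  expect_equal(classify_tier(c(0.01, 0.5, 0.5, 0.5),
                             c(-1, 1, 1, 1), 0.001)$tier, "low")
  # discordant majority: the minority-sign guide does not count
  t3 <- classify_tier(c(0.01, 0.02, 0.03, 0.9), c(-1, -1, 1, 1), 0.001)
  expect_equal(t3$support, 2L)
  # FDR gate: any support is ns at FDR >= 0.05
  expect_equal(classify_tier(rep(0.001, 4), rep(-1, 4), 0.2)$tier, "ns")
  # sign tie among significant guides: cell-weighted mean decides
  t4 <- classify_tier(c(0.01, 0.01), c(-2, 0.5), 0.001,
                      n_cells = c(10, 500))
  expect_equal(t4$support, 1L)
  expect_equal(t4$tier, "low")
})

test_that("aggregation combines guides and partitions tiers exactly", {
  an <- tiny_analysis()
  tab <- an$e2g$table
  # every row's combined p equals Fisher of its guide p-values
  for (i in sample(nrow(tab), 20)) {
    expect_equal(tab$p_combined[i],
                 fisher_combine(tab$guide_p[[i]]), tolerance = 1e-12)
  }
  expect_equal(tab$fdr, bh_adjust(tab$p_combined))
  # tier counts partition the FDR < 5% rows
  sig <- !is.na(tab$fdr) & tab$fdr < 0.05 & tab$support > 0
  expect_equal(sum(tab$tier != "ns"), sum(sig))
  expect_equal(sum(tab$tier %in% c("high", "medium", "low")), sum(sig))
})

test_that("e2g annotation: distances, nearest flag, empty input", {
  design <- list(targets = data.frame(
    target_id = "T1", class = "ENH", chrom = "chr1",
    start = 1000000, end = 1000300,
    expected_gene_id = "gA", stringsAsFactors = FALSE))
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss = c(1040150, 1900150))
  e2g <- data.frame(target_id = "T1", gene_id = "gA",
                    p_combined = 1e-6, n_guides_tested = 4L,
                    summary_log2fc = -0.5,
                    guide_p = I(list(rep(0.01, 4))),
                    guide_log2fc = I(list(rep(-0.5, 4))),
                    guide_n_cells = I(list(rep(100, 4))),
                    fdr = 1e-5, support = 4L, tier = "high",
                    stringsAsFactors = FALSE)
  out <- build_e2g_table(e2g, design, ann, tested_genes = c("gA", "gB"))
  # midpoint 1000150 to TSS 1040150 = 40 kb exactly
  expect_equal(out$table$distance_bp, 40000)
  expect_true(out$table$is_nearest_expressed_gene)
  expect_equal(out$summaries$nearest_gene_fraction, 1)
  # no significant rows: zero summaries, no errors
  e2g0 <- e2g
  e2g0$fdr <- 0.9
  e2g0$tier <- "ns"
  out0 <- build_e2g_table(e2g0, design, ann, c("gA", "gB"))
  expect_equal(out0$summaries$n_significant, 0)
  expect_equal(unname(out0$summaries$tier_counts["high"]), 0L)
})

test_that("planted effects produce no false high-tier links", {
  an <- tiny_analysis()
  tab <- an$e2g$table
  high <- tab[tab$tier == "high", ]
  if (nrow(high) > 0) {
    expect_true(all(high$is_expected_pair))
  }
  # overall false-link rate among non-planted pairs stays near nominal
  nonplanted <- tab[!tab$is_expected_pair, ]
  fl <- mean(nonplanted$fdr < 0.05, na.rm = TRUE)
  expect_lte(fl, 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(nonplanted)))
})
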