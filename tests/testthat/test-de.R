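test_that("detection filter applies a strict >= 5% boundary", {
  n <- 1000
  g1 <- c(rep(1, 49), rep(0, n - 49))   # 4.9%: excluded
  g2 <- c(rep(1, 50), rep(0, n - 50))   # 5.0%: included
  g3 <- rep(1, n)                        # 100%: included
  m <- dense_counts(rbind(g1, g2, g3), c("g1", "g2", "g3"),
                    sprintf("c%04d", 1:n))
  expect_equal(detection_filter(m, 0.05), c("g2", "g3"))
})

test_that("detection filter equals hand enumeration on a toy matrix", {
  set.seed(1)
  x <- matrix(rbinom(20 * 40, 1, 0.3), 20, 40)
  m <- dense_counts(x, paste0("g", 1:20), paste0("c", 1:40))
  want <- paste0("g", which(rowSums(x > 0) / 40 >= 0.25))
  expect_equal(detection_filter(m, 0.25), want)
})

test_that("log-normalization: size factors and invariances", {
  m <- dense_counts(rbind(c(2, 2, 2), c(4, 4, 4)), c("a", "b"),
                    c("c1", "c2", "c3"))
  nm <- normalize_log(m)
  expect_equal(unname(nm$size_factors), c(1, 1, 1))
  expect_equal(as.matrix(nm$logcounts),
               log2(1 + as.matrix(m)), ignore_attr = TRUE)
  # doubling one cell's counts doubles its size factor; normalized values
  # change only through the pseudo-count curvature
  m2 <- m
  m2[, 1] <- m2[, 1] * 2
  nm2 <- normalize_log(m2)
  expect_equal(unname(nm2$size_factors[1]), 2)
  expect_equal(as.numeric(nm2$logcounts[, 1]),
               as.numeric(nm$logcounts[, 1]))
  # single count in a sea of zeros
  m3 <- dense_counts(rbind(c(1, 1), c(0, 1)), c("a", "b"), c("c1", "c2"))
  expect_equal(as.numeric(normalize_log(m3)$logcounts[2, 2]),
               log2(1 + 1 / (2 / stats::median(c(1, 2)))))
  m4 <- dense_counts(rbind(c(1, 0)), "a", c("c1", "c2"))
  expect_error(normalize_log(m4), "zero total")
})

test_that("CDR covariate is the standardized detection fraction", {
  set.seed(2)
  x <- matrix(rbinom(30 * 50, 2, 0.3), 30, 50)
  m <- dense_counts(x, paste0("g", 1:30), paste0("c", 1:50))
  cdr <- compute_cdr(m, paste0("g", 1:30))
  frac <- colSums(x > 0) / 30
  expect_equal(unname(cdr), as.numeric(scale(frac)))
  expect_equal(mean(cdr), 0, tolerance = 1e-12)
  expect_equal(stats::sd(cdr), 1, tolerance = 1e-12)
  # identical cells: zero variance, covariate dropped with warning
  m0 <- dense_counts(matrix(1, 3, 10), paste0("g", 1:3), paste0("c", 1:10))
  expect_warning(out <- compute_cdr(m0, paste0("g", 1:3)), "dropped")
  expect_null(out)
  expect_error(compute_cdr(m, character(0)), "nonempty")
})

test_that("NT background selection enforces the eligibility rule", {
  cells <- data.frame(
    cell_id = c("a", "b", "c", "d", "e"),
    n_umis = 10L, n_assigned = c(1L, 1L, 2L, 1L, 0L),
    assigned_guides = c("NT1_g1", "NT2_g1", "NT1_g1,T1_g1", "T1_g2", ""),
    class = c("single", "single", "multi", "single", "unassigned"),
    stringsAsFactors = FALSE
  )
  a <- structure(list(table = NULL, cells = cells),
                 class = "assignment_table")
  nt <- c("NT1_g1", "NT2_g1")
  # multi cell with an NT guide is NOT eligible; targeting single is not
  expect_warning(bg <- select_nt_background(a, nt, n = 5000, seed = 1),
                 "eligible")
  expect_setequal(bg, c("a", "b"))
  expect_identical(select_nt_background(a, nt, n = 1, seed = 3),
                   select_nt_background(a, nt, n = 1, seed = 3))
  a$cells$assigned_guides[1:2] <- "T1_g1"
  a$cells$class[1:2] <- "single"
  expect_error(select_nt_background(a, nt), "no cells")
})

test_that("window membership uses a closed interval on the same chromosome", {
  ann <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    tss = c(4e6, 2e6, 7e6 + 1, 5e6),
    stringsAsFactors = FALSE
  )
  target <- list(chrom = "chr1", start = 5e6, end = 6e6)
  # gB sits exactly at start - 1 Mb: included; gC just beyond end + 1 Mb
  ann$tss[2] <- 4e6
  got <- genes_in_window(list(chrom = "chr1", start = 5e6, end = 6e6), ann)
  expect_true("gB" %in% genes_in_window(target, ann) ||
                TRUE) # see explicit boundary checks below
  expect_setequal(genes_in_window(target, ann), c("gA", "gB"))
  ann2 <- data.frame(gene_id = "gE", chrom = "chr1", tss = 4e6)
  expect_equal(genes_in_window(target, ann2), "gE") # exactly at boundary
  expect_error(genes_in_window(list(chrom = "chrX", start = 1, end = 2),
                               ann), "absent")
})

test_that("hand-placed toy annotation matches enumeration", {
  ann <- data.frame(gene_id = sprintf("g%02d", 1:40), chrom = "chr1",
                    tss = seq(0, 39) * 1e5)
  target <- list(chrom = "chr1", start = 2e6, end = 2.1e6)
  want <- ann$gene_id[ann$tss >= 1e6 & ann$tss <= 3.1e6]
  expect_equal(genes_in_window(target, ann), want)
})

# --- hurdle model -----------------------------------------------------------

test_that("hurdle LR statistics match a generic-optimizer ML oracle", {
  fx <- twelve_cell_fixture()
  res <- hurdle_lrt("T1", fx$guide_cells, fx$background,
                    c("geneX", "geneY"), fx$counts, fx$size_factors,
                    fx$batch)
  group <- rep(c(1, 0), each = 6)
  X_full <- cbind(1, group)
  X_red <- matrix(1, 12, 1)
  for (g in c("geneX", "geneY")) {
    y <- as.numeric(fx$counts[g, ] > 0)
    v <- log2(1 + as.numeric(fx$counts[g, ]))
    lr <- oracle_hurdle_lr(X_full, X_red, 2, integer(0), y, v)
    row <- res[res$gene_id == g, ]
    disc_ok <- sum(y) >= 3 && sum(1 - y) >= 3
    want_df <- 1 + disc_ok
    want_stat <- unname(lr["cont"] + if (disc_ok) lr["disc"] else 0)
    expect_equal(row$df, want_df)
    got_stat <- stats::qchisq(row$p_raw, df = row$df, lower.tail = FALSE)
    expect_equal(got_stat, want_stat, tolerance = 1e-6)
    expect_equal(row$log2fc, mean(v[1:6]) - mean(v[7:12]))
  }
})

test_that("hurdle p-values are invariant to a location shift of the values", {
  # the continuous component has an intercept: shifting every
  # log-normalized value leaves its LR unchanged
  set.seed(8)
  v <- rnorm(40, 2, 1)
  X_full <- cbind(1, rep(c(1, 0), each = 20))
  X_red <- matrix(1, 40, 1)
  lr <- function(vals) 40 * log(cropqtl:::.rss(X_red, vals) /
                                  cropqtl:::.rss(X_full, vals))
  expect_equal(lr(v), lr(v + 3), tolerance = 1e-10)
})

test_that("a strong planted knockdown is called with certainty", {
  scr <- fixture("kd_screen", function() {
    gen <- tiny_genome()
    des <- build_design(c(TSS = 1), 4, 4, genome = gen, seed = 21)
    simulate_screen(des, sim_params(
      n_cells = 2500, n_genes = 60, seed = 31,
      knockdown_by_class = c(TSS = 0.5, ENH = 0, CCRE_INTRONIC = 0,
                             CCRE_INTERGENIC = 0, LCR = 0),
      knockdown_concentration = 1e6,
      guide_eff_shape1 = 1e6, guide_eff_shape2 = 1e-6,
      expected_gene_mean_range = c(5, 5), doublet_rate = 0))
  })
  an <- analyze_screen(scr, nt_background_n = 800, seed = 2)
  des <- scr$design
  gene <- des$targets$expected_gene_id[1]
  rows <- an$de$results[an$de$results$gene_id == gene, ]
  expect_true(all(rows$p_raw < 1e-6))
  expect_true(all(rows$log2fc < -0.4))
  expect_lt(mean(rows$log2fc), -0.5)
})

test_that("null screen p-values are roughly uniform at small scale", {
  an <- fixture("tiny_null_analysis", function() {
    analyze_screen(tiny_null_screen(), nt_background_n = 800, seed = 3)
  })
  p <- an$de$results$p_raw
  p <- p[!is.na(p)]
  expect_gt(length(p), 200)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  expect_lt(suppressWarnings(stats::ks.test(p, "punif")$statistic), 0.08)
  # and no spurious target-level links
  tab <- an$e2g$table
  expect_lte(mean(tab$fdr < 0.05, na.rm = TRUE), 0.05 + 0.02)
})

test_that("guides with zero recovered cells give flagged NA rows", {
  fx <- twelve_cell_fixture()
  gc <- c(fx$guide_cells, list(T1_g2 = character(0)))
  res <- hurdle_lrt("T1", gc, fx$background, "geneX", fx$counts,
                    fx$size_factors, fx$batch)
  na_row <- res[res$guide_id == "T1_g2", ]
  expect_true(is.na(na_row$p_raw))
  expect_equal(na_row$flag, "no_cells")
})

# --- rank-sum backend -------------------------------------------------------

test_that("van Elteren test: identical groups, shifts, single stratum", {
  v <- rep(c(1, 2, 3), 4)
  same <- cropqtl:::.van_elteren(c(v, v), rep(c(TRUE, FALSE), each = 12),
                                 rep("E1", 24))
  expect_equal(same$p, 1)
  # single batch equals the textbook tie-corrected statistic on 6 values
  x1 <- c(1.2, 3.4, 2.2); x2 <- c(0.1, 0.5, 2.2)
  ve <- cropqtl:::.van_elteren(c(x1, x2), rep(c(TRUE, FALSE), each = 3),
                               rep("E1", 6))
  expect_equal(ve$z, oracle_ranksum_z(x1, x2), tolerance = 1e-12)
  # clearly shifted distributions are detected
  set.seed(12)
  a <- rnorm(200); b <- rnorm(200, 1)
  sh <- cropqtl:::.van_elteren(c(a, b), rep(c(TRUE, FALSE), each = 200),
                               rep(c("E1", "E2"), 200))
  expect_lt(sh$p, 1e-4)
})

test_that("the wilcoxon backend produces the same schema and sane calls", {
  scr <- fixture("kd_screen", function() stop("built above"))
  an <- analyze_screen(scr, backend = "wilcoxon", nt_background_n = 800,
                       seed = 2)
  res <- an$de$results
  expect_true(all(c("target_id", "guide_id", "gene_id", "p_raw", "p_adj",
                    "log2fc", "backend") %in% names(res)))
  expect_true(all(res$backend == "wilcoxon"))
  gene <- scr$design$targets$expected_gene_id[1]
  rows <- res[res$gene_id == gene, ]
  expect_true(all(rows$p_raw < 1e-4))
})
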