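test_that("binomial tail p-value: closed forms and input validation", {
  expect_equal(binomial_tail_pvalue(0, 10, 0.3), 1)
  expect_equal(binomial_tail_pvalue(5, 5, 0.5), 0.03125)
  expect_error(binomial_tail_pvalue(6, 5, 0.5), "x must")
  expect_error(binomial_tail_pvalue(1, 5, 0), "strictly")
  expect_error(binomial_tail_pvalue(1, 5, 1), "strictly")
  # monotone non-increasing in x
  p <- binomial_tail_pvalue(0:50, 50, 0.1)
  expect_true(all(diff(p) <= 0))
})

test_that("tail p-values match term-by-term summation to 1e-10 relative", {
  expect_equal(binomial_tail_pvalue(10, 1000, 1 / 355),
               oracle_binom_tail(10, 1000, 1 / 355),
               tolerance = 1e-10)
  set.seed(202)
  for (i in 1:200) {
    n <- sample(5000, 1)
    x <- sample.int(n, 1)
    p <- stats::runif(1, 1e-4, 0.5)
    got <- binomial_tail_pvalue(x, n, p)
    want <- oracle_binom_tail(x, n, p)
    expect_lt(abs(got - want) / max(want, 1e-300), 1e-10)
  }
})

make_guide_matrix <- function(x, guides, cells) {
  m <- Matrix::Matrix(x, nrow = length(guides), sparse = TRUE,
                      dimnames = list(guides, cells))
  methods::as(m, "CsparseMatrix")
}

test_that("the UMI floor discards significant low-support assignments", {
  lib <- data.frame(guide_id = c("g1", "g2"), plasmid_count = c(1, 999),
                    proportion = c(0.001, 0.999))
  class(lib) <- c("guide_library", "data.frame")
  # 3 UMIs of a rare guide: highly significant but at the floor
  m <- make_guide_matrix(c(3, 7), c("g1", "g2"), "cellA")
  a <- assign_guides(m, lib)
  row <- a$table[a$table$guide_id == "g1", ]
  expect_lt(row$p_adj, 0.001)
  expect_false(row$assigned)
  # 4 UMIs clears the floor
  m2 <- make_guide_matrix(c(4, 7), c("g1", "g2"), "cellA")
  a2 <- assign_guides(m2, lib)
  expect_true(a2$table$assigned[a2$table$guide_id == "g1"])
})

test_that("cells with no guide UMIs are unassigned", {
  lib <- data.frame(guide_id = c("g1", "g2"), plasmid_count = c(5, 5),
                    proportion = c(0.5, 0.5))
  class(lib) <- c("guide_library", "data.frame")
  m <- make_guide_matrix(c(0, 0, 20, 0), c("g1", "g2"),
                         c("cell1", "cell2"))
  a <- assign_guides(m, lib)
  expect_equal(a$cells$class, c("unassigned", "single"))
  expect_error(
    assign_guides(make_guide_matrix(1:3, c("g1", "g2", "gX"), "c1"), lib),
    "gX")
})

test_that("with alpha -> 1 and no floor, any observed guide is assigned", {
  lib <- data.frame(guide_id = paste0("g", 1:4),
                    plasmid_count = c(1, 2, 3, 4),
                    proportion = (1:4) / 10)
  class(lib) <- c("guide_library", "data.frame")
  m <- make_guide_matrix(c(1, 0, 2, 0, 0, 5, 0, 1), paste0("g", 1:4),
                         c("c1", "c2"))
  a <- assign_guides(m, lib, alpha = 1, umi_floor = 0)
  expect_true(all(a$table$assigned))
})

test_that("assignment decisions equal the brute-force oracle", {
  scr <- tiny_screen()
  sub <- scr$guide_counts[, 1:400]
  a <- assign_guides(sub, scr$library)
  want <- oracle_assign(sub, scr$library)
  got <- matrix(FALSE, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  at <- a$table[a$table$assigned, ]
  got[cbind(at$guide_id, at$cell_id)] <- TRUE
  expect_identical(got, want)
})

test_that("assignment recovers the simulated truth accurately", {
  scr <- tiny_screen()
  a <- tiny_analysis()$assignments
  truth <- scr$truth
  singles <- a$cells[a$cells$class == "single", ]
  ints <- truth$integrations[match(singles$cell_id, truth$cell_id)]
  precision <- mean(mapply(function(g, tr) g %in% tr,
                           singles$assigned_guides, ints))
  expect_gte(precision, 0.98)
  true_single <- truth$cell_id[lengths(truth$integrations) == 1 &
                                 !truth$doublet]
  true_single <- intersect(true_single, a$cells$cell_id)
  sub <- a$cells[match(true_single, a$cells$cell_id), ]
  tr_guide <- unlist(truth$integrations[match(true_single,
                                              truth$cell_id)])
  recall <- mean(sub$class == "single" & sub$assigned_guides == tr_guide)
  expect_gte(recall, 0.85)
})

test_that("cell class proportions partition and match the truncated Poisson", {
  # trivial partitions: rare guides with strong counts are significant
  lib <- data.frame(guide_id = paste0("g", 1:4),
                    plasmid_count = c(5, 5, 45, 45),
                    proportion = c(0.05, 0.05, 0.45, 0.45))
  class(lib) <- c("guide_library", "data.frame")
  m <- make_guide_matrix(c(30, 0, 0, 0, 20, 25, 0, 0), paste0("g", 1:4),
                         c("c1", "c2"))
  a <- assign_guides(m, lib)
  s <- classify_cells(a)
  expect_equal(sum(s$proportion), 1)
  expect_equal(s$proportion[s$class == "single"], 0.5)
  expect_equal(s$proportion[s$class == "multi"], 0.5)
  # clean screen: no ambient, no doublets, strong capture
  scr <- fixture("clean_assign_screen", function() {
    simulate_screen(tiny_design(),
                    sim_params(n_cells = 3000, n_genes = 50,
                               ambient_rate = 0, doublet_rate = 0,
                               guide_umi_mean = 60, capture_sdlog = 0.1,
                               seed = 55))
  })
  a2 <- assign_guides(scr$guide_counts, scr$library)
  s2 <- classify_cells(a2)
  assigned <- s2$n[s2$class != "unassigned"]
  frac_single <- assigned[1] / sum(assigned)
  expected <- 0.3 * exp(-0.3) / (1 - exp(-0.3))
  se <- sqrt(expected * (1 - expected) / sum(assigned))
  expect_lt(abs(frac_single - expected), 3 * se + 0.01)
})

test_that("raising ambient noise does not improve assignment precision", {
  prec_at <- function(ar) {
    scr <- simulate_screen(
      tiny_design(),
      sim_params(n_cells = 1500, n_genes = 30, ambient_rate = ar,
                 doublet_rate = 0, seed = 91))
    a <- assign_guides(scr$guide_counts, scr$library)
    singles <- a$cells[a$cells$class == "single", ]
    ints <- scr$truth$integrations[match(singles$cell_id,
                                         scr$truth$cell_id)]
    mean(mapply(function(g, tr) g %in% tr, singles$assigned_guides, ints))
  }
  p0 <- prec_at(0)
  p30 <- prec_at(0.30)
  expect_gte(p0, p30 - 0.02)
})
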