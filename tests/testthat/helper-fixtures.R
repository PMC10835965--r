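# Small hand-coded fixtures shared across test files.

dense_counts <- function(x, genes, cells) {
  m <- Matrix::Matrix(x, nrow = length(genes), sparse = TRUE,
                      dimnames = list(genes, cells))
  methods::as(m, "CsparseMatrix")
}

# 12 cells, one guide group (6) vs background (6); geneX has zeros in both
# groups (both hurdle components estimable), geneY is detected almost
# everywhere (discrete component unusable)
twelve_cell_fixture <- function() {
  cells <- sprintf("c%02d", 1:12)
  counts <- dense_counts(rbind(
    geneX = c(3, 0, 5, 2, 0, 1, 8, 6, 0, 4, 0, 7),
    geneY = c(1, 1, 2, 0, 1, 2, 1, 0, 2, 1, 3, 1)
  ), c("geneX", "geneY"), cells)
  list(
    counts = counts,
    guide_cells = list(T1_g1 = cells[1:6]),
    background = cells[7:12],
    size_factors = stats::setNames(rep(1, 12), cells),
    batch = stats::setNames(rep("E1", 12), cells)
  )
}
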