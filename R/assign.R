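#' Upper-tail binomial p-value
#'
#' Probability P[X >= x] for X ~ Binomial(n, p), inclusive upper tail,
#' computed with the numerically stable survival function. This is the
#' per-guide test of the probabilistic guide-to-cell assignment framework:
#' x is a guide's UMI count in a cell, n the cell's total guide-library
#' UMIs, and p the guide's expected proportion from the plasmid library,
#' so the test accounts for both per-cell library size and per-guide
#' abundance.
#'
#' @param x observed count(s), 0 <= x <= n.
#' @param n number of trials.
#' @param p success probability in (0, 1).
#' @return p-value(s), vectorized over x/n/p.
#' @export
binomial_tail_pvalue <- function(x, n, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  if (any(x < 0) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  stats::pbinom(x - 1, n, p, lower.tail = FALSE)
}

#' Assign guides to cells by binomial testing
#'
#' For each cell with at least one guide UMI, every observed guide is
#' tested against its expected plasmid proportion with an upper-tail
#' binomial test on (x_gc, N_c, p_g). P-values are Bonferroni-adjusted per
#' cell across all guides in the library. A guide is assigned when its
#' adjusted p-value is below `alpha` AND it is supported by more than
#' `umi_floor` UMIs (significant assignments with `umi_floor` or fewer
#' UMIs are discarded). Cells may carry any number of assigned guides.
#'
#' @param guide_counts sparse guides x cells UMI matrix with dimnames.
#' @param library a `guide_library`; proportions are renormalized to sum
#'   to 1 if needed.
#' @param alpha significance level on the Bonferroni-adjusted p-value;
#'   `alpha = 1` disables the significance gate entirely (limit
#'   behavior: every guide with any UMI support above the floor is
#'   assigned).
#' @param umi_floor assignments supported by <= umi_floor UMIs are
#'   discarded.
#' @return list of class `assignment_table`: `table` (data.frame cell_id,
#'   guide_id, x, n, p_raw, p_adj, assigned for every nonzero candidate)
#'   and `cells` (data.frame cell_id, n_umis, n_assigned, assigned_guides
#'   (comma-separated), class in {unassigned, single, multi}).
#' @export
assign_guides <- function(guide_counts, library, alpha = 0.001,
                          umi_floor = 3) {
  stopifnot(alpha > 0, alpha <= 1, umi_floor >= 0)
  if (is.null(rownames(guide_counts)) || is.null(colnames(guide_counts))) {
    stop("guide_counts must carry guide and cell dimnames")
  }
  unknown <- setdiff(rownames(guide_counts), library$guide_id)
  if (length(unknown)) {
    stop("guide(s) absent from library: ", paste(unknown, collapse = ", "))
  }
  if (any(guide_counts@x < 0) || any(guide_counts@x != round(guide_counts@x))) {
    stop("guide_counts must contain nonnegative integers")
  }
  prop <- library$proportion / sum(library$proportion)
  names(prop) <- library$guide_id
  n_family <- nrow(library)
  m <- methods::as(guide_counts, "CsparseMatrix")
  ncell <- ncol(m)
  n_c <- Matrix::colSums(m)
  # triplet view of nonzero candidates
  dp <- diff(m@p)
  cell_j <- rep.int(seq_len(ncell), dp)
  guide_i <- m@i + 1L
  x <- m@x
  p_g <- prop[rownames(m)][guide_i]
  p_raw <- binomial_tail_pvalue(x, n_c[cell_j], p_g)
  p_adj <- pmin(1, p_raw * n_family)
  sig <- if (alpha >= 1) rep(TRUE, length(p_adj)) else p_adj < alpha
  assigned <- sig & (x > umi_floor)
  tab <- data.frame(
    cell_id = colnames(m)[cell_j],
    guide_id = rownames(m)[guide_i],
    x = as.integer(x),
    n = as.integer(n_c[cell_j]),
    p_raw = p_raw,
    p_adj = p_adj,
    assigned = assigned,
    stringsAsFactors = FALSE
  )
  n_assigned <- integer(ncell)
  if (any(assigned)) {
    ta <- table(factor(cell_j[assigned], levels = seq_len(ncell)))
    n_assigned <- as.integer(ta)
  }
  ag <- character(ncell)
  if (any(assigned)) {
    sp <- split(tab$guide_id[assigned], cell_j[assigned])
    ag[as.integer(names(sp))] <- vapply(sp, paste, "", collapse = ",")
  }
  cells <- data.frame(
    cell_id = colnames(m),
    n_umis = as.integer(n_c),
    n_assigned = n_assigned,
    assigned_guides = ag,
    class = ifelse(n_assigned == 0, "unassigned",
                   ifelse(n_assigned == 1, "single", "multi")),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, cells = cells,
                 alpha = alpha, umi_floor = umi_floor),
            class = "assignment_table")
}

#' Summarize per-cell assignment classes
#'
#' Partitions cells into unassigned / single / multi and reports counts and
#' proportions (summing to 1).
#'
#' @param assignments an `assignment_table`.
#' @return data.frame with class, n, proportion.
#' @export
classify_cells <- function(assignments) {
  cls <- factor(assignments$cells$class,
                levels = c("unassigned", "single", "multi"))
  n <- as.integer(table(cls))
  data.frame(class = levels(cls), n = n,
             proportion = if (sum(n) > 0) n / sum(n) else rep(0, 3),
             stringsAsFactors = FALSE)
}

#' @export
print.assignment_table <- function(x, ...) {
  s <- classify_cells(x)
  cat("guide assignment:", nrow(x$cells), "cells;",
      sprintf("%.1f%% single, %.1f%% multi, %.1f%% unassigned\n",
              100 * s$proportion[s$class == "single"],
              100 * s$proportion[s$class == "multi"],
              100 * s$proportion[s$class == "unassigned"]))
  invisible(x)
}
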