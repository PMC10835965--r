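#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the total UMI count, the number of genes
#' detected and the fraction of counts mapping to mitochondrial genes.
#' All-zero cells get a mitochondrial fraction of 0.
#'
#' @param counts sparse or dense gene x cell count matrix with rownames.
#' @param mito_gene_ids character vector of mitochondrial gene ids; defaults
#'   to rownames starting with "MT-".
#' @param batch optional per-cell batch labels (recycled into the result).
#' @return data.frame of class `cell_qc_metrics`: cell_id, total_umis,
#'   n_genes_detected, mito_fraction, batch.
#' @export
compute_qc_metrics <- function(counts, mito_gene_ids = NULL, batch = NULL) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0) {
    stop("counts must be a non-empty gene x cell matrix")
  }
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (is.null(mito_gene_ids)) {
    mito_gene_ids <- grep("^MT-", rownames(counts), value = TRUE)
  } else if (!all(mito_gene_ids %in% rownames(counts))) {
    stop("mito_gene_ids must be a subset of the matrix rownames")
  }
  total <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mt <- if (length(mito_gene_ids)) {
    Matrix::colSums(counts[mito_gene_ids, , drop = FALSE])
  } else rep(0, ncol(counts))
  mfrac <- ifelse(total > 0, mt / total, 0)
  out <- data.frame(
    cell_id = colnames(counts) %||% sprintf("CELL%07d", seq_len(ncol(counts))),
    total_umis = as.numeric(total),
    n_genes_detected = as.integer(ngene),
    mito_fraction = as.numeric(mfrac),
    batch = if (is.null(batch)) "E1" else as.character(batch),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_qc_metrics", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# MAD with the 1.4826 normal-consistency constant
.mad <- function(x) stats::mad(x, constant = 1.4826)

#' MAD-based per-batch cell filtering
#'
#' Removes a cell when, within its batch, any of the following holds:
#' log1p(total UMIs) or log1p(genes detected) falls below median - n_mads *
#' MAD; mitochondrial fraction (natural scale) rises above median + n_mads *
#' MAD; or mitochondrial fraction falls below median - n_mads * MAD (the
#' stripped-nuclei rule). Boundary cells exactly at the threshold are kept
#' (the exclusion rule is strictly "more than" n_mads deviations). If a
#' metric's MAD is 0 within a batch, that metric filters nothing there
#' (degenerate, documented behavior).
#'
#' @param metrics a `cell_qc_metrics` data.frame.
#' @param n_mads number of MADs defining the outlier threshold.
#' @return list with `keep` (named logical per cell) and `thresholds`
#'   (data.frame per batch: lower bounds on totals/genes, bounds on
#'   mitochondrial fraction).
#' @export
filter_cells <- function(metrics, n_mads = 3) {
  stopifnot(n_mads >= 0)
  batches <- unique(metrics$batch)
  keep <- rep(TRUE, nrow(metrics))
  thr <- vector("list", length(batches))
  for (i in seq_along(batches)) {
    b <- batches[i]
    idx <- which(metrics$batch == b)
    if (length(idx) < 2) stop("need at least 2 cells per batch")
    lt <- log1p(metrics$total_umis[idx])
    lg <- log1p(metrics$n_genes_detected[idx])
    mf <- metrics$mito_fraction[idx]
    lo_t <- .lower_bound(lt, n_mads)
    lo_g <- .lower_bound(lg, n_mads)
    hi_m <- .upper_bound(mf, n_mads)
    lo_m <- .lower_bound(mf, n_mads)
    bad <- (lt < lo_t) | (lg < lo_g) | (mf > hi_m) | (mf < lo_m)
    keep[idx] <- !bad
    thr[[i]] <- data.frame(
      batch = b,
      min_log1p_total = lo_t, min_log1p_genes = lo_g,
      max_mito_fraction = hi_m, min_mito_fraction = lo_m,
      n_cells = length(idx), n_removed = sum(bad),
      stringsAsFactors = FALSE
    )
  }
  list(keep = stats::setNames(keep, metrics$cell_id),
       thresholds = do.call(rbind, thr))
}

# -Inf when MAD = 0 so the metric filters nothing in that batch
.lower_bound <- function(x, n_mads) {
  m <- .mad(x)
  if (m == 0) -Inf else stats::median(x) - n_mads * m
}
.upper_bound <- function(x, n_mads) {
  m <- .mad(x)
  if (m == 0) Inf else stats::median(x) + n_mads * m
}

#' Heuristic doublet flag
#'
#' Flags cells that are BOTH assigned multiple guides and above their
#' batch's 95th percentile of total UMI counts. This is a lightweight
#' stand-in for neighbor-simulation doublet callers: droplet doublets carry
#' more mRNA and are more likely to show two guides. The flag is advisory;
#' removal is a pipeline option.
#'
#' @param assignments an `assignment_table` (see [assign_guides()]).
#' @param metrics a `cell_qc_metrics` data.frame.
#' @param quantile total-UMI quantile above which a multi-guide cell is
#'   flagged.
#' @return named logical vector per cell in `metrics`.
#' @export
flag_doublet_like <- function(assignments, metrics, quantile = 0.95) {
  cls <- assignments$cells
  multi <- cls$cell_id[cls$class == "multi"]
  flag <- rep(FALSE, nrow(metrics))
  for (b in unique(metrics$batch)) {
    idx <- which(metrics$batch == b)
    q <- stats::quantile(metrics$total_umis[idx], quantile, names = FALSE,
                         type = 7)
    hi <- metrics$total_umis[idx] > q
    flag[idx] <- hi & (metrics$cell_id[idx] %in% multi)
  }
  stats::setNames(flag, metrics$cell_id)
}
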