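#' Detection filter
#'
#' Genes tested for differential expression must be detected (nonzero
#' count) in at least `min_frac` of cells; the boundary is inclusive.
#'
#' @param counts gene x cell count matrix.
#' @param min_frac minimum detection fraction in (0, 1).
#' @return character vector of gene ids passing the filter.
#' @export
detection_filter <- function(counts, min_frac = 0.05) {
  stopifnot(min_frac > 0, min_frac < 1)
  det <- Matrix::rowSums(counts > 0) / ncol(counts)
  rownames(counts)[det >= min_frac]
}

#' Library-size log-normalization
#'
#' Size factors are per-cell totals scaled to median 1; normalized values
#' are log2(1 + count / size_factor). This is a deliberate simplification
#' of pooling-based deconvolution factors; the factor definition is
#' isolated here so alternatives can be substituted.
#'
#' @param counts gene x cell count matrix (QC-passing cells).
#' @return list of class `normalized_expression`: `size_factors` (named),
#'   `logcounts` (sparse, same dims as counts).
#' @export
normalize_log <- function(counts) {
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("cells with zero total counts must be removed by QC")
  s <- total / stats::median(total)
  lc <- counts
  if (methods::is(lc, "sparseMatrix")) {
    lc <- methods::as(lc, "CsparseMatrix")
    dp <- diff(lc@p)
    lc@x <- log2(1 + lc@x / rep.int(s, dp))
  } else {
    lc <- log2(1 + sweep(as.matrix(counts), 2, s, "/"))
  }
  structure(list(size_factors = stats::setNames(s, colnames(counts)),
                 logcounts = lc),
            class = "normalized_expression")
}

# dense log-normalized block for a subset of genes/cells
.norm_block <- function(counts, size_factors, genes, cells) {
  m <- as.matrix(counts[genes, cells, drop = FALSE])
  log2(1 + sweep(m, 2, size_factors[cells], "/"))
}

#' Cellular detection rate covariate
#'
#' Fraction of tested genes detected in each cell, centered and scaled to
#' unit variance. With zero variance the covariate is dropped (returns
#' NULL) with a warning.
#'
#' @param counts gene x cell count matrix.
#' @param tested_genes character vector of tested gene ids.
#' @return named numeric vector per cell, or NULL.
#' @export
compute_cdr <- function(counts, tested_genes) {
  if (!length(tested_genes)) stop("tested_genes must be nonempty")
  frac <- Matrix::colSums(counts[tested_genes, , drop = FALSE] > 0) /
    length(tested_genes)
  if (stats::sd(frac) == 0) {
    warning("cellular detection rate has zero variance; covariate dropped")
    return(NULL)
  }
  stats::setNames(as.numeric(scale(frac)), colnames(counts))
}

#' Select the non-targeting background cell set
#'
#' Samples up to `n` cells uniformly without replacement among cells whose
#' ONLY assigned guide is non-targeting. The same set is reused for every
#' target in a run.
#'
#' @param assignments an `assignment_table`.
#' @param nt_guides character vector of non-targeting guide ids.
#' @param n background size (all eligible cells, with a warning, if fewer).
#' @param seed integer seed.
#' @return character vector of cell ids.
#' @export
select_nt_background <- function(assignments, nt_guides, n = 5000,
                                 seed = 1) {
  cls <- assignments$cells
  elig <- cls$cell_id[cls$class == "single" &
                        cls$assigned_guides %in% nt_guides]
  if (!length(elig)) stop("no cells with a single non-targeting guide")
  if (length(elig) <= n) {
    if (length(elig) < n) {
      warning("only ", length(elig), " eligible NT cells (requested ", n, ")")
    }
    return(elig)
  }
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  sample(elig, n)
}

#' Genes within the testing window of a target
#'
#' Returns genes whose TSS lies in the closed interval
#' [start - window, end + window] on the target's chromosome.
#'
#' @param target list or one-row data.frame with chrom, start, end.
#' @param annotation data.frame with gene_id, chrom, tss.
#' @param window flank size in bp (default 1 Mb).
#' @return character vector of gene ids.
#' @export
genes_in_window <- function(target, annotation, window = 1e6) {
  if (!target$chrom %in% annotation$chrom) {
    stop("chromosome ", target$chrom, " absent from annotation")
  }
  sel <- annotation$chrom == target$chrom &
    annotation$tss >= target$start - window &
    annotation$tss <= target$end + window
  annotation$gene_id[sel]
}

# ridge-penalized logistic regression by iteratively reweighted least
# squares; penalty only on the columns in pen_cols. Deterministic.
.fit_logistic_ridge <- function(X, y, pen_cols, lambda = 1e-6,
                                maxit = 30, tol = 1e-10) {
  p <- ncol(X)
  n <- nrow(X)
  aug <- matrix(0, length(pen_cols), p)
  if (length(pen_cols)) {
    aug[cbind(seq_along(pen_cols), pen_cols)] <- sqrt(lambda)
  }
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  pll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- .lm.fit(rbind(X * sw, aug), c(z * sw, numeric(length(pen_cols))))
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    if (!is.null(fit$pivot)) beta_new[fit$pivot] <- beta_new
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    pll <- sum(y * log(mu) + (1 - y) * log(1 - mu)) -
      0.5 * lambda * sum(beta[pen_cols]^2)
    if (abs(pll - pll_old) < tol * (abs(pll_old) + 1)) {
      converged <- TRUE
      pll_old <- pll
      break
    }
    pll_old <- pll
  }
  degenerate <- !converged ||
    (length(pen_cols) > 0 && any(abs(beta[pen_cols]) > 15))
  list(beta = beta, pll = pll_old, converged = converged,
       degenerate = degenerate)
}

# profile Gaussian log-likelihood given residual sum of squares
.gauss_ll <- function(rss, n) {
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

# residual sum of squares of a least-squares fit
.rss <- function(X, v) {
  fit <- .lm.fit(X, v)
  sum(fit$residuals^2)
}

# build full and per-guide reduced design matrices for a target fit
.target_designs <- function(group, batch, cdr, guides) {
  df <- data.frame(group = group)
  rhs <- "group"
  if (nlevels(batch) > 1) {
    df$batch <- batch
    rhs <- c(rhs, "batch")
  }
  if (!is.null(cdr)) {
    df$cdr <- cdr
    rhs <- c(rhs, "cdr")
  }
  form <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X_full <- stats::model.matrix(form, df)
  pen_cols <- grep("^group", colnames(X_full))
  X_red <- lapply(guides, function(g) {
    dfr <- df
    gr <- as.character(dfr$group)
    gr[gr == g] <- "NT"
    dfr$group <- factor(gr, levels = setdiff(levels(group), g))
    if (nlevels(dfr$group) < 2) {
      # single-guide target: the reduced model loses the group term
      rhs_r <- setdiff(rhs, "group")
      form_r <- if (length(rhs_r)) {
        stats::as.formula(paste("~", paste(rhs_r, collapse = " + ")))
      } else ~1
      return(stats::model.matrix(form_r, dfr))
    }
    stats::model.matrix(form, dfr)
  })
  names(X_red) <- guides
  pen_red <- lapply(X_red, function(m) grep("^group", colnames(m)))
  list(full = X_full, reduced = X_red, pen_full = pen_cols,
       pen_red = pen_red)
}

#' Hurdle likelihood-ratio tests for one target
#'
#' Fits, per gene, a two-part model on the cells carrying any of the
#' target's guides plus the non-targeting background: a logistic
#' (detection) component and a Gaussian component on log-normalized
#' expression among detected cells, both with guide-group indicators,
#' batch and cellular-detection-rate covariates. Each guide is tested by a
#' likelihood-ratio statistic comparing the full model to the model with
#' that guide's indicator removed (its cells merged into the background
#' baseline) in both components; the statistic is the sum of the two
#' component LR statistics, referred to a chi-square with df equal to the
#' number of estimable dropped parameters (2, or 1 when a component is
#' degenerate for that gene/guide). The logistic component carries a tiny
#' ridge penalty (1e-6) on guide coefficients for determinism under
#' separation and is flagged degenerate when a guide coefficient exceeds
#' 15 in absolute value; the Gaussian component requires at least 3
#' detected cells in the dropped group and 3 in the remainder.
#'
#' @param target_id target identifier (annotation only).
#' @param guide_cells named list: for each guide, the cell ids exposed to
#'   it (cells with that single assigned guide). Guides with zero cells
#'   yield NA rows flagged "no_cells".
#' @param background character vector of background (NT) cell ids; any
#'   overlap with guide cells is removed from the background for this
#'   target.
#' @param genes character vector of gene ids to test.
#' @param counts gene x cell count matrix (QC-passing cells).
#' @param size_factors named per-cell size factors (see [normalize_log()]).
#' @param batch named per-cell batch labels.
#' @param cdr named per-cell detection-rate covariate, or NULL.
#' @return data.frame: target_id, guide_id, gene_id, n_cells, n_background,
#'   p_raw, log2fc, df, flag.
#' @export
hurdle_lrt <- function(target_id, guide_cells, background, genes, counts,
                       size_factors, batch, cdr = NULL) {
  guides <- names(guide_cells)
  have_cells <- vapply(guide_cells, length, 0L) > 0
  background <- setdiff(background, unlist(guide_cells))
  used <- guides[have_cells]
  if (!length(used) || !length(genes) || length(background) < 2) {
    return(.na_rows(target_id, guides, genes, guide_cells,
                    length(background), "no_cells"))
  }
  cells <- c(unlist(guide_cells[used], use.names = FALSE), background)
  group <- factor(
    c(rep(used, vapply(guide_cells[used], length, 0L)),
      rep("NT", length(background))),
    levels = c("NT", used)
  )
  bf <- droplevels(factor(batch[cells]))
  cv <- if (is.null(cdr)) NULL else cdr[cells]
  designs <- .target_designs(group, bf, cv, used)
  norm <- .norm_block(counts, size_factors, genes, cells)
  det <- as.matrix(counts[genes, cells, drop = FALSE] > 0) * 1
  is_nt <- group == "NT"
  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    y <- det[gi, ]
    v <- norm[gi, ]
    n_det_tot <- sum(y)
    disc_global <- n_det_tot >= 3 && (length(y) - n_det_tot) >= 3
    full_disc <- if (disc_global) {
      .fit_logistic_ridge(designs$full, y, designs$pen_full)
    } else NULL
    idx_det <- which(y == 1)
    rss_full <- if (n_det_tot >= ncol(designs$full) + 1) {
      .rss(designs$full[idx_det, , drop = FALSE], v[idx_det])
    } else NA_real_
    rows <- lapply(used, function(g) {
      gmask <- group == g
      d_g <- sum(y[gmask])
      cont_ok <- !is.na(rss_full) && d_g >= 3 && (n_det_tot - d_g) >= 3
      disc_ok <- disc_global && !is.null(full_disc) && !full_disc$degenerate
      lr <- 0
      df <- 0L
      flag <- ""
      if (disc_ok) {
        red <- .fit_logistic_ridge(designs$reduced[[g]], y,
                                   designs$pen_red[[g]])
        if (red$degenerate) {
          disc_ok <- FALSE
        } else {
          lr <- lr + max(0, 2 * (full_disc$pll - red$pll))
          df <- df + 1L
        }
      }
      if (cont_ok) {
        rss_red <- .rss(designs$reduced[[g]][idx_det, , drop = FALSE],
                        v[idx_det])
        lr <- lr + max(0, n_det_tot * log(rss_red / rss_full))
        df <- df + 1L
      }
      if (!disc_ok && disc_global && !is.null(full_disc) &&
          full_disc$degenerate) flag <- "degenerate_fit"
      p <- if (df > 0) {
        stats::pchisq(lr, df = df, lower.tail = FALSE)
      } else {
        flag <- if (nzchar(flag)) flag else "untestable"
        NA_real_
      }
      data.frame(
        target_id = target_id, guide_id = g, gene_id = genes[gi],
        n_cells = sum(gmask), n_background = sum(is_nt),
        p_raw = p,
        log2fc = mean(v[gmask]) - mean(v[is_nt]),
        df = df, flag = flag, stringsAsFactors = FALSE
      )
    })
    out[[gi]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (any(!have_cells)) {
    res <- rbind(res, .na_rows(target_id, guides[!have_cells], genes,
                               guide_cells, length(background), "no_cells"))
  }
  rownames(res) <- NULL
  res
}

.na_rows <- function(target_id, guides, genes, guide_cells, n_bg, flag) {
  if (!length(guides) || !length(genes)) {
    return(data.frame(target_id = character(), guide_id = character(),
                      gene_id = character(), n_cells = integer(),
                      n_background = integer(), p_raw = numeric(),
                      log2fc = numeric(), df = integer(),
                      flag = character(), stringsAsFactors = FALSE))
  }
  expand <- expand.grid(guide_id = guides, gene_id = genes,
                        stringsAsFactors = FALSE)
  data.frame(target_id = target_id, guide_id = expand$guide_id,
             gene_id = expand$gene_id,
             n_cells = vapply(expand$guide_id,
                              function(g) length(guide_cells[[g]]), 0L),
             n_background = n_bg, p_raw = NA_real_, log2fc = NA_real_,
             df = 0L, flag = flag, stringsAsFactors = FALSE)
}

# van Elteren (stratified rank-sum) test of group1 vs group2 values
.van_elteren <- function(values, is_group1, strata) {
  num <- 0
  den <- 0
  for (s in unique(strata)) {
    idx <- strata == s
    x <- values[idx]
    g1 <- is_group1[idx]
    n1 <- sum(g1)
    n2 <- sum(!g1)
    if (n1 < 2 || n2 < 2) next
    n <- n1 + n2
    r <- rank(x)
    w <- sum(r[g1])
    e <- n1 * (n + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    wt <- 1 / (n + 1)
    num <- num + wt * (w - e)
    den <- den + wt^2 * v
  }
  if (den == 0) return(list(z = 0, p = 1))
  z <- num / sqrt(den)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Rank-sum alternative backend for one target
#'
#' Wilcoxon rank-sum test of each guide's cells against the background,
#' stratified by batch via a van Elteren combination. Output schema matches
#' [hurdle_lrt()]. Groups with fewer than 2 cells in every stratum give NA.
#'
#' @inheritParams hurdle_lrt
#' @export
wilcoxon_target <- function(target_id, guide_cells, background, genes,
                            counts, size_factors, batch, cdr = NULL) {
  guides <- names(guide_cells)
  have_cells <- vapply(guide_cells, length, 0L) > 1
  background <- setdiff(background, unlist(guide_cells))
  used <- guides[have_cells]
  if (!length(used) || !length(genes) || length(background) < 2) {
    return(.na_rows(target_id, guides, genes, guide_cells,
                    length(background), "no_cells"))
  }
  cells <- c(unlist(guide_cells[used], use.names = FALSE), background)
  group <- c(rep(used, vapply(guide_cells[used], length, 0L)),
             rep("NT", length(background)))
  bf <- as.character(batch[cells])
  norm <- .norm_block(counts, size_factors, genes, cells)
  is_nt <- group == "NT"
  out <- list()
  for (gi in seq_along(genes)) {
    v <- norm[gi, ]
    for (g in used) {
      gmask <- group == g
      sel <- gmask | is_nt
      ve <- .van_elteren(v[sel], gmask[sel], bf[sel])
      out[[length(out) + 1]] <- data.frame(
        target_id = target_id, guide_id = g, gene_id = genes[gi],
        n_cells = sum(gmask), n_background = sum(is_nt),
        p_raw = ve$p,
        log2fc = mean(v[gmask]) - mean(v[is_nt]),
        df = 1L, flag = "", stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (any(!have_cells)) {
    res <- rbind(res, .na_rows(target_id, guides[!have_cells], genes,
                               guide_cells, length(background), "no_cells"))
  }
  rownames(res) <- NULL
  res
}

#' Per-guide differential expression across all targets
#'
#' Orchestrates the guide-level testing stage: detection filter, size
#' factors, detection-rate covariate, a fixed non-targeting background,
#' then per-target hurdle (or rank-sum) tests of every guide against the
#' background for all tested genes within the target's window. Cells with
#' multiple assigned guides are excluded; each guide's cell set is the
#' cells whose single assigned guide it is. Benjamini-Hochberg adjustment
#' is applied across all (guide, gene) tests of the run.
#'
#' @param counts gene x cell counts for QC-passing cells.
#' @param assignments an `assignment_table`.
#' @param design a `screen_design` (or compatible list with `targets` and
#'   `guides` data.frames).
#' @param annotation gene annotation data.frame (gene_id, chrom, tss).
#' @param batch named per-cell batch labels.
#' @param backend "hurdle" or "wilcoxon".
#' @param window testing window flank in bp.
#' @param min_frac detection filter threshold.
#' @param nt_background_n background size.
#' @param seed seed for background sampling.
#' @param gene_universe optional fixed gene set tested for every target
#'   (used for pseudo-target calibration runs, where targets have no
#'   genomic window); intersected with the detection filter.
#' @param targets optional subset of target ids to test.
#' @return list of class `de_result`: `results` (data.frame with p_adj
#'   added), `tested_genes`, `background`, `size_factors`, `backend`.
#' @export
de_test <- function(counts, assignments, design, annotation, batch,
                    backend = c("hurdle", "wilcoxon"), window = 1e6,
                    min_frac = 0.05, nt_background_n = 5000, seed = 1,
                    gene_universe = NULL, targets = NULL) {
  backend <- match.arg(backend)
  tested <- detection_filter(counts, min_frac)
  if (!length(tested)) stop("no genes pass the detection filter")
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("cells with zero total counts must be removed by QC")
  size_factors <- stats::setNames(total / stats::median(total),
                                  colnames(counts))
  cdr <- compute_cdr(counts, tested)
  nt_guides <- design$guides$guide_id[
    design$guides$target_id %in%
      design$targets$target_id[design$targets$class == "NT"]]
  background <- select_nt_background(assignments, nt_guides,
                                     n = nt_background_n, seed = seed)
  tt <- design$targets[design$targets$class != "NT", , drop = FALSE]
  if (!is.null(targets)) tt <- tt[tt$target_id %in% targets, , drop = FALSE]
  cls <- assignments$cells
  singles <- cls[cls$class == "single", c("cell_id", "assigned_guides")]
  cell_by_guide <- split(singles$cell_id, singles$assigned_guides)
  fun <- if (backend == "hurdle") hurdle_lrt else wilcoxon_target
  res <- vector("list", nrow(tt))
  for (i in seq_len(nrow(tt))) {
    tg <- tt[i, ]
    genes <- if (is.null(gene_universe)) {
      intersect(genes_in_window(tg, annotation, window), tested)
    } else {
      intersect(gene_universe, tested)
    }
    gids <- design$guides$guide_id[design$guides$target_id == tg$target_id]
    gcells <- lapply(gids, function(g) cell_by_guide[[g]] %||% character(0))
    names(gcells) <- gids
    res[[i]] <- fun(tg$target_id, gcells, background, genes, counts,
                    size_factors, batch, cdr)
  }
  results <- do.call(rbind, res)
  results$backend <- backend
  results$p_adj <- bh_adjust(results$p_raw)
  structure(list(results = results, tested_genes = tested,
                 background = background,
                 size_factors = size_factors, backend = backend),
            class = "de_result")
}
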