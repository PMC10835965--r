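#' Fisher's method for combining p-values
#'
#' Combines k p-values via X2 = -2 * sum(log p), referred to a chi-square
#' distribution with 2k degrees of freedom. NA entries (e.g. guides with no
#' recovered cells) are dropped before combining, reducing the degrees of
#' freedom rather than imputing p = 1.
#'
#' @param pvals numeric vector of p-values in (0, 1]; NAs dropped.
#' @return combined p-value, or NA if no finite p-values remain.
#' @export
fisher_combine <- function(pvals) {
  p <- pvals[!is.na(pvals)]
  if (!length(p)) return(NA_real_)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement,
#' preserving input order. NAs are kept in place and excluded from the
#' family size.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Confidence tier from per-guide evidence
#'
#' Support is the number of guides with raw p < 0.05 whose log2
#' fold-change sign agrees with the majority sign among those guides (sign
#' ties broken by the cell-count-weighted mean fold-change). Tiers: high
#' when the target-level FDR < `fdr` and support is 3 or 4; medium at
#' support 2; low at support 1; "ns" otherwise (including FDR >= `fdr`,
#' regardless of support).
#'
#' @param p_raw per-guide raw p-values (NAs allowed).
#' @param log2fc per-guide log2 fold-changes.
#' @param fdr_value the target-level BH-adjusted p-value for this pair.
#' @param n_cells per-guide cell counts (for the weighted tie-break).
#' @param fdr significance threshold on the target-level FDR.
#' @return list with `tier` and `support`.
#' @export
classify_tier <- function(p_raw, log2fc, fdr_value, n_cells = NULL,
                          fdr = 0.05) {
  sig <- !is.na(p_raw) & p_raw < 0.05 & !is.na(log2fc)
  support <- 0L
  if (any(sig)) {
    signs <- sign(log2fc[sig])
    pos <- sum(signs > 0)
    neg <- sum(signs < 0)
    maj <- if (pos > neg) 1 else if (neg > pos) -1 else {
      w <- if (is.null(n_cells)) rep(1, length(log2fc)) else n_cells
      s <- sign(sum(w[sig] * log2fc[sig]))
      if (s == 0) 1 else s
    }
    support <- sum(signs == maj)
  }
  tier <- if (is.na(fdr_value) || fdr_value >= fdr || support == 0) {
    "ns"
  } else if (support >= 3) {
    "high"
  } else if (support == 2) {
    "medium"
  } else {
    "low"
  }
  list(tier = tier, support = as.integer(support))
}

#' Aggregate guide-level tests into target-level element-to-gene calls
#'
#' For every (target, gene) pair, combines the per-guide raw p-values with
#' Fisher's method, adjusts the combined p-values across all pairs of the
#' run with Benjamini-Hochberg, and assigns confidence tiers from the
#' number of concordant supporting guides. The summary log2 fold-change is
#' the cell-count-weighted mean of per-guide fold-changes.
#'
#' @param de a `de_result` from [de_test()] (or its `results` data.frame).
#' @param fdr FDR threshold for significance and tier assignment.
#' @return data.frame of class `e2g_table`: one row per target-gene pair
#'   with p_combined, fdr, support, tier, summary_log2fc, n_guides_tested.
#' @export
aggregate_targets <- function(de, fdr = 0.05) {
  res <- if (inherits(de, "de_result")) de$results else de
  key <- paste(res$target_id, res$gene_id, sep = "\r")
  sp <- split(seq_len(nrow(res)), key)
  rows <- lapply(sp, function(idx) {
    d <- res[idx, ]
    w <- pmax(d$n_cells, 0)
    ok <- !is.na(d$log2fc)
    sfc <- if (any(ok) && sum(w[ok]) > 0) {
      sum(w[ok] * d$log2fc[ok]) / sum(w[ok])
    } else NA_real_
    data.frame(
      target_id = d$target_id[1], gene_id = d$gene_id[1],
      p_combined = fisher_combine(pmin(pmax(d$p_raw, 1e-300), 1)),
      n_guides_tested = sum(!is.na(d$p_raw)),
      summary_log2fc = sfc,
      guide_p = I(list(d$p_raw)),
      guide_log2fc = I(list(d$log2fc)),
      guide_n_cells = I(list(d$n_cells)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p_combined)
  tiers <- Map(classify_tier, out$guide_p, out$guide_log2fc, out$fdr,
               out$guide_n_cells, fdr = fdr)
  out$support <- vapply(tiers, function(t) t$support, 0L)
  out$tier <- vapply(tiers, function(t) t$tier, "")
  class(out) <- c("e2g_table", "data.frame")
  out
}

#' Annotated element-to-gene result table and summaries
#'
#' Adds genomic context to the aggregated calls: distance from the target
#' interval midpoint to the gene TSS, whether the gene is the nearest
#' tested (expressed) gene to the target, and whether the pair is the
#' design's expected (planted) link. Summaries report tier counts, the
#' DEGs-per-target histogram, distance quantiles split by the nearest-gene
#' flag, and per-class expected-gene recovery. Low-confidence (single
#' guide) calls are retained in the table but excluded from the headline
#' summaries.
#'
#' @param e2g an `e2g_table` from [aggregate_targets()].
#' @param design a `screen_design`.
#' @param annotation gene annotation (gene_id, chrom, tss).
#' @param tested_genes genes that passed the detection filter.
#' @param fdr FDR threshold used for summaries.
#' @return list with `table` (e2g rows + distance_bp,
#'   is_nearest_expressed_gene, is_expected_pair) and `summaries`.
#' @export
build_e2g_table <- function(e2g, design, annotation, tested_genes,
                            fdr = 0.05) {
  tt <- design$targets
  tt <- tt[match(e2g$target_id, tt$target_id), ]
  mid <- (tt$start + tt$end) / 2
  ann_idx <- match(e2g$gene_id, annotation$gene_id)
  e2g$distance_bp <- abs(annotation$tss[ann_idx] - mid)
  expr_ann <- annotation[annotation$gene_id %in% tested_genes, ]
  nearest <- vapply(seq_len(nrow(e2g)), function(i) {
    ch <- tt$chrom[i]
    if (is.na(ch)) return(NA_character_)
    cand <- expr_ann[expr_ann$chrom == ch, ]
    if (!nrow(cand)) return(NA_character_)
    cand$gene_id[which.min(abs(cand$tss - mid[i]))]
  }, "")
  e2g$is_nearest_expressed_gene <- !is.na(nearest) & e2g$gene_id == nearest
  e2g$is_expected_pair <- e2g$gene_id == tt$expected_gene_id &
    !is.na(tt$expected_gene_id)
  e2g$target_class <- tt$class
  sig <- e2g[!is.na(e2g$fdr) & e2g$fdr < fdr & e2g$tier != "ns", ]
  hm <- sig[sig$tier %in% c("high", "medium"), ]
  tier_counts <- table(factor(e2g$tier, levels = c("high", "medium", "low",
                                                   "ns")))
  degs_per_target <- if (nrow(hm)) table(table(hm$target_id)) else table(integer(0))
  dist_q <- function(d) if (length(d)) {
    stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  } else c(NA, NA, NA)
  recovery <- NULL
  exp_rows <- e2g[e2g$is_expected_pair, ]
  if (nrow(exp_rows)) {
    recovery <- do.call(rbind, lapply(split(exp_rows, exp_rows$target_class),
      function(d) data.frame(
        class = d$target_class[1], n = nrow(d),
        recovered = sum(!is.na(d$fdr) & d$fdr < fdr & d$support >= 2 &
                          d$summary_log2fc < 0),
        stringsAsFactors = FALSE
      )))
    rownames(recovery) <- NULL
  }
  summaries <- list(
    tier_counts = tier_counts,
    n_significant = nrow(sig),
    n_high_medium = nrow(hm),
    degs_per_target = degs_per_target,
    distance_quantiles_nearest =
      dist_q(hm$distance_bp[hm$is_nearest_expressed_gene %in% TRUE]),
    distance_quantiles_other =
      dist_q(hm$distance_bp[hm$is_nearest_expressed_gene %in% FALSE]),
    nearest_gene_fraction = if (nrow(hm)) {
      mean(hm$is_nearest_expressed_gene, na.rm = TRUE)
    } else NA_real_,
    expected_gene_recovery = recovery
  )
  list(table = e2g, summaries = summaries)
}
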