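#' Group non-targeting guides into pseudo-targets
#'
#' Randomly partitions the non-targeting guides into disjoint groups of
#' `group_size`, emulating the guides-per-target structure of real
#' perturbations. Leftover guides (n mod group_size) are excluded rather
#' than recycled, keeping groups disjoint; 35 NT guides therefore yield 8
#' groups of 4 with 3 guides unused.
#'
#' @param nt_guides character vector of non-targeting guide ids.
#' @param group_size guides per pseudo-target.
#' @param seed integer seed.
#' @return data.frame with target_id (NTPSEUDO...), guide_id.
#' @export
build_nt_pseudo_targets <- function(nt_guides, group_size = 4, seed = 1) {
  if (length(nt_guides) < group_size) {
    stop("need at least ", group_size, " non-targeting guides")
  }
  n_groups <- length(nt_guides) %/% group_size
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  perm <- sample(nt_guides)
  used <- perm[seq_len(n_groups * group_size)]
  data.frame(
    target_id = rep(sprintf("NTPSEUDO%02d", seq_len(n_groups)),
                    each = group_size),
    guide_id = used,
    stringsAsFactors = FALSE
  )
}

#' Run the DE pipeline on non-targeting pseudo-targets
#'
#' Executes the identical guide-level testing stage on pseudo-targets
#' assembled from non-targeting guides. Since pseudo-targets have no
#' genomic position, each is tested against the union of window genes of
#' all real targets (every gene tested against any targeting guide). The
#' pseudo-target's own cells are excluded from the NT background for its
#' fits so no cell is used on both sides.
#'
#' @param pseudo_targets data.frame from [build_nt_pseudo_targets()].
#' @param counts,assignments,design,annotation,batch as in [de_test()].
#' @param backend,window,min_frac,nt_background_n,seed as in [de_test()].
#' @param max_genes optional cap on the size of the null gene universe
#'   (evenly subsampled) to bound runtime.
#' @return a `de_result` whose `results` hold the null guide-level
#'   p-values.
#' @export
run_null_screen <- function(pseudo_targets, counts, assignments, design,
                            annotation, batch,
                            backend = "hurdle", window = 1e6,
                            min_frac = 0.05, nt_background_n = 5000,
                            seed = 1, max_genes = NULL) {
  tested <- detection_filter(counts, min_frac)
  real <- design$targets[design$targets$class != "NT", , drop = FALSE]
  universe <- unique(unlist(lapply(seq_len(nrow(real)), function(i) {
    genes_in_window(real[i, ], annotation, window)
  })))
  universe <- intersect(universe, tested)
  if (!is.null(max_genes) && length(universe) > max_genes) {
    universe <- universe[unique(round(seq(1, length(universe),
                                          length.out = max_genes)))]
  }
  pd <- list(
    targets = data.frame(
      target_id = unique(pseudo_targets$target_id),
      class = "PSEUDO", chrom = NA_character_, start = NA_real_,
      end = NA_real_, expected_gene_id = NA_character_,
      stringsAsFactors = FALSE),
    guides = pseudo_targets
  )
  # keep the real design's NT guides as the background definition
  nt_targets <- design$targets[design$targets$class == "NT", , drop = FALSE]
  nt_guides <- design$guides[design$guides$target_id %in%
                               nt_targets$target_id, ]
  pd$targets <- rbind(pd$targets, nt_targets)
  pd$guides <- rbind(pd$guides, nt_guides[!duplicated(nt_guides$guide_id), ])
  de_test(counts, assignments, pd, annotation, batch, backend = backend,
          window = window, min_frac = min_frac,
          nt_background_n = nt_background_n, seed = seed,
          gene_universe = universe)
}

#' Calibration diagnostics for a null p-value set
#'
#' Summarizes how close a p-value vector is to the uniform null:
#' Kolmogorov-Smirnov statistic against U(0,1), an inflation factor
#' (median observed -log10 p over the median expected, i.e. -log10 0.5),
#' and empirical type-I rates at alpha 0.05 and 0.01.
#'
#' @param pvals numeric vector of p-values (NAs dropped); at least 100
#'   required.
#' @return list of class `calibration_report`: n, ks_statistic,
#'   inflation_factor, type1_at_05, type1_at_01, degenerate flag.
#' @export
qq_diagnostics <- function(pvals) {
  p <- pvals[!is.na(pvals)]
  if (length(p) < 100) stop("need at least 100 p-values")
  degenerate <- length(unique(p)) == 1
  if (degenerate) {
    warning("all p-values identical; calibration report is degenerate")
  }
  ks <- suppressWarnings(
    as.numeric(stats::ks.test(p, "punif")$statistic))
  infl <- stats::median(-log10(pmax(p, 1e-300))) / (-log10(0.5))
  structure(list(
    n = length(p),
    ks_statistic = ks,
    inflation_factor = infl,
    type1_at_05 = mean(p < 0.05),
    type1_at_01 = mean(p < 0.01),
    degenerate = degenerate
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "calibration: n=%d  KS=%.4f  inflation=%.3f  P(p<0.05)=%.4f  P(p<0.01)=%.4f\n",
    x$n, x$ks_statistic, x$inflation_factor, x$type1_at_05, x$type1_at_01))
  invisible(x)
}

#' Full calibration diagnostic from a screen
#'
#' Convenience wrapper: builds pseudo-targets from the design's NT guides,
#' runs the null screen through the identical DE entry point, and returns
#' the QQ diagnostics together with the null results.
#'
#' @inheritParams run_null_screen
#' @param group_size guides per pseudo-target.
#' @return list with `report` (a `calibration_report`), `null_de` (the
#'   `de_result`), `pseudo_targets`.
#' @export
calibrate_screen <- function(counts, assignments, design, annotation,
                             batch, group_size = 4, backend = "hurdle",
                             window = 1e6, min_frac = 0.05,
                             nt_background_n = 5000, seed = 1,
                             max_genes = NULL) {
  nt_ids <- design$targets$target_id[design$targets$class == "NT"]
  nt_guides <- design$guides$guide_id[design$guides$target_id %in% nt_ids]
  pseudo <- build_nt_pseudo_targets(nt_guides, group_size, seed)
  null_de <- run_null_screen(pseudo, counts, assignments, design,
                             annotation, batch, backend = backend,
                             window = window, min_frac = min_frac,
                             nt_background_n = nt_background_n,
                             seed = seed, max_genes = max_genes)
  list(report = qq_diagnostics(null_de$results$p_raw),
       null_de = null_de, pseudo_targets = pseudo)
}
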