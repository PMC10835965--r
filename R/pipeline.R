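#' Pipeline configuration
#'
#' A validated container mirroring every pipeline flag, serializable to a
#' YAML file that round-trips losslessly. Unknown keys are rejected.
#'
#' @param gene_counts,guide_counts directories of the two triplet
#'   matrices.
#' @param guide_library,targets_bed,annotation,batches input table paths
#'   (`batches` optional; single batch assumed when absent).
#' @param output_dir artifact directory.
#' @param alpha,umi_floor guide-assignment parameters.
#' @param n_mads QC threshold width.
#' @param min_frac detection filter.
#' @param window testing window flank (bp).
#' @param nt_background_n background size.
#' @param fdr significance threshold for target-level calls.
#' @param backend "hurdle" or "wilcoxon".
#' @param seed run seed.
#' @param drop_doublet_flagged remove heuristically flagged doublets.
#' @param calibrate also run the NT pseudo-target calibration.
#' @param calibration_group_size guides per pseudo-target.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_counts, guide_counts, guide_library,
                            targets_bed, annotation, batches = NULL,
                            output_dir = "cropqtl_out",
                            alpha = 0.001, umi_floor = 3, n_mads = 3,
                            min_frac = 0.05, window = 1e6,
                            nt_background_n = 5000, fdr = 0.05,
                            backend = "hurdle", seed = 1,
                            drop_doublet_flagged = FALSE,
                            calibrate = FALSE,
                            calibration_group_size = 4) {
  cfg <- as.list(environment())
  cfg$version <- as.character(utils::packageVersion("cropqtl"))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

config_fields <- function() {
  c("gene_counts", "guide_counts", "guide_library", "targets_bed",
    "annotation", "batches", "output_dir", "alpha", "umi_floor", "n_mads",
    "min_frac", "window", "nt_background_n", "fdr", "backend", "seed",
    "drop_doublet_flagged", "calibrate", "calibration_group_size",
    "version")
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_fields())
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(c("gene_counts", "guide_counts", "guide_library",
                       "targets_bed", "annotation"), names(cfg))
  if (length(missing)) {
    stop("config missing required path(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$umi_floor >= 0,
            cfg$n_mads >= 0, cfg$min_frac > 0, cfg$min_frac < 1,
            cfg$window >= 0, cfg$nt_background_n >= 1,
            cfg$fdr > 0, cfg$fdr < 1,
            cfg$backend %in% c("hurdle", "wilcoxon"))
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML config path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- formals(pipeline_config)
  for (k in setdiff(names(defaults), c(names(cfg), ""))) {
    v <- defaults[[k]]
    if (!is.symbol(v)) cfg[[k]] <- eval(v)
  }
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes QC -> guide assignment -> per-guide DE -> target aggregation
#' (and optionally NT calibration) from a configuration, writing every
#' artifact as TSV/JSON plus a manifest with versions, seeds and input
#' checksums. Each stage error aborts with a stage-named message.
#'
#' @param cfg a `pipeline_config` or path to a YAML config file.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  for (p in c(cfg$gene_counts, cfg$guide_counts, cfg$guide_library,
              cfg$targets_bed, cfg$annotation, cfg$batches)) {
    if (!is.null(p) && !file.exists(p)) stop("config: input not found: ", p)
  }
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  gene_counts <- stage("read", read_matrix_triplet(cfg$gene_counts))
  guide_counts <- stage("read", read_matrix_triplet(cfg$guide_counts))
  library <- stage("read", read_guide_library(cfg$guide_library))
  targets <- stage("read", read_targets_bed(cfg$targets_bed))
  annotation <- stage("read", read_gene_annotation(cfg$annotation))
  batch <- if (!is.null(cfg$batches)) {
    b <- utils::read.table(cfg$batches, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    stats::setNames(b$batch, b$cell_id)
  } else {
    stats::setNames(rep("E1", ncol(gene_counts)), colnames(gene_counts))
  }
  design <- .design_from_tables(targets, library, annotation)

  # --- QC ----------------------------------------------------------------
  metrics <- stage("qc", compute_qc_metrics(
    gene_counts, batch = batch[colnames(gene_counts)]))
  filt <- stage("qc", filter_cells(metrics, n_mads = cfg$n_mads))
  kept <- names(filt$keep)[filt$keep]
  # --- assignment --------------------------------------------------------
  assignments <- stage("assign", assign_guides(
    guide_counts[, intersect(colnames(guide_counts), kept), drop = FALSE],
    library, alpha = cfg$alpha, umi_floor = cfg$umi_floor))
  doublet_flag <- stage("qc", flag_doublet_like(
    assignments, metrics[metrics$cell_id %in% kept, ]))
  metrics$keep <- filt$keep[metrics$cell_id]
  metrics$doublet_flag <- FALSE
  metrics$doublet_flag[match(names(doublet_flag), metrics$cell_id)] <-
    doublet_flag
  if (isTRUE(cfg$drop_doublet_flagged)) {
    kept <- setdiff(kept, names(doublet_flag)[doublet_flag])
  }
  counts_qc <- gene_counts[, kept, drop = FALSE]
  # --- DE ----------------------------------------------------------------
  de <- stage("test", de_test(
    counts_qc, assignments, design, annotation, batch,
    backend = cfg$backend, window = cfg$window, min_frac = cfg$min_frac,
    nt_background_n = cfg$nt_background_n, seed = cfg$seed))
  # --- aggregation -------------------------------------------------------
  e2g <- stage("aggregate", aggregate_targets(de, fdr = cfg$fdr))
  e2g_full <- stage("aggregate", build_e2g_table(
    e2g, design, annotation, de$tested_genes, fdr = cfg$fdr))
  # --- calibration (optional) -------------------------------------------
  calib <- NULL
  if (isTRUE(cfg$calibrate)) {
    calib <- stage("calibrate", calibrate_screen(
      counts_qc, assignments, design, annotation, batch,
      group_size = cfg$calibration_group_size, backend = cfg$backend,
      window = cfg$window, min_frac = cfg$min_frac,
      nt_background_n = cfg$nt_background_n, seed = cfg$seed))
  }
  # --- artifacts ---------------------------------------------------------
  paths <- c(
    qc = file.path(out, "qc_metrics.tsv"),
    qc_thresholds = file.path(out, "qc_thresholds.tsv"),
    assignment = file.path(out, "assignments.tsv"),
    cell_classes = file.path(out, "cell_classes.tsv"),
    de = file.path(out, "de_results.tsv"),
    e2g = file.path(out, "e2g_table.tsv"),
    summary = file.path(out, "summary.json")
  )
  write_tsv_report(metrics, paths[["qc"]])
  write_tsv_report(filt$thresholds, paths[["qc_thresholds"]])
  write_tsv_report(assignments$table, paths[["assignment"]])
  write_tsv_report(assignments$cells, paths[["cell_classes"]])
  write_tsv_report(de$results, paths[["de"]])
  write_tsv_report(e2g_full$table, paths[["e2g"]])
  write_json_report(c(
    e2g_full$summaries,
    list(n_cells_input = ncol(gene_counts),
         n_cells_qc = length(kept),
         n_tested_genes = length(de$tested_genes),
         n_de_tests = nrow(de$results),
         assignment_classes = classify_cells(assignments))
  ), paths[["summary"]])
  if (!is.null(calib)) {
    paths[["calibration"]] <- file.path(out, "calibration.json")
    write_json_report(unclass(calib$report), paths[["calibration"]])
    paths[["calibration_pvals"]] <- file.path(out, "calibration_pvals.tsv")
    write_tsv_report(calib$null_de$results, paths[["calibration_pvals"]])
  }
  manifest_path <- file.path(out, "manifest.json")
  write_manifest(
    inputs = c(file.path(cfg$gene_counts, "matrix.mtx"),
               file.path(cfg$guide_counts, "matrix.mtx"),
               cfg$guide_library, cfg$targets_bed, cfg$annotation,
               if (!is.null(cfg$batches)) cfg$batches),
    artifacts = paths,
    seeds = list(run = cfg$seed),
    counts = list(cells_input = ncol(gene_counts),
                  cells_qc = length(kept),
                  tested_genes = length(de$tested_genes),
                  de_tests = nrow(de$results),
                  e2g_pairs = nrow(e2g_full$table)),
    path = manifest_path
  )
  invisible(list(config = cfg, metrics = metrics, assignments = assignments,
                 de = de, e2g = e2g_full, calibration = calib,
                 artifacts = c(paths, manifest = manifest_path)))
}

# reconstruct a minimal design object from on-disk tables
.design_from_tables <- function(targets, library, annotation) {
  lib_targets <- unique(library$target_id)
  nt_ids <- setdiff(lib_targets, targets$target_id)
  tt <- rbind(
    data.frame(target_id = targets$target_id, class = targets$class,
               chrom = targets$chrom, start = targets$start,
               end = targets$end,
               expected_gene_id = NA_character_,
               stringsAsFactors = FALSE),
    if (length(nt_ids)) data.frame(
      target_id = nt_ids, class = "NT", chrom = NA_character_,
      start = NA_real_, end = NA_real_,
      expected_gene_id = NA_character_, stringsAsFactors = FALSE)
  )
  list(targets = tt,
       guides = data.frame(guide_id = library$guide_id,
                           target_id = library$target_id,
                           stringsAsFactors = FALSE))
}

#' Analyze a screen in memory
#'
#' Convenience wrapper used for simulated screens: runs QC, guide
#' assignment, per-guide DE and target aggregation on a `crop_screen`
#' without touching disk. Identical stage functions and defaults as
#' [run_pipeline()].
#'
#' @param screen a `crop_screen`.
#' @param backend,window,min_frac,nt_background_n,fdr,alpha,umi_floor,n_mads
#'   stage parameters as in [pipeline_config()].
#' @param seed seed for background sampling.
#' @param drop_doublet_flagged remove heuristically flagged doublets
#'   before DE.
#' @return list with `metrics`, `qc`, `assignments`, `de`, `e2g` (the
#'   annotated table + summaries), `kept_cells`.
#' @export
analyze_screen <- function(screen, backend = "hurdle", window = 1e6,
                           min_frac = 0.05, nt_background_n = 5000,
                           fdr = 0.05, alpha = 0.001, umi_floor = 3,
                           n_mads = 3, seed = 1,
                           drop_doublet_flagged = FALSE) {
  metrics <- compute_qc_metrics(screen$gene_counts, batch = screen$batch)
  filt <- filter_cells(metrics, n_mads = n_mads)
  kept <- names(filt$keep)[filt$keep]
  assignments <- assign_guides(screen$guide_counts[, kept, drop = FALSE],
                               screen$library, alpha = alpha,
                               umi_floor = umi_floor)
  if (drop_doublet_flagged) {
    dbl <- flag_doublet_like(assignments,
                             metrics[metrics$cell_id %in% kept, ])
    kept <- setdiff(kept, names(dbl)[dbl])
    assignments <- assign_guides(
      screen$guide_counts[, kept, drop = FALSE], screen$library,
      alpha = alpha, umi_floor = umi_floor)
  }
  de <- de_test(screen$gene_counts[, kept, drop = FALSE], assignments,
                screen$design, screen$annotation, screen$batch,
                backend = backend, window = window, min_frac = min_frac,
                nt_background_n = nt_background_n, seed = seed)
  e2g <- aggregate_targets(de, fdr = fdr)
  e2g_full <- build_e2g_table(e2g, screen$design, screen$annotation,
                              de$tested_genes, fdr = fdr)
  list(metrics = metrics, qc = filt, assignments = assignments, de = de,
       e2g = e2g_full, kept_cells = kept)
}
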