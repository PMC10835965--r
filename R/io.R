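#' Read a 10X-style triplet count matrix
#'
#' Reads a MatrixMarket coordinate file with its barcode and feature
#' tables (the cellranger output layout: matrix.mtx, barcodes.tsv,
#' features.tsv, optionally gzipped). Counts must be nonnegative integers;
#' duplicate barcodes or features, or dimension mismatches, are errors.
#'
#' @param dir directory holding matrix.mtx[.gz], barcodes.tsv[.gz] and
#'   features.tsv[.gz]; alternatively supply the three paths explicitly.
#' @param matrix_path,barcodes_path,features_path explicit file paths
#'   (override `dir`).
#' @return sparse `dgCMatrix`, features x cells, with dimnames.
#' @export
read_matrix_triplet <- function(dir = NULL, matrix_path = NULL,
                                barcodes_path = NULL, features_path = NULL) {
  pick <- function(path, base) {
    if (!is.null(path)) return(path)
    for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("cannot find ", base, " under ", dir)
  }
  mp <- pick(matrix_path, "matrix.mtx")
  bp <- pick(barcodes_path, "barcodes.tsv")
  fp <- pick(features_path, "features.tsv")
  m <- tryCatch(Matrix::readMM(mp), error = function(e) {
    stop("failed to parse MatrixMarket file ", mp, ": ",
         conditionMessage(e))
  })
  barcodes <- readLines(bp)
  features_tab <- utils::read.table(fp, sep = "\t", header = FALSE,
                                    colClasses = "character", quote = "")
  features <- features_tab[[1]]
  if (nrow(m) != length(features)) {
    stop("matrix has ", nrow(m), " rows but ", length(features),
         " features")
  }
  if (ncol(m) != length(barcodes)) {
    stop("matrix has ", ncol(m), " columns but ", length(barcodes),
         " barcodes")
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in ", bp)
  if (anyDuplicated(features)) stop("duplicate features in ", fp)
  if (anyNA(m@x)) {
    stop("truncated or malformed entries in MatrixMarket file ", mp)
  }
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop("matrix contains negative or non-integer entries")
  }
  dimnames(m) <- list(features, barcodes)
  methods::as(m, "CsparseMatrix")
}

#' Write a 10X-style triplet count matrix
#'
#' @param m features x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @param gzip compress the three files.
#' @return invisibly, the directory.
#' @export
write_matrix_triplet <- function(m, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  mp <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), mp)
  if (gzip) {
    .gzip_file(mp)
  }
  con <- function(f) if (gzip) gzfile(f) else file(f)
  writeLines(colnames(m), con(file.path(dir, paste0("barcodes.tsv", ext))))
  writeLines(rownames(m), con(file.path(dir, paste0("features.tsv", ext))))
  invisible(dir)
}

.gzip_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  gz <- gzfile(paste0(path, ".gz"), "wb")
  writeBin(raw, gz)
  close(gz)
  unlink(path)
}

#' Read/write target intervals as 6-column BED
#'
#' BED uses 0-based half-open coordinates, matching the package's internal
#' convention. Column 4 is the target id, column 5 the class label, column
#' 6 the (unused) strand. Non-targeting entries are not written (they have
#' no interval).
#'
#' @param path BED file path.
#' @return data.frame target_id, class, chrom, start, end.
#' @export
read_targets_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         colClasses = c("character", "numeric", "numeric",
                                        "character", "character",
                                        "character"))
  if (ncol(d) != 6) stop("expected 6 BED columns, found ", ncol(d))
  if (any(d[[2]] >= d[[3]])) stop("BED intervals must satisfy start < end")
  if (any(d[[2]] < 0)) stop("BED start must be >= 0")
  data.frame(target_id = d[[4]], class = d[[5]], chrom = d[[1]],
             start = d[[2]], end = d[[3]], stringsAsFactors = FALSE)
}

#' @rdname read_targets_bed
#' @param targets data.frame with target_id, class, chrom, start, end.
#' @export
write_targets_bed <- function(targets, path) {
  t <- targets[!is.na(targets$start), , drop = FALSE]
  utils::write.table(
    data.frame(t$chrom, format(t$start, scientific = FALSE, trim = TRUE),
               format(t$end, scientific = FALSE, trim = TRUE),
               t$target_id, t$class, "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write gene annotation
#'
#' Tab-separated with header: gene_id, chrom, tss (1-based in the file,
#' converted to 0-based internally), strand (+/-). The TSS is the
#' annotated transcription start itself — for minus-strand genes this is
#' the downstream-most coordinate, not the interval minimum.
#'
#' @param path annotation TSV path.
#' @return data.frame gene_id, chrom, tss (0-based), strand.
#' @export
read_gene_annotation <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(d))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(d$tss < 1)) stop("file TSS coordinates are 1-based; found < 1")
  d$tss <- d$tss - 1
  d[, need]
}

#' @rdname read_gene_annotation
#' @param annotation data.frame with gene_id, chrom, tss (0-based), strand.
#' @export
write_gene_annotation <- function(annotation, path) {
  out <- annotation[, c("gene_id", "chrom", "tss", "strand")]
  out$tss <- format(out$tss + 1, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write the guide library table
#'
#' Tab-separated with header: guide_id, target_id, plasmid_count;
#' proportions are recomputed on read so they always sum to 1.
#'
#' @param path library TSV path.
#' @param design optional `screen_design` used to validate guide ids.
#' @return a `guide_library` data.frame (guide_id, target_id,
#'   plasmid_count, proportion).
#' @export
read_guide_library <- function(path, design = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         stringsAsFactors = FALSE)
  need <- c("guide_id", "plasmid_count")
  if (!all(need %in% names(d))) {
    stop("library must have columns: ", paste(need, collapse = ", "))
  }
  if (any(d$plasmid_count < 0)) stop("plasmid counts must be nonnegative")
  if (!is.null(design) && !setequal(d$guide_id, design$guides$guide_id)) {
    stop("library guides do not match the design")
  }
  d$proportion <- d$plasmid_count / sum(d$plasmid_count)
  class(d) <- c("guide_library", "data.frame")
  d
}

#' @rdname read_guide_library
#' @param library a `guide_library`; a target_id column is added from
#'   `design` when available.
#' @export
write_guide_library <- function(library, path, design = NULL) {
  out <- as.data.frame(library)
  if (!"target_id" %in% names(out) && !is.null(design)) {
    out$target_id <- design$guides$target_id[
      match(out$guide_id, design$guides$guide_id)]
  }
  keep <- intersect(c("guide_id", "target_id", "plasmid_count"), names(out))
  utils::write.table(out[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated screen to disk
#'
#' Emits the standard layout: gene and guide matrices in 10X triplet
#' format, guide library TSV, targets BED, gene annotation TSV, per-cell
#' batch TSV, and the ground truth TSV (per-cell integrations, doublet
#' flags; per-target planted effects).
#'
#' @param screen a `crop_screen`.
#' @param dir output directory.
#' @param gzip compress matrix files.
#' @return invisibly, a character vector of written paths.
#' @export
write_screen <- function(screen, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_triplet(screen$gene_counts, file.path(dir, "gene_counts"),
                       gzip)
  write_matrix_triplet(screen$guide_counts, file.path(dir, "guide_counts"),
                       gzip)
  write_guide_library(screen$library, file.path(dir, "guide_library.tsv"),
                      screen$design)
  write_targets_bed(screen$design$targets, file.path(dir, "targets.bed"))
  write_gene_annotation(screen$annotation, file.path(dir, "genes.tsv"))
  utils::write.table(
    data.frame(cell_id = names(screen$batch), batch = unname(screen$batch)),
    file.path(dir, "batches.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- screen$truth
  utils::write.table(
    data.frame(cell_id = truth$cell_id,
               integrations = vapply(truth$integrations, paste, "",
                                     collapse = ","),
               batch = truth$batch, doublet = truth$doublet),
    file.path(dir, "truth_cells.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(truth$effects, file.path(dir, "truth_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list.files(dir, recursive = TRUE, full.names = TRUE))
}

#' Read a per-cell ground-truth table written by [write_screen()]
#' @param path truth_cells.tsv path.
#' @return data.frame cell_id, integrations (comma-separated), batch,
#'   doublet.
#' @export
read_truth_cells <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "logical"))
}

#' Write pipeline report tables
#'
#' Writers with stable column order for every tabular artifact; empty
#' tables produce header-only files.
#'
#' @param x data.frame to write.
#' @param path output TSV path.
#' @export
write_tsv_report <- function(x, path) {
  drop <- vapply(x, is.list, TRUE)
  utils::write.table(x[, !drop, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv_report
#' @param summaries a list of summary statistics (JSON-serializable).
#' @export
write_json_report <- function(summaries, path) {
  jsonlite::write_json(summaries, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Manifest of a pipeline run
#'
#' Records package version, seeds, per-stage counts and md5 checksums of
#' all inputs and artifacts, so a run is fully identified by its manifest.
#'
#' @param inputs,artifacts named character vectors of file paths.
#' @param seeds named list of seeds used.
#' @param counts named list of per-stage counts.
#' @param path output JSON path.
#' @export
write_manifest <- function(inputs, artifacts, seeds, counts, path) {
  checksum <- function(paths) {
    ex <- paths[file.exists(paths)]
    as.list(tools::md5sum(ex))
  }
  write_json_report(list(
    package = "cropqtl",
    version = as.character(utils::packageVersion("cropqtl")),
    seeds = seeds,
    counts = counts,
    inputs = checksum(inputs),
    artifacts = checksum(artifacts)
  ), path)
}
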