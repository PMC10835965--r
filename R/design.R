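#' Toy genome specification
#'
#' Builds a deterministic toy genome used by the synthetic screen generator:
#' one or more chromosomes with uniformly spaced gene transcription start
#' sites, plus a small mitochondrial contig. Uniform spacing guarantees that
#' every simulated target has genes both inside and outside its testing
#' window. All internal coordinates are 0-based.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param gene_spacing distance in bp between consecutive gene TSSs.
#' @param n_mito number of mitochondrial genes placed on contig "chrM".
#' @return list of class `toy_genome` with elements `chroms` (data.frame of
#'   chrom, length), `genes` (data.frame of gene_id, chrom, tss, strand) and
#'   `gene_spacing`. Mitochondrial gene ids carry the conventional "MT-"
#'   prefix so they can be selected for QC metrics.
#' @export
toy_genome <- function(chrom_lengths = c(chr1 = 250e6),
                       gene_spacing = 50e3,
                       n_mito = 13) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            gene_spacing > 0)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  genes <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    tss <- seq(from = round(gene_spacing / 2), to = len - 1, by = gene_spacing)
    data.frame(chrom = ch, tss = as.numeric(tss), stringsAsFactors = FALSE)
  }))
  genes$strand <- rep_len(c("+", "-"), nrow(genes))
  genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
  if (n_mito > 0) {
    mito <- data.frame(
      chrom = "chrM",
      tss = as.numeric(seq(100, by = 1000, length.out = n_mito)),
      strand = "+",
      gene_id = sprintf("MT-G%02d", seq_len(n_mito)),
      stringsAsFactors = FALSE
    )
    genes <- rbind(genes, mito)
  }
  genes <- genes[, c("gene_id", "chrom", "tss", "strand")]
  structure(
    list(chroms = data.frame(chrom = names(chrom_lengths),
                             length = as.numeric(chrom_lengths),
                             stringsAsFactors = FALSE),
         genes = genes,
         gene_spacing = gene_spacing),
    class = "toy_genome"
  )
}

#' Default class composition of the screen library
#'
#' 35 TSS positive controls, 28 previously reported enhancer-gene pairs,
#' 11 intronic and 3 intergenic candidate cis-regulatory elements and
#' 3 locus-control-region elements: 80 targets in total, 45 of them
#' non-coding.
#' @export
default_class_counts <- function() {
  c(TSS = 35, ENH = 28, CCRE_INTRONIC = 11, CCRE_INTERGENIC = 3, LCR = 3)
}

target_classes <- function() {
  c("TSS", "ENH", "CCRE_INTRONIC", "CCRE_INTERGENIC", "LCR", "NT")
}

#' Build a screen design
#'
#' Lays out perturbation targets on a toy genome and attaches guides. Each
#' non-NT target receives `guides_per_target` guides and an expected gene
#' whose TSS lies within 1 Mb of the target. TSS-class targets sit on their
#' expected gene's TSS; non-coding targets are offset from it by a distance
#' drawn from a short-range/long-range mixture so that most (but not all)
#' targets regulate their nearest gene, as observed in element-to-gene
#' screens. Non-targeting (NT) guides have no genomic interval.
#'
#' @param class_counts named integer vector, number of targets per class
#'   (classes among TSS, ENH, CCRE_INTRONIC, CCRE_INTERGENIC, LCR).
#' @param guides_per_target number of guides per (non-NT) target.
#' @param n_nt number of non-targeting control guides.
#' @param genome a [toy_genome()].
#' @param seed integer seed controlling target placement.
#' @return object of class `screen_design`: list with `targets` (data.frame
#'   target_id, class, chrom, start, end, expected_gene_id), `guides`
#'   (data.frame guide_id, target_id), `guides_per_target`, `n_nt`,
#'   `genome`.
#' @export
build_design <- function(class_counts = default_class_counts(),
                         guides_per_target = 4,
                         n_nt = 35,
                         genome = toy_genome(),
                         seed = 1) {
  class_counts <- class_counts[class_counts > 0]
  stopifnot(all(class_counts >= 0), guides_per_target >= 1, n_nt >= 0)
  if (length(class_counts) &&
      !all(names(class_counts) %in% setdiff(target_classes(), "NT"))) {
    stop("unknown target class in class_counts")
  }
  n_targets <- sum(class_counts)
  nuclear <- genome$genes[!startsWith(genome$genes$gene_id, "MT-"), ]
  # placement uses the longest chromosome; targets evenly spread
  ch <- genome$chroms$chrom[which.max(genome$chroms$length)]
  len <- max(genome$chroms$length)
  if (n_targets > 0) {
    spacing <- floor(len / (n_targets + 1))
    if (spacing < 2e6 + genome$gene_spacing) {
      stop("genome too small to place ", n_targets,
           " targets with non-overlapping 1 Mb windows")
    }
    ch_genes <- nuclear[nuclear$chrom == ch, ]
    centers <- spacing * seq_len(n_targets)
    withr_seed <- .with_seed(seed)
    on.exit(withr_seed(), add = TRUE)
    classes <- sample(rep(names(class_counts), times = class_counts))
    # anchor each target to the gene nearest its nominal center
    anchor_idx <- vapply(centers, function(x) which.min(abs(ch_genes$tss - x)),
                         integer(1))
    anchors <- ch_genes[anchor_idx, ]
    # non-coding elements: 70% proximal (5-25 kb), 30% distal (135-715 kb)
    offset <- numeric(n_targets)
    noncoding <- classes != "TSS"
    n_nc <- sum(noncoding)
    if (n_nc > 0) {
      distal <- stats::runif(n_nc) < 0.3
      d <- ifelse(distal,
                  stats::runif(n_nc, 135e3, 715e3),
                  stats::runif(n_nc, 5e3, 25e3))
      offset[noncoding] <- round(d) * sample(c(-1, 1), n_nc, replace = TRUE)
    }
    mid <- anchors$tss + offset
    width <- ifelse(classes == "TSS", 300, 300)
    start <- pmax(0, round(mid - width / 2))
    end <- pmin(len, start + width)
    targets <- data.frame(
      target_id = sprintf("T%03d", seq_len(n_targets)),
      class = classes,
      chrom = ch,
      start = start,
      end = end,
      expected_gene_id = anchors$gene_id,
      stringsAsFactors = FALSE
    )
  } else {
    targets <- data.frame(target_id = character(), class = character(),
                          chrom = character(), start = numeric(),
                          end = numeric(), expected_gene_id = character(),
                          stringsAsFactors = FALSE)
  }
  if (n_nt > 0) {
    nt <- data.frame(
      target_id = sprintf("NT%03d", seq_len(n_nt)),
      class = "NT", chrom = NA_character_,
      start = NA_real_, end = NA_real_,
      expected_gene_id = NA_character_,
      stringsAsFactors = FALSE
    )
    targets <- rbind(targets, nt)
  }
  g_t <- targets$target_id[targets$class != "NT"]
  guides <- data.frame(
    guide_id = c(
      if (length(g_t)) paste0(rep(g_t, each = guides_per_target), "_g",
                              rep(seq_len(guides_per_target), length(g_t))),
      if (n_nt > 0) paste0(targets$target_id[targets$class == "NT"], "_g1")
    ),
    target_id = c(rep(g_t, each = guides_per_target),
                  targets$target_id[targets$class == "NT"]),
    stringsAsFactors = FALSE
  )
  design <- structure(
    list(targets = targets, guides = guides,
         guides_per_target = guides_per_target, n_nt = n_nt,
         genome = genome),
    class = "screen_design"
  )
  validate_design(design)
  design
}

validate_design <- function(design) {
  t <- design$targets
  g <- design$guides
  if (anyDuplicated(g$guide_id)) stop("guide ids are not unique")
  non_nt <- t$target_id[t$class != "NT"]
  if (length(non_nt)) {
    per <- table(g$target_id[g$target_id %in% non_nt])
    if (!all(per == design$guides_per_target)) {
      stop("every non-NT target must have exactly ",
           design$guides_per_target, " guides")
    }
    iv <- t[t$class != "NT", ]
    if (any(!(iv$start >= 0 & iv$start < iv$end))) {
      stop("target intervals must satisfy 0 <= start < end")
    }
  }
  invisible(design)
}

#' Number of guides / targets in a design
#' @param design a `screen_design`.
#' @export
n_guides <- function(design) nrow(design$guides)

#' @rdname n_guides
#' @export
n_targets <- function(design) sum(design$targets$class != "NT")

#' Simulate a plasmid guide library
#'
#' Draws per-guide plasmid abundances from a lognormal distribution (the
#' shape seen in sequencing of cloned pooled libraries) and converts them to
#' read counts at a fixed sequencing depth. Expected per-guide proportions
#' are the normalized counts.
#'
#' @param design a `screen_design`.
#' @param lognormal_sigma spread of log-abundances; 0 gives an exactly
#'   uniform library.
#' @param seed integer seed.
#' @param depth total plasmid read count to distribute.
#' @return object of class `guide_library`: data.frame with `guide_id`,
#'   `plasmid_count`, `proportion` (summing to 1).
#' @export
simulate_plasmid_library <- function(design, lognormal_sigma = 0.5, seed = 1,
                                     depth = 1e6) {
  stopifnot(lognormal_sigma >= 0, depth > 0)
  n <- n_guides(design)
  if (n == 0) stop("design has no guides")
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  w <- if (lognormal_sigma == 0) rep(1, n) else
    stats::rlnorm(n, meanlog = 0, sdlog = lognormal_sigma)
  counts <- pmax(1L, as.integer(round(w / sum(w) * depth)))
  lib <- data.frame(guide_id = design$guides$guide_id,
                    plasmid_count = counts,
                    proportion = counts / sum(counts),
                    stringsAsFactors = FALSE)
  class(lib) <- c("guide_library", "data.frame")
  lib
}

# run code under a local RNG state and restore afterwards
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
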