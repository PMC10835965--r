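#' Simulation parameters for a synthetic CROP-seq screen
#'
#' Bundles every tunable of the generator with defaults chosen to emulate a
#' low-MOI pooled CRISPRi screen in primary T cells: Poisson transduction
#' below 0.3 integrations per cell, plasmid-proportional ambient guide
#' noise, negative-binomial gene expression with class-specific mean
#' knockdowns (0.31 at promoters, 0.20 at enhancer-class elements, 0.29 at
#' locus-control regions), two experiments (batches) of unequal size, and
#' per-cell QC covariates.
#'
#' @param n_cells number of profiled cells emitted by the screen.
#' @param moi Poisson mean of lentiviral integrations per cell.
#' @param ambient_rate expected fraction of a cell's guide-library UMIs that
#'   are ambient (drawn from plasmid proportions irrespective of infection).
#' @param guide_umi_mean mean UMI count of a truly present guide at capture
#'   factor 1.
#' @param capture_sdlog lognormal sd of the per-cell guide capture factor.
#' @param n_genes optional cap on the number of nuclear genes simulated
#'   (evenly subsampled from the genome); NULL uses all genes.
#' @param nb_meanlog,nb_sdlog lognormal parameters of baseline per-gene mean
#'   UMIs per cell.
#' @param nb_dispersion negative-binomial size parameter (theta).
#' @param expected_gene_mean_range baseline mean UMI range for the expected
#'   genes of targets, sampled log-uniformly so effects span the dynamic
#'   range of expression.
#' @param knockdown_by_class named vector of mean fractional knockdowns per
#'   target class.
#' @param knockdown_concentration concentration of an optional Beta spread
#'   around each class mean for per-target true effects; the default (Inf)
#'   plants exactly the class-mean effect at every target, leaving
#'   per-guide efficiency as the sole source of effect variability.
#' @param guide_eff_shape1,guide_eff_shape2 Beta parameters of per-guide
#'   efficiency (default mean 5/6).
#' @param n_batches,batch_props number of experiments and their cell
#'   proportions.
#' @param batch_effect_scale sd of per-gene log batch effects.
#' @param expr_sdlog lognormal sd of the per-cell expression size factor.
#' @param mito_mean_by_batch mean mitochondrial fraction per batch.
#' @param mito_concentration Beta concentration of mitochondrial fractions.
#' @param stripped_rate fraction of stripped-nuclei cells (near-zero
#'   mitochondrial fraction, reduced gene counts).
#' @param doublet_rate fraction of emitted cells that are doublets (sums of
#'   two cells' columns).
#' @param select_transduced if TRUE (screen default), emulate puromycin
#'   selection: profiled cells are drawn from the transduced (>= 1
#'   integration) fraction of the infection pool.
#' @param seed integer seed for all randomness.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 135000,
                       moi = 0.3,
                       ambient_rate = 0.05,
                       guide_umi_mean = 25,
                       capture_sdlog = 0.3,
                       n_genes = 2500,
                       nb_meanlog = -2.3,
                       nb_sdlog = 1.5,
                       nb_dispersion = 2,
                       expected_gene_mean_range = c(0.1, 20),
                       knockdown_by_class = c(TSS = 0.31, ENH = 0.20,
                                              CCRE_INTRONIC = 0.20,
                                              CCRE_INTERGENIC = 0.20,
                                              LCR = 0.29),
                       knockdown_concentration = Inf,
                       guide_eff_shape1 = 5,
                       guide_eff_shape2 = 1,
                       n_batches = 2,
                       batch_props = c(0.2, 0.8),
                       batch_effect_scale = 0.1,
                       expr_sdlog = 0.3,
                       mito_mean_by_batch = c(0.06, 0.08),
                       mito_concentration = 60,
                       stripped_rate = 0.01,
                       doublet_rate = 0.05,
                       select_transduced = TRUE,
                       seed = 1) {
  p <- as.list(environment())
  stopifnot(p$n_cells >= 1, p$moi >= 0,
            p$ambient_rate >= 0, p$ambient_rate < 1,
            all(p$knockdown_by_class >= 0), all(p$knockdown_by_class <= 1),
            p$nb_dispersion > 0, p$doublet_rate >= 0, p$doublet_rate < 0.5,
            p$stripped_rate >= 0, p$stripped_rate < 1,
            length(p$batch_props) == p$n_batches,
            abs(sum(p$batch_props) - 1) < 1e-8)
  class(p) <- "sim_params"
  p
}

#' Simulate lentiviral integrations at low MOI
#'
#' Each cell receives a Poisson(`moi`) number of integrations; guide
#' identities are drawn proportionally to plasmid-library abundance,
#' without replacement within a cell.
#'
#' @param design a `screen_design`.
#' @param library a `guide_library`.
#' @param n_cells number of cells.
#' @param moi Poisson mean integrations per cell.
#' @param seed integer seed.
#' @return list of class `ground_truth` (partial): `cell_id`,
#'   `integrations` (list of guide-id character vectors per cell), `batch`
#'   and `doublet` placeholders.
#' @export
simulate_infections <- function(design, library, n_cells, moi, seed = 1) {
  stopifnot(moi >= 0, n_cells >= 0)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  k <- stats::rpois(n_cells, moi)
  k <- pmin(k, n_guides(design))
  integrations <- .draw_guides(k, library)
  structure(
    list(cell_id = sprintf("CELL%07d", seq_len(n_cells)),
         integrations = integrations,
         batch = rep(NA_character_, n_cells),
         doublet = rep(FALSE, n_cells)),
    class = "ground_truth"
  )
}

# sample guide identities without replacement per cell, proportional to p_g
.draw_guides <- function(k, library) {
  ids <- library$guide_id
  p <- library$proportion
  lapply(k, function(ki) {
    if (ki == 0) character(0) else sample(ids, ki, replace = FALSE, prob = p)
  })
}

#' Simulate the guide-library UMI matrix
#'
#' Truly present guides receive Poisson counts with mean `guide_umi_mean`
#' scaled by a lognormal per-cell capture factor (cell-to-cell recovery
#' bias); every cell additionally receives ambient UMIs whose total is
#' Poisson with mean `capture * guide_umi_mean * ambient_rate /
#' (1 - ambient_rate)` and whose identities follow the plasmid proportions.
#'
#' @param truth a `ground_truth` covering all cells.
#' @param library a `guide_library`.
#' @param params a `sim_params`.
#' @param seed integer seed.
#' @return sparse `dgCMatrix`, guides x cells, with dimnames.
#' @export
simulate_guide_counts <- function(truth, library, params, seed = 1) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  n <- length(truth$cell_id)
  ng <- nrow(library)
  capture <- stats::rlnorm(n, 0, params$capture_sdlog)
  gidx <- seq_len(ng)
  names(gidx) <- library$guide_id
  # true integrations
  ki <- lengths(truth$integrations)
  cells_i <- rep.int(seq_len(n), ki)
  guide_i <- gidx[unlist(truth$integrations, use.names = FALSE)]
  x_true <- stats::rpois(length(cells_i),
                         params$guide_umi_mean * capture[cells_i])
  # ambient UMIs: total per cell, multinomial identities by p_g
  ar <- params$ambient_rate
  if (ar > 0) {
    amb_tot <- stats::rpois(n, capture * params$guide_umi_mean * ar / (1 - ar))
    amb_cells <- rep.int(seq_len(n), amb_tot)
    amb_guides <- sample.int(ng, length(amb_cells), replace = TRUE,
                             prob = library$proportion)
    cells_i <- c(cells_i, amb_cells)
    guide_i <- c(guide_i, amb_guides)
    x_true <- c(x_true, rep.int(1L, length(amb_cells)))
  }
  keep <- x_true > 0
  m <- Matrix::sparseMatrix(
    i = guide_i[keep], j = cells_i[keep], x = as.numeric(x_true[keep]),
    dims = c(ng, n),
    dimnames = list(library$guide_id, truth$cell_id)
  )
  methods::as(m, "CsparseMatrix")
}

#' Simulate the gene-expression UMI matrix
#'
#' Baseline counts are negative binomial with per-gene lognormal means,
#' per-cell lognormal size factors and per-gene multiplicative batch
#' effects. For a cell carrying a guide of target t, the expected gene's
#' mean is multiplied by (1 - effect_t * guide_efficiency). Mitochondrial
#' counts are added from per-cell Beta mitochondrial fractions
#' (batch-specific means), with a configurable tail of "stripped nuclei"
#' cells with near-zero mitochondrial fraction and thinned gene counts.
#'
#' @param design a `screen_design`.
#' @param truth a `ground_truth` with batches assigned (see
#'   [simulate_screen()]); effects/efficiencies are drawn here and recorded
#'   into the returned truth.
#' @param params a `sim_params`.
#' @param seed integer seed.
#' @return list with `counts` (sparse genes x cells), `annotation`
#'   (data.frame gene_id, chrom, tss, strand, base_mean), and `truth`
#'   (augmented with `effects` per target-gene and `guide_efficiency`).
#' @export
simulate_expression <- function(design, truth, params, seed = 1) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  n <- length(truth$cell_id)
  genes <- design$genome$genes
  nuclear <- genes[!startsWith(genes$gene_id, "MT-"), ]
  mito <- genes[startsWith(genes$gene_id, "MT-"), ]
  if (!is.null(params$n_genes) && params$n_genes < nrow(nuclear)) {
    idx <- unique(round(seq(1, nrow(nuclear), length.out = params$n_genes)))
    # expected genes of the design are always retained
    keep_ids <- design$targets$expected_gene_id
    idx <- sort(unique(c(idx, match(keep_ids[!is.na(keep_ids)],
                                    nuclear$gene_id))))
    nuclear <- nuclear[idx, ]
  }
  ngene <- nrow(nuclear)
  mu <- stats::rlnorm(ngene, params$nb_meanlog, params$nb_sdlog)
  # expected genes span the dynamic range log-uniformly
  tg <- design$targets[design$targets$class != "NT", ]
  exp_idx <- match(tg$expected_gene_id, nuclear$gene_id)
  if (any(is.na(exp_idx)) && nrow(tg) > 0) {
    stop("expected gene absent from simulated gene set")
  }
  if (nrow(tg) > 0) {
    r <- params$expected_gene_mean_range
    mu[exp_idx] <- exp(stats::runif(nrow(tg), log(r[1]), log(r[2])))
  }
  # per-target true effects and per-guide efficiencies
  kc <- params$knockdown_by_class
  conc <- params$knockdown_concentration
  eff <- numeric(nrow(tg))
  for (i in seq_len(nrow(tg))) {
    m_cl <- kc[[tg$class[i]]]
    eff[i] <- if (m_cl == 0) 0 else if (is.infinite(conc)) m_cl else
      stats::rbeta(1, m_cl * conc, (1 - m_cl) * conc)
  }
  effects <- data.frame(target_id = tg$target_id,
                        gene_id = tg$expected_gene_id,
                        effect = eff, stringsAsFactors = FALSE)
  gtab <- design$guides
  gtab$efficiency <- stats::rbeta(nrow(gtab), params$guide_eff_shape1,
                                  params$guide_eff_shape2)
  # per-cell multiplicative factor on each perturbed expected gene
  batch <- truth$batch
  if (anyNA(batch)) batch <- rep("E1", n)
  batches <- sort(unique(batch))
  bfac <- matrix(exp(stats::rnorm(ngene * length(batches), 0,
                                  params$batch_effect_scale)),
                 nrow = ngene,
                 dimnames = list(nuclear$gene_id, batches))
  s <- stats::rlnorm(n, 0, params$expr_sdlog)
  stripped <- stats::runif(n) < params$stripped_rate
  s[stripped] <- s[stripped] * 0.5
  # map: for each perturbed expected gene, the cells and their multiplier
  kd <- .knockdown_map(truth, gtab, effects, exp_idx, n, ngene)
  bcol <- match(batch, batches)
  has_mito <- nrow(mito) > 0 && length(params$mito_mean_by_batch) > 0
  annotation <- if (has_mito) rbind(nuclear, mito) else nuclear
  if (has_mito) {
    mm <- rep_len(params$mito_mean_by_batch, length(batches))
    mfrac <- stats::rbeta(n, mm[bcol] * params$mito_concentration,
                          (1 - mm[bcol]) * params$mito_concentration)
    mfrac[stripped] <- stats::rbeta(sum(stripped), 0.003 * 300, 0.997 * 300)
    w <- stats::rlnorm(nrow(mito), 0, 0.5)
    w <- w / sum(w)
  }
  # kd cells sorted so chunk membership is a range lookup
  kd <- lapply(kd, function(h) {
    if (is.null(h)) return(NULL)
    o <- order(h$cell)
    list(cell = h$cell[o], fac = h$fac[o])
  })
  # generate in fixed-size cell chunks to bound transient memory
  chunk_size <- 20000L
  starts <- seq(1L, n, by = chunk_size)
  chunks <- vector("list", length(starts))
  for (ci in seq_along(starts)) {
    lo <- starts[ci]
    hi <- min(lo + chunk_size - 1L, n)
    cs <- lo:hi
    nc <- length(cs)
    ti <- vector("list", ngene)
    tx <- vector("list", ngene)
    tot <- numeric(nc)
    s_c <- s[cs]
    b_c <- bcol[cs]
    for (g in seq_len(ngene)) {
      mvec <- mu[g] * s_c * bfac[g, b_c]
      hit <- kd[[g]]
      if (!is.null(hit)) {
        sel <- which(hit$cell >= lo & hit$cell <= hi)
        if (length(sel)) {
          loc <- hit$cell[sel] - lo + 1L
          mvec[loc] <- mvec[loc] * hit$fac[sel]
        }
      }
      x <- stats::rnbinom(nc, size = params$nb_dispersion, mu = mvec)
      nz <- which(x > 0L)
      ti[[g]] <- nz
      tx[[g]] <- x[nz]
      tot[nz] <- tot[nz] + x[nz]
    }
    gene_of <- rep.int(seq_len(ngene), lengths(ti))
    cell_of <- unlist(ti, use.names = FALSE)
    x_of <- as.numeric(unlist(tx, use.names = FALSE))
    if (has_mito) {
      mf <- mfrac[cs]
      mt_tot <- stats::rpois(nc, tot * mf / pmax(1e-9, 1 - mf))
      mt_cells <- rep.int(seq_len(nc), mt_tot)
      mt_gene <- sample.int(nrow(mito), length(mt_cells), replace = TRUE,
                            prob = w)
      mt_agg <- rowsum(rep(1, length(mt_cells)),
                       group = (mt_cells - 1) * nrow(mito) + mt_gene)
      mt_key <- as.numeric(rownames(mt_agg))
      gene_of <- c(gene_of, ngene + ((mt_key - 1) %% nrow(mito)) + 1)
      cell_of <- c(cell_of, ((mt_key - 1) %/% nrow(mito)) + 1)
      x_of <- c(x_of, as.numeric(mt_agg))
    }
    chunks[[ci]] <- Matrix::sparseMatrix(
      i = gene_of, j = cell_of, x = x_of,
      dims = c(nrow(annotation), nc),
      dimnames = list(annotation$gene_id, truth$cell_id[cs]))
  }
  counts <- if (length(chunks) == 1) chunks[[1]] else
    do.call(cbind, chunks)
  rm(chunks)
  annotation$base_mean <- c(mu, rep(NA_real_, nrow(annotation) - ngene))
  truth$effects <- effects
  truth$guide_efficiency <- gtab
  list(counts = methods::as(counts, "CsparseMatrix"),
       annotation = annotation, truth = truth)
}

# per-gene list of perturbed cells and their mean multipliers
.knockdown_map <- function(truth, gtab, effects, exp_idx, n, ngene) {
  kd <- vector("list", ngene)
  if (nrow(effects) == 0) return(kd)
  ki <- lengths(truth$integrations)
  if (sum(ki) == 0) return(kd)
  cell_of <- rep.int(seq_len(n), ki)
  guide_of <- unlist(truth$integrations, use.names = FALSE)
  gi <- match(guide_of, gtab$guide_id)
  tid <- gtab$target_id[gi]
  ei <- match(tid, effects$target_id)
  hit <- !is.na(ei)
  if (!any(hit)) return(kd)
  fac <- 1 - effects$effect[ei[hit]] * gtab$efficiency[gi[hit]]
  gene_row <- exp_idx[ei[hit]]
  cell <- cell_of[hit]
  sp <- split(data.frame(cell = cell, fac = fac), gene_row)
  for (nm in names(sp)) {
    d <- sp[[nm]]
    # a cell with several guides of the same target multiplies factors
    agg <- tapply(d$fac, d$cell, prod)
    kd[[as.integer(nm)]] <- list(cell = as.integer(names(agg)),
                                 fac = as.numeric(agg))
  }
  kd
}

#' Simulate a complete synthetic CROP-seq screen
#'
#' End-to-end generator: plasmid library, low-MOI infection (with optional
#' puromycin-style selection of transduced cells), batch structure, guide
#' UMI matrix with ambient noise, negative-binomial expression with planted
#' knockdowns, and doublets formed by summing two cells' columns.
#'
#' @param design a `screen_design` (default: the full 80-target library).
#' @param params a `sim_params`.
#' @param library optional `guide_library`; simulated if NULL.
#' @param lognormal_sigma plasmid-abundance spread when simulating the
#'   library.
#' @return list of class `crop_screen`: `design`, `library`, `params`,
#'   `gene_counts`, `guide_counts`, `annotation`, `batch` (named per cell),
#'   `truth` (integrations, batch, doublet flags, effects, efficiencies).
#' @export
simulate_screen <- function(design = build_design(),
                            params = sim_params(),
                            library = NULL,
                            lognormal_sigma = 0.5) {
  seed <- params$seed
  if (is.null(library)) {
    library <- simulate_plasmid_library(design, lognormal_sigma, seed = seed)
  }
  n_doublets <- round(params$doublet_rate * params$n_cells)
  n_base <- params$n_cells + n_doublets
  if (params$select_transduced && params$moi > 0) {
    p_inf <- 1 - exp(-params$moi)
    n_pool <- ceiling(n_base / p_inf * 1.05) + 100
    truth <- simulate_infections(design, library, n_pool, params$moi,
                                 seed = seed + 1)
    keep <- which(lengths(truth$integrations) > 0)
    if (length(keep) < n_base) {
      stop("infection pool too small; increase n_cells margin")
    }
    keep <- keep[seq_len(n_base)]
    truth$cell_id <- sprintf("CELL%07d", seq_len(n_base))
    truth$integrations <- truth$integrations[keep]
    truth$doublet <- rep(FALSE, n_base)
    truth$batch <- rep(NA_character_, n_base)
  } else {
    truth <- simulate_infections(design, library, n_base, params$moi,
                                 seed = seed + 1)
  }
  restore <- .with_seed(seed + 2)
  batch_lab <- paste0("E", seq_len(params$n_batches))
  truth$batch <- sample(batch_lab, n_base, replace = TRUE,
                        prob = params$batch_props)
  restore()
  guide_counts <- simulate_guide_counts(truth, library, params,
                                        seed = seed + 3)
  expr <- simulate_expression(design, truth, params, seed = seed + 4)
  truth <- expr$truth
  gene_counts <- expr$counts
  # doublets: the last n_doublets base cells are absorbed into earlier cells
  if (n_doublets > 0) {
    restore <- .with_seed(seed + 5)
    hosts <- sample.int(params$n_cells, n_doublets)
    restore()
    partners <- params$n_cells + seq_len(n_doublets)
    # partner batch follows the host (droplet doublets are within-channel)
    truth$batch[partners] <- truth$batch[hosts]
    # column subassignment on large sparse matrices is slow; rebuild by
    # cbind (host columns moved to the end) and reorder the per-cell
    # metadata to match — downstream stages key on cell ids, not order
    others <- setdiff(seq_len(params$n_cells), hosts)
    merge_cols <- function(m) {
      merged <- m[, hosts, drop = FALSE] + m[, partners, drop = FALSE]
      cbind(m[, others, drop = FALSE], merged)
    }
    gene_counts <- merge_cols(gene_counts)
    guide_counts <- merge_cols(guide_counts)
    truth$integrations[hosts] <- Map(
      function(a, b) unique(c(a, b)),
      truth$integrations[hosts], truth$integrations[partners])
    truth$doublet[hosts] <- TRUE
    keep <- c(others, hosts)
    truth$cell_id <- truth$cell_id[keep]
    truth$integrations <- truth$integrations[keep]
    truth$batch <- truth$batch[keep]
    truth$doublet <- truth$doublet[keep]
  }
  batch <- stats::setNames(truth$batch, truth$cell_id)
  structure(
    list(design = design, library = library, params = params,
         gene_counts = gene_counts, guide_counts = guide_counts,
         annotation = expr$annotation, batch = batch, truth = truth),
    class = "crop_screen"
  )
}

#' @export
print.crop_screen <- function(x, ...) {
  cat("crop_screen:", ncol(x$gene_counts), "cells,",
      nrow(x$gene_counts), "genes,", nrow(x$guide_counts), "guides,",
      n_targets(x$design), "targets (+", x$design$n_nt, "NT)\n")
  invisible(x)
}
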