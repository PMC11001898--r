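#' Transcriptional-noise configuration
#'
#' @param n_bins abundance bins used by invariant-gene selection.
#' @param invariant_fraction fraction of genes kept per bin (lowest
#'   coefficient of variation), at least one gene per bin.
#' @param grouping stratification for the centroid variant:
#'   `"by_celltype_and_group"` (default; age trends are not absorbed into
#'   the centroids) or `"by_celltype"` (pooled across groups).
#' @return list of class `noise_config`.
#' @export
noise_config <- function(n_bins = 10, invariant_fraction = 0.10,
                         grouping = c("by_celltype_and_group", "by_celltype")) {
  stopifnot(n_bins >= 1, invariant_fraction > 0, invariant_fraction <= 1)
  structure(list(n_bins = n_bins, invariant_fraction = invariant_fraction,
                 grouping = match.arg(grouping)), class = "noise_config")
}

# squared column distances to a centroid, sparse-aware:
# ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2
col_dist_to_centroid <- function(mat, centroid) {
  x2 <- Matrix::colSums(mat^2)
  xc <- as.numeric(Matrix::crossprod(mat, centroid))
  d2 <- pmax(x2 - 2 * xc + sum(centroid^2), 0)
  sqrt(d2)
}

#' Per-cell noise as distance to the cell-type centroid
#'
#' Transcriptional noise of a cell is its Euclidean distance, over all
#' retained genes in log-normalized space, to the arithmetic-mean expression
#' vector (centroid) of its stratum. Strata are cell types, optionally
#' crossed with the age group (see [noise_config()]); strata with fewer than
#' two cells are excluded with a warning rather than an error.
#'
#' @param norm log-normalized matrix from [normalize_cp10k()].
#' @param ann annotation aligned to `norm` columns.
#' @param cfg [noise_config()].
#' @return data.frame: cell, cell_type, group, distance, variant.
#' @export
noise_to_celltype_mean <- function(norm, ann, cfg = noise_config()) {
  stopifnot(identical(colnames(norm), rownames(ann)))
  if (any(is.na(ann$cell_type) | !nzchar(ann$cell_type))) {
    stop("every cell needs a non-empty cell_type")
  }
  strat <- if (cfg$grouping == "by_celltype_and_group") {
    paste(ann$cell_type, ann$group, sep = "|")
  } else {
    ann$cell_type
  }
  out <- vector("list", length(unique(strat)))
  i <- 0
  for (s in unique(strat)) {
    cols <- which(strat == s)
    if (length(cols) < 2) {
      warning("stratum '", s, "' has < 2 cells; excluded from noise estimation")
      next
    }
    sub <- norm[, cols, drop = FALSE]
    centroid <- Matrix::rowMeans(sub)
    d <- col_dist_to_centroid(sub, centroid)
    i <- i + 1
    out[[i]] <- data.frame(cell = colnames(norm)[cols],
                           cell_type = ann$cell_type[cols],
                           group = as.character(ann$group[cols]),
                           distance = d, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[seq_len(i)])
  if (is.null(res)) stop("no stratum with >= 2 cells")
  res <- res[match(intersect(colnames(norm), res$cell), res$cell), , drop = FALSE]
  rownames(res) <- NULL
  res$variant <- "celltype_mean"
  res
}

#' Select invariant genes evenly across the abundance range
#'
#' Genes are ranked by mean log-normalized abundance and split into
#' `n_bins` equal-size bins (remainder genes go to the highest-abundance
#' bins); within each bin the genes with the lowest coefficient of
#' variation (sd/mean over cells) are selected -- at least one per bin.
#' "Invariant" is operationalized as lowest within-bin CV: a scale-aware
#' stability criterion comparable across abundance levels. Genes with zero
#' mean carry no signal and are excluded before binning.
#'
#' @param norm log-normalized matrix.
#' @param cfg [noise_config()].
#' @return Character vector of selected gene symbols.
#' @export
select_invariant_genes <- function(norm, cfg = noise_config()) {
  mu <- Matrix::rowMeans(norm)
  nz <- which(mu > 0)
  if (length(nz) < cfg$n_bins) {
    stop("fewer genes with nonzero mean (", length(nz), ") than bins (", cfg$n_bins, ")")
  }
  m2 <- Matrix::rowMeans(norm[nz, , drop = FALSE]^2)
  n <- ncol(norm)
  sdv <- sqrt(pmax(m2 - mu[nz]^2, 0) * n / max(n - 1, 1))
  cv <- sdv / mu[nz]
  ord <- nz[order(mu[nz], decreasing = FALSE)]
  cv_ord <- cv[match(ord, nz)]
  G <- length(ord)
  base <- G %/% cfg$n_bins
  rem <- G %% cfg$n_bins
  # remainder genes to the highest-abundance bins
  sizes <- rep(base, cfg$n_bins) + c(rep(0, cfg$n_bins - rem), rep(1, rem))
  bin <- rep(seq_len(cfg$n_bins), times = sizes)
  picked <- integer(0)
  for (b in seq_len(cfg$n_bins)) {
    in_bin <- which(bin == b)
    k <- max(1L, ceiling(cfg$invariant_fraction * length(in_bin)))
    sel <- in_bin[order(cv_ord[in_bin])][seq_len(k)]
    picked <- c(picked, ord[sel])
  }
  rownames(norm)[picked]
}

#' Per-cell noise as distance to the global mean over invariant genes
#'
#' Alternative noise measure: the Euclidean distance from each cell to the
#' average profile across ALL cells, restricted to the invariant gene set
#' (no cell-type stratification).
#'
#' @param norm log-normalized matrix.
#' @param ann annotation aligned to `norm`.
#' @param invariant character vector of invariant gene symbols
#'   (from [select_invariant_genes()]).
#' @return data.frame: cell, cell_type, group, distance, variant.
#' @export
noise_invariant_variant <- function(norm, ann, invariant) {
  genes <- intersect(invariant, rownames(norm))
  if (length(genes) == 0) stop("invariant gene set disjoint from matrix")
  sub <- norm[genes, , drop = FALSE]
  centroid <- Matrix::rowMeans(sub)
  d <- col_dist_to_centroid(sub, centroid)
  data.frame(cell = colnames(norm),
             cell_type = ann$cell_type,
             group = as.character(ann$group),
             distance = d, variant = "invariant_gene",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize noise per cell type and group
#'
#' The quantities a boxplot shows: median, quartiles (linear-interpolation
#' quantiles) and n per (cell_type, group). Empty strata are absent rows.
#'
#' @param res result of a noise estimator.
#' @return data.frame: cell_type, group, n, q1, median, q3.
#' @export
summarize_noise <- function(res) {
  stopifnot(nrow(res) > 0)
  key <- interaction(res$cell_type, res$group, drop = TRUE, sep = "|")
  rows <- lapply(levels(key), function(k) {
    d <- res$distance[key == k]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(cell_type = parts[1], group = parts[2], n = length(d),
               q1 = unname(quantile(d, 0.25)), median = median(d),
               q3 = unname(quantile(d, 0.75)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$cell_type, out$group), , drop = FALSE]
}
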