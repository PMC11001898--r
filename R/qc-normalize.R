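#' QC thresholds
#'
#' Defaults follow common droplet scRNA-seq practice for this pipeline:
#' cells need at least 200 detected genes and at most 10% mitochondrial
#' UMIs; genes are retained when their total UMI count is strictly greater
#' than 5.
#'
#' @param min_features minimum detected genes per cell (cells below are
#'   removed; the boundary value is kept).
#' @param max_percent_mt maximum mitochondrial percentage (strictly greater
#'   removes; the boundary value is kept).
#' @param min_gene_umi gene total-UMI threshold, strict (`> min_gene_umi`
#'   keeps).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200, max_percent_mt = 10, min_gene_umi = 5) {
  stopifnot(min_features >= 0, max_percent_mt >= 0, max_percent_mt <= 100)
  structure(list(min_features = min_features,
                 max_percent_mt = max_percent_mt,
                 min_gene_umi = min_gene_umi),
            class = "qc_thresholds")
}

#' Filter cells then genes
#'
#' Order matters and is fixed: first remove cells with
#' `n_feature < min_features` or `percent_mt > max_percent_mt`, then remove
#' genes whose total UMI over the remaining cells is `<= min_gene_umi`.
#' Applying the filter twice is a no-op (idempotent) apart from gene totals
#' already being computed on the filtered cells.
#'
#' @param counts count matrix.
#' @param ann annotation aligned to `counts` (see [cell_annotation()]).
#' @param thr [qc_thresholds()].
#' @return list `counts`, `annotation`, `report` (data.frame with cells/genes
#'   removed at each step, in application order).
#' @export
qc_filter <- function(counts, ann, thr = qc_thresholds()) {
  stopifnot(identical(colnames(counts), rownames(ann)))
  keep_cell <- ann$n_feature >= thr$min_features & ann$percent_mt <= thr$max_percent_mt
  n_cell_rm <- sum(!keep_cell)
  if (!any(keep_cell)) stop("empty after QC: all cells removed")
  counts <- counts[, keep_cell, drop = FALSE]
  ann <- ann[keep_cell, , drop = FALSE]
  gene_tot <- Matrix::rowSums(counts)
  keep_gene <- gene_tot > thr$min_gene_umi
  n_gene_rm <- sum(!keep_gene)
  counts <- counts[keep_gene, , drop = FALSE]
  report <- data.frame(
    step = c("cell_filter", "gene_filter"),
    removed = c(n_cell_rm, n_gene_rm),
    retained = c(ncol(counts), nrow(counts)),
    criterion = c(sprintf("n_feature >= %d & percent_mt <= %g",
                          thr$min_features, thr$max_percent_mt),
                  sprintf("total UMI > %g", thr$min_gene_umi)),
    stringsAsFactors = FALSE
  )
  ls_log("QC: removed ", n_cell_rm, " cells, ", n_gene_rm, " genes; ",
         ncol(counts), " cells x ", nrow(counts), " genes retained")
  list(counts = counts, annotation = ann, report = report)
}

#' CP10K log normalization
#'
#' Scales each cell to 10,000 transcripts and applies the natural log:
#' `value(g,c) = ln(1 + 10000 * count(g,c) / total(c))`. Cell totals are
#' computed on the gene universe of the input (i.e. post-QC when called
#' after [qc_filter()]), so per cell `sum(expm1(values)) == 10000` on that
#' universe. Invariant to per-cell count scaling.
#'
#' @param counts post-QC count matrix; every cell total must be positive.
#' @return Sparse genes x cells matrix of log-normalized values.
#' @export
normalize_cp10k <- function(counts) {
  tot <- Matrix::colSums(counts)
  if (any(tot <= 0)) {
    stop("zero-total cell(s): ", paste(head(colnames(counts)[tot <= 0]), collapse = ", "))
  }
  norm <- counts %*% Matrix::Diagonal(x = 10000 / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}
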