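#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in p rank.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-gene two-group differential expression (t-test)
#'
#' Genes are pre-filtered to those detected in at least `min_pct` of cells
#' in one of the two groups and with `|log2FC| >= logfc_threshold`; the
#' surviving genes get a Welch (unequal-variance) two-sample t-test on
#' log-normalized values, with BH adjustment over the tested genes only.
#' log2FC is computed on de-logged means with a pseudocount:
#' `log2((mean(expm1(xA)) + 1) / (mean(expm1(xB)) + 1))`, the common
#' single-cell convention that tolerates all-zero groups.
#'
#' @param norm log-normalized matrix.
#' @param ann annotation aligned to `norm`.
#' @param group_a,group_b group labels (e.g. `"T5"`, `"T4"`); cells are
#'   selected by `ann$group`.
#' @param min_pct minimum detection fraction in at least one group.
#' @param logfc_threshold minimum |log2FC| to test.
#' @param pseudocount added to each de-logged group mean.
#' @return data.frame: gene, log2FC, p, p_adj, pct_a, pct_b (empty when no
#'   gene passes the pre-filter).
#' @export
deg_t_test <- function(norm, ann, group_a, group_b, min_pct = 0.1,
                       logfc_threshold = 0.25, pseudocount = 1) {
  stopifnot(identical(colnames(norm), rownames(ann)))
  ca <- which(ann$group == group_a)
  cb <- which(ann$group == group_b)
  if (length(ca) == 0) stop("group absent: ", group_a)
  if (length(cb) == 0) stop("group absent: ", group_b)
  if (length(ca) < 3 || length(cb) < 3) stop("both groups need >= 3 cells")
  A <- norm[, ca, drop = FALSE]
  B <- norm[, cb, drop = FALSE]
  na <- length(ca); nb <- length(cb)
  pct_a <- Matrix::rowSums(A > 0) / na
  pct_b <- Matrix::rowSums(B > 0) / nb
  mean_de_a <- Matrix::rowMeans(expm1(A))
  mean_de_b <- Matrix::rowMeans(expm1(B))
  lfc <- log2((mean_de_a + pseudocount) / (mean_de_b + pseudocount))
  keep <- (pmax(pct_a, pct_b) >= min_pct) & (abs(lfc) >= logfc_threshold)
  if (!any(keep)) {
    return(data.frame(gene = character(0), log2FC = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0)))
  }
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  # vectorized Welch t over rows
  ma <- Matrix::rowMeans(A); mb <- Matrix::rowMeans(B)
  va <- (Matrix::rowMeans(A^2) - ma^2) * na / (na - 1)
  vb <- (Matrix::rowMeans(B^2) - mb^2) * nb / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- 2 * pt(-abs(tstat), df)
  p[se2 == 0] <- 1   # no variance, no evidence
  out <- data.frame(gene = rownames(A), log2FC = lfc[keep], p = p,
                    p_adj = bh_adjust(p), pct_a = pct_a[keep],
                    pct_b = pct_b[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$p, out$gene), , drop = FALSE]
}

#' Overlap significant DEGs with disease gene lists
#'
#' Representative genes are those with `p < p_cut` and `log2FC > lfc_cut`
#' (up-regulated; unadjusted p, matching the selection convention of the
#' overlap analysis); each disease list is intersected with them.
#'
#' @param deg DEG table from [deg_t_test()].
#' @param disease_lists named list of gene symbol vectors.
#' @param p_cut p-value cutoff (default 0.05).
#' @param lfc_cut log2 fold-change cutoff (default 0.25, strict `>`).
#' @return data.frame: list_name, n_overlap, genes (comma-separated).
#' @export
overlap_disease_genes <- function(deg, disease_lists, p_cut = 0.05, lfc_cut = 0.25) {
  stopifnot(length(disease_lists) > 0)
  sig <- deg$gene[deg$p < p_cut & deg$log2FC > lfc_cut]
  rows <- lapply(names(disease_lists), function(nm) {
    ov <- intersect(sig, disease_lists[[nm]])
    data.frame(list_name = nm, n_overlap = length(ov),
               genes = paste(ov, collapse = ","), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
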