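#' Score-gated Pearson correlation of a gene with signature scores
#'
#' Selects the cells belonging to the given groups whose scores are ALL
#' strictly greater than `score_gate` (the gate is a conjunction over every
#' supplied score; "greater than" is read strictly, so boundary cells are
#' excluded), then correlates the gene's log-normalized expression with
#' each score over that subset. The p-value uses the t approximation
#' `t = r * sqrt((n-2)/(1-r^2))`.
#'
#' @param norm log-normalized matrix.
#' @param ann annotation aligned to `norm`.
#' @param gene gene symbol present in `norm`.
#' @param scores named list of score data.frames (from [module_score()];
#'   columns `cell`, `score`) covering all cells.
#' @param groups groups whose cells enter the correlation (default T4, T5).
#' @param score_gate gate threshold (default 0.01).
#' @return data.frame: gene, score_name, r, p, n_cells, gate.
#' @export
score_gene_correlation <- function(norm, ann, gene, scores,
                                   groups = c("T4", "T5"), score_gate = 0.01) {
  stopifnot(identical(colnames(norm), rownames(ann)))
  if (!gene %in% rownames(norm)) stop("gene not in matrix: ", gene)
  if (length(scores) == 0) stop("no scores supplied")
  cells <- colnames(norm)
  in_group <- ann$group %in% groups
  pass <- in_group
  for (sc in scores) {
    v <- sc$score[match(cells, sc$cell)]
    if (any(is.na(v))) stop("score table does not cover all cells")
    pass <- pass & (v > score_gate)
  }
  n <- sum(pass)
  if (n < 3) {
    stop("fewer than 3 cells pass the gate (", n, "); cannot correlate")
  }
  expr <- as.numeric(norm[gene, pass])
  gate_desc <- sprintf("groups %s & all scores > %g",
                       paste(groups, collapse = ","), score_gate)
  rows <- lapply(seq_along(scores), function(i) {
    v <- scores[[i]]$score[match(cells, scores[[i]]$cell)][pass]
    r <- cor(expr, v)
    if (is.na(r)) stop("correlation undefined (constant input) for score ",
                       names(scores)[i])
    t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(t), n - 2)
    data.frame(gene = gene,
               score_name = if (is.null(names(scores))) as.character(i)
                            else names(scores)[i],
               r = r, p = p, n_cells = n, gate = gate_desc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
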