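#' Assign abundance-matched control genes to a gene set
#'
#' All matrix genes are ranked by mean log-normalized expression and cut
#' into `n_bins` equal-size bins; for each target gene, `controls_per_gene`
#' control genes are sampled uniformly from its bin -- without replacement
#' when the bin is large enough, with replacement otherwise. Controls never
#' include members of the gene set itself; if that leaves a bin empty,
#' sampling falls back to the nearest non-empty bin with a warning. The
#' pooled controls have an expression distribution comparable to the
#' target set but are otherwise random, so the score's null expectation
#' is zero.
#'
#' @param norm log-normalized matrix.
#' @param gene_set character vector of gene symbols.
#' @param n_bins expression bins (default 25).
#' @param controls_per_gene controls sampled per target gene (default 100).
#' @param seed RNG seed for reproducible draws.
#' @return list of class `control_assignment`: `controls` (named list,
#'   target gene -> control genes, possibly with multiplicity), `bins`
#'   (gene -> bin index), parameters and seed.
#' @export
assign_control_genes <- function(norm, gene_set, n_bins = 25,
                                 controls_per_gene = 100, seed = 1) {
  genes <- rownames(norm)
  set_genes <- intersect(gene_set, genes)
  if (length(set_genes) == 0) stop("gene set disjoint from matrix genes")
  mu <- Matrix::rowMeans(norm)
  ord <- order(mu)          # ascending abundance; ties by input order
  G <- length(genes)
  n_bins <- min(n_bins, G)
  # equal-size bins by rank, remainder spread over the last bins
  base <- G %/% n_bins
  rem <- G %% n_bins
  sizes <- rep(base, n_bins) + c(rep(0, n_bins - rem), rep(1, rem))
  bin_of <- integer(G)
  bin_of[ord] <- rep(seq_len(n_bins), times = sizes)
  names(bin_of) <- genes
  candidates_by_bin <- lapply(seq_len(n_bins), function(b) {
    setdiff(genes[bin_of == b], gene_set)
  })
  set.seed(seed)
  controls <- vector("list", length(set_genes))
  names(controls) <- set_genes
  for (g in set_genes) {
    b <- bin_of[[g]]
    cand <- candidates_by_bin[[b]]
    if (length(cand) == 0) {
      # nearest non-empty bin (all its own members are set genes)
      dists <- abs(seq_len(n_bins) - b)
      ok <- which(vapply(candidates_by_bin, length, integer(1)) > 0)
      if (length(ok) == 0) stop("no control candidates outside the gene set")
      nb <- ok[which.min(dists[ok])]
      warning("bin ", b, " has no control candidates for '", g,
              "'; falling back to bin ", nb)
      cand <- candidates_by_bin[[nb]]
    }
    replace <- length(cand) < controls_per_gene
    controls[[g]] <- sample(cand, controls_per_gene, replace = replace)
  }
  structure(list(controls = controls, bins = bin_of, n_bins = n_bins,
                 controls_per_gene = controls_per_gene, seed = seed,
                 gene_set = set_genes),
            class = "control_assignment")
}

#' Signature (module) score per cell
#'
#' For cell i and gene set j, the score is the difference of two averages
#' of log-normalized expression:
#' `SC_j(i) = mean(Er(G_j, i)) - mean(Er(G_jcont, i))`,
#' where the control average pools all control draws of all target genes
#' (with multiplicity). Adding a constant to every expression value of a
#' cell leaves the score unchanged.
#'
#' @param norm log-normalized matrix (the one used to build `assignment`).
#' @param gene_set character vector of gene symbols.
#' @param assignment [assign_control_genes()] result.
#' @return data.frame: cell, score, set_mean, control_mean.
#' @export
module_score <- function(norm, gene_set, assignment) {
  stopifnot(inherits(assignment, "control_assignment"))
  set_genes <- intersect(gene_set, rownames(norm))
  if (!setequal(set_genes, assignment$gene_set)) {
    stop("assignment was built for a different gene set / matrix")
  }
  set_mean <- Matrix::colMeans(norm[set_genes, , drop = FALSE])
  pooled <- unlist(assignment$controls, use.names = FALSE)
  # mean with multiplicity: accumulate counts per distinct control gene
  tab <- table(pooled)
  ctrl_genes <- names(tab)
  w <- as.numeric(tab) / length(pooled)
  ctrl_mean <- as.numeric(Matrix::crossprod(norm[ctrl_genes, , drop = FALSE], w))
  data.frame(cell = colnames(norm),
             score = set_mean - ctrl_mean,
             set_mean = set_mean, control_mean = ctrl_mean,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score a collection of gene sets
#'
#' Convenience wrapper: one [module_score()] per set, with control draws
#' seeded per set from `seed`.
#'
#' @param norm log-normalized matrix.
#' @param gene_sets named list of gene symbol vectors.
#' @param n_bins,controls_per_gene,seed see [assign_control_genes()].
#' @return Named list of score data.frames.
#' @export
score_gene_sets <- function(norm, gene_sets, n_bins = 25,
                            controls_per_gene = 100, seed = 1) {
  out <- vector("list", length(gene_sets))
  names(out) <- names(gene_sets)
  for (i in seq_along(gene_sets)) {
    a <- assign_control_genes(norm, gene_sets[[i]], n_bins = n_bins,
                              controls_per_gene = controls_per_gene,
                              seed = derive_seed(seed, i))
    out[[i]] <- module_score(norm, gene_sets[[i]], a)
  }
  out
}
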