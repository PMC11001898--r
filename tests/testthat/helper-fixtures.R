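ls_quiet(TRUE)

# tiny deterministic bundle: 3 genes (one mitochondrial) x 4 cells
tiny_bundle <- function() {
  counts <- count_matrix(
    matrix(c(5, 0, 2, 8,
             0, 3, 1, 0,
             1, 1, 1, 1), nrow = 3, byrow = TRUE,
           dimnames = list(c("GENE1", "GENE2", "MT-CO1"),
                           c("c1", "c2", "c3", "c4"))))
  meta <- data.frame(cell = c("c1", "c2", "c3", "c4"),
                     sample = "s1",
                     group = c("T1", "T1", "T5", "T5"),
                     cell_type = c("A", "A", "B", "B"),
                     stringsAsFactors = FALSE)
  list(counts = counts, annotation = cell_annotation(counts, meta))
}

# dense matrix -> normalized container via the package path
norm_from_dense <- function(m, groups = NULL, types = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  cm <- count_matrix(m)
  meta <- data.frame(cell = colnames(m), sample = "s1",
                     group = if (is.null(groups)) "T1" else groups,
                     cell_type = if (is.null(types)) "A" else types,
                     stringsAsFactors = FALSE)
  list(counts = cm, annotation = cell_annotation(cm, meta))
}

# null configuration: no planted structure of any kind
null_sim_config <- function(n_genes = 500, cells = c(T1 = 5, T2 = 5, T3 = 5, T4 = 200, T5 = 200),
                            seed = 1, ...) {
  simulation_config(
    n_genes = n_genes, cells_per_group = cells,
    temporal_programs = list(), signature_link = list(r = NA),
    focal = list(base_mean = 50, amplitude = 0),
    dispersion = list(base_size = 10, focal_size = 200, hk_size = 500,
                      multipliers = c(T1 = 1, T2 = 1, T3 = 1, T4 = 1, T5 = 1)),
    seed = seed, ...)
}

# z-scored prototype trajectories plus a pure-noise flat cluster
planted_pattern_matrix <- function(genes_per_cluster = 100, sigma = 0.3, seed = 99) {
  sh <- pattern_shapes()
  zsc <- function(v) if (sd(v) == 0) rep(0, 5) else (v - mean(v)) / sd(v)
  protos <- rbind(zsc(sh$dev_up), zsc(sh$dev_down), zsc(sh$t3_peak),
                  zsc(sh$t3_trough), zsc(sh$aging_down), rep(0, 5))
  set.seed(seed)
  x <- protos[rep(1:6, each = genes_per_cluster), ] +
    matrix(rnorm(6 * genes_per_cluster * 5, 0, sigma), 6 * genes_per_cluster, 5)
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- group_levels()
  list(x = x, truth = rep(1:6, each = genes_per_cluster),
       expected_primary = c("development_up", "aging_down", "t3_peak",
                            "flat", "aging_down", "flat"))
}

# independent adjusted-Rand-index oracle (simple contingency formula)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
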