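test_that("centroid-distance noise matches hand computations", {
  # identical cells -> all distances zero
  m <- matrix(rep(c(2L, 5L, 1L), 4), 3,
              dimnames = list(c("a", "b", "c"), sprintf("c%d", 1:4)))
  toy <- norm_from_dense(m)
  res <- noise_to_celltype_mean(normalize_cp10k(toy$counts), toy$annotation)
  expect_equal(res$distance, rep(0, 4), tolerance = 1e-12)

  # two cells at (1,3) and (3,1) in expression space -> both sqrt(2) from centroid
  norm <- Matrix::Matrix(matrix(c(1, 3, 3, 1), 2,
                                dimnames = list(c("a", "b"), c("x", "y"))), sparse = TRUE)
  ann <- data.frame(cell = c("x", "y"), sample = "s", group = c("T1", "T1"),
                    cell_type = "A", n_feature = 2, percent_mt = 0,
                    row.names = c("x", "y"))
  ann$group <- factor(ann$group, levels = group_levels(), ordered = TRUE)
  res2 <- noise_to_celltype_mean(norm, ann)
  expect_equal(res2$distance, c(sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("noise is invariant to gene permutation and zero-variance genes, linear in deviations", {
  set.seed(7)
  base <- matrix(rnorm(200, 5, 1), 10, 20,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("c%02d", 1:20)))
  ann <- data.frame(cell = colnames(base), sample = "s", group = "T1",
                    cell_type = "A", n_feature = 10, percent_mt = 0,
                    row.names = colnames(base))
  ann$group <- factor(ann$group, levels = group_levels(), ordered = TRUE)
  mat <- Matrix::Matrix(base, sparse = TRUE)
  d0 <- noise_to_celltype_mean(mat, ann)$distance

  perm <- sample(nrow(base))
  d_perm <- noise_to_celltype_mean(mat[perm, ], ann)$distance
  expect_equal(d_perm, d0, tolerance = 1e-12)

  with_const <- rbind(base, constant = rep(3, 20))
  d_const <- noise_to_celltype_mean(Matrix::Matrix(with_const, sparse = TRUE), ann)$distance
  expect_equal(d_const, d0, tolerance = 1e-12)

  centroid <- rowMeans(base)
  scaled <- centroid + 3 * (base - centroid)
  d_scaled <- noise_to_celltype_mean(Matrix::Matrix(scaled, sparse = TRUE), ann)$distance
  expect_equal(d_scaled, 3 * d0, tolerance = 1e-9)
})

test_that("strata with fewer than two cells are excluded with a warning", {
  m <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), sprintf("c%d", 1:4)))
  toy <- norm_from_dense(m, types = c("A", "A", "A", "B"))
  expect_warning(
    res <- noise_to_celltype_mean(normalize_cp10k(toy$counts), toy$annotation),
    "< 2 cells")
  expect_false("c4" %in% res$cell)
})

test_that("invariant-gene selection honors bin structure and CV ordering", {
  # 20 genes, 10 bins, fraction 0.10 -> forced one per bin
  set.seed(3)
  m <- matrix(rpois(20 * 50, rep(seq(2, 40, length.out = 20), 50)), 20, 50,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:50)))
  norm <- normalize_cp10k(count_matrix(m))
  inv <- select_invariant_genes(norm, noise_config())
  expect_length(inv, 10)

  # a zero-variance gene beats everything in its bin
  dense <- as.matrix(norm)
  dense["g05", ] <- mean(dense["g05", ])
  inv2 <- select_invariant_genes(Matrix::Matrix(dense, sparse = TRUE), noise_config())
  expect_true("g05" %in% inv2)

  expect_error(select_invariant_genes(norm[1:5, ], noise_config(n_bins = 10)),
               "fewer genes")
})

test_that("planted housekeepers dominate the invariant selection", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 1000, housekeeping = list(n_genes = 100),
    base_mean = list(shape = 5, scale = 8),
    temporal_programs = list(), signature_link = list(r = NA), seed = 2))
  norm <- normalize_cp10k(sim$counts)
  inv <- select_invariant_genes(norm, noise_config())
  hk <- names(sim$truth$gene_program)[sim$truth$gene_program == "housekeeping"]
  expect_length(inv, 100)
  expect_gte(length(intersect(inv, hk)), 90)
})

test_that("invariant-gene noise variant uses the global mean profile", {
  # one invariant gene with values 0 and 2 -> both cells at distance 1
  norm <- Matrix::Matrix(matrix(c(0, 5, 2, 5), 2,
                                dimnames = list(c("inv", "other"), c("x", "y"))),
                         sparse = TRUE)
  ann <- data.frame(cell = c("x", "y"), sample = "s", group = c("T4", "T5"),
                    cell_type = "A", row.names = c("x", "y"))
  ann$group <- factor(ann$group, levels = group_levels(), ordered = TRUE)
  res <- noise_invariant_variant(norm, ann, "inv")
  expect_equal(res$distance, c(1, 1), tolerance = 1e-12)
  # adding a constant gene to the invariant set changes nothing
  norm2 <- rbind(norm, Matrix::Matrix(matrix(c(7, 7), 1,
                                             dimnames = list("const", NULL)), sparse = TRUE))
  res2 <- noise_invariant_variant(norm2, ann, c("inv", "const"))
  expect_equal(res2$distance, res$distance, tolerance = 1e-12)
  expect_error(noise_invariant_variant(norm, ann, "absent"), "disjoint")
})

test_that("noise summary reports boxplot quantities per stratum", {
  res <- data.frame(cell = c("a", "b", "c"), cell_type = "A",
                    group = "T1", distance = c(1, 2, 3))
  s <- summarize_noise(res)
  expect_identical(nrow(s), 1L)
  expect_equal(s$median, 2)
  expect_equal(s$q1, 1.5)
  expect_equal(s$q3, 2.5)
  # empty strata are absent rows, not NaN rows
  expect_false(any(is.na(s)))
})

test_that("group-median noise is non-decreasing in the planted dispersion multiplier", {
  meds <- sapply(c(1, 1.5, 2), function(k) {
    sim <- simulate_dataset(simulation_config(
      n_genes = 400,
      cells_per_group = c(T1 = 30, T2 = 30, T3 = 30, T4 = 100, T5 = 100),
      cell_types = list(list(name = "AT2", n_markers = 10, fold = 3)),
      temporal_programs = list(), signature_link = list(r = NA),
      dispersion = list(base_size = 10, focal_size = 200, hk_size = 500,
                        multipliers = c(T1 = 1, T2 = 1, T3 = 1, T4 = 1, T5 = k)),
      seed = 31))
    norm <- normalize_cp10k(sim$counts)
    sm <- summarize_noise(noise_to_celltype_mean(norm, sim$annotation))
    sm$median[sm$group == "T5"]
  })
  expect_true(all(diff(meds) > 0))
})
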