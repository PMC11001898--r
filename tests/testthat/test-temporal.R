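test_that("pseudobulk z-scores trajectories and drops constant genes", {
  norm <- Matrix::Matrix(matrix(c(0:4, rep(2, 5)), 2, 5, byrow = TRUE,
                                dimnames = list(c("ramp", "const"),
                                                sprintf("c%d", 1:5))), sparse = TRUE)
  ann <- data.frame(cell = colnames(norm), sample = "s",
                    group = group_levels(), cell_type = "A",
                    row.names = colnames(norm))
  ann$group <- factor(ann$group, levels = group_levels(), ordered = TRUE)
  expect_warning(tc <- pseudobulk_timecourse(norm, ann), "constant")
  expect_identical(rownames(tc$z), "ramp")
  z <- tc$z["ramp", ]
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(unname(z), -rev(unname(z)), tolerance = 1e-12)   # symmetric ramp
  # missing group is an error
  expect_error(pseudobulk_timecourse(norm[, 1:4], ann[1:4, ]), "absent")
})

test_that("planted dev_up genes give monotone pseudobulk trajectories", {
  sim <- simulate_dataset(simulation_config(n_genes = 1000,
    temporal_programs = list(list(pattern = "dev_up", n_genes = 100, amplitude = 2)),
    seed = 7))
  norm <- normalize_cp10k(sim$counts)
  tc <- suppressWarnings(pseudobulk_timecourse(norm, sim$annotation))
  dev <- names(sim$truth$gene_program)[sim$truth$gene_program == "dev_up"]
  mono <- apply(tc$raw[dev, ], 1, function(r) all(diff(r) >= 0))
  expect_gte(mean(mono), 0.95)
})

test_that("fuzzy c-means fixes exact prototypes, is deterministic, memberships sum to 1", {
  protos <- matrix(rnorm(30), 6, 5)
  x <- protos[rep(1:6, each = 4), ]
  rownames(x) <- sprintf("g%02d", 1:24)
  fit <- fuzzy_cmeans(x, k = 6, seed = 2, restarts = 10)
  expect_equal(max(fit$membership[cbind(seq_len(24), fit$label)]), 1, tolerance = 1e-9)
  expect_equal(sort(fit$objective), 0, tolerance = 1e-9)
  ord <- order(fit$centroids[, 1])
  expect_equal(fit$centroids[ord, ], protos[order(protos[, 1]), ],
               tolerance = 1e-6, ignore_attr = TRUE)

  fit2 <- fuzzy_cmeans(x, k = 6, seed = 2, restarts = 10)
  expect_identical(fit$membership, fit2$membership)

  expect_equal(unname(rowSums(fit$membership)), rep(1, 24), tolerance = 1e-9)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_error(fuzzy_cmeans(x[1:3, ], k = 6), "exceeds")
})

test_that("clustering is invariant to gene order up to relabeling", {
  pm <- planted_pattern_matrix(genes_per_cluster = 30, seed = 5)
  fit1 <- fuzzy_cmeans(pm$x, k = 6, seed = 3)
  perm <- sample(nrow(pm$x))
  fit2 <- fuzzy_cmeans(pm$x[perm, ], k = 6, seed = 3)
  expect_equal(ari(fit1$label[perm], fit2$label), 1, tolerance = 1e-12)
})

test_that("memberships and objective agree with an independent fuzzy c-means", {
  skip_if_not_installed("e1071")
  pm <- planted_pattern_matrix(genes_per_cluster = 20, seed = 11)
  fit <- fuzzy_cmeans(pm$x, k = 6, seed = 4, restarts = 30)
  fcm_J <- function(x, centers, u, m = 2) {
    d2 <- t(apply(x, 1, function(r) colSums((t(centers) - r)^2)))
    sum(u^m * d2)
  }
  ref <- NULL
  for (s in 1:30) {
    set.seed(s)
    cand <- e1071::cmeans(pm$x, centers = 6, m = 2, iter.max = 500)
    J <- fcm_J(pm$x, cand$centers, cand$membership)
    if (is.null(ref) || J < ref$J) ref <- list(fit = cand, J = J)
  }
  expect_equal(fit$objective, ref$J, tolerance = 0.01)
  expect_equal(ari(fit$label, ref$fit$cluster), 1, tolerance = 1e-12)
})

test_that("trend classification follows the step rules", {
  r <- classify_trend(c(-1.2, -0.4, 1.5, 0.4, -0.3))
  expect_setequal(r$flags, c("development_up", "t3_peak", "aging_down"))
  expect_identical(r$primary, "t3_peak")
  expect_identical(classify_trend(c(0, 0, 0, 0, 0))$primary, "flat")
  expect_identical(classify_trend(c(0, 0.5, 1, 1.2, 1.5))$primary, "development_up")
  expect_identical(classify_trend(c(1, 1, 1, 1, 0))$primary, "aging_down")
  # steps below epsilon count as flat
  expect_identical(classify_trend(c(0, 0.05, 0.08, 0.05, 0))$primary, "flat")
})

test_that("six planted patterns are recovered with matching trend labels", {
  pm <- planted_pattern_matrix(genes_per_cluster = 100, sigma = 0.3, seed = 99)
  fit <- fuzzy_cmeans(pm$x, k = 6, seed = 5)
  expect_gte(ari(fit$label, pm$truth), 0.9)
  # majority-vote mapping cluster -> planted pattern, compare primary labels
  labs <- label_modules(fit)
  hits <- 0
  for (k in 1:6) {
    planted <- as.integer(names(which.max(table(pm$truth[fit$label == k]))))
    if (labs$primary[k] == pm$expected_primary[planted]) hits <- hits + 1
  }
  expect_gte(hits, 5)
})
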