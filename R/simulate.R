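#' Temporal pattern shapes on group rank
#'
#' Unit trajectories over the five ordered groups, scaled by a program's
#' amplitude in log2 units. Patterns are parameterized on group rank (1..5),
#' not on chronological age: the downstream analysis only ever sees the five
#' ordered groups. `dev_up` rises through development and keeps rising
#' slightly in adulthood (strictly increasing so pseudobulk trajectories are
#' monotone up to sampling noise); `t3_peak` peaks at T3; `aging_down` is
#' stable until T4 and drops in the aging group; `flat` is constant.
#' `dev_down` / `t3_trough` are the negations of their counterparts.
#'
#' @return Named list of 5-vectors.
#' @export
pattern_shapes <- function() {
  up <- c(0, 0.35, 0.6, 0.8, 1)
  peak <- c(0, 0.6, 1, 0.6, 0)
  list(
    dev_up      = up,
    dev_down    = -up,
    t3_peak     = peak,
    t3_trough   = -peak,
    aging_down  = c(1, 1, 1, 1, 0),
    flat        = c(0, 0, 0, 0, 0)
  )
}

#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic scRNA-seq dataset:
#' negative-binomial (Gamma-Poisson) counts with lognormal library-size
#' factors, cell types with marker-gene blocks, group-dependent dispersion
#' inflation (aging noise as wider dispersion in T5, which raises per-cell
#' distance to the centroid without moving the centroid), planted temporal
#' gene programs across T1..T5, and a focal high-expression gene whose
#' trajectory rises during development and falls during aging and which is
#' latently linked to a planted gene-set score.
#'
#' @param n_genes total genes (incl. special blocks).
#' @param cells_per_group named counts for T1..T5.
#' @param cell_types list of `list(name, n_markers, fold)` blocks; cells are
#'   assigned to types uniformly at random.
#' @param base_mean `list(shape, scale)` of the Gamma distribution of
#'   per-gene expected counts (at library factor 1).
#' @param dispersion `list(base_size, focal_size, hk_size, multipliers)`;
#'   NB size (inverse dispersion) per gene is divided by the group
#'   multiplier, so `multipliers = c(..., T5 = 2)` doubles dispersion in T5.
#' @param library_size `list(sdlog)`; size factors are lognormal with
#'   `meanlog = -sdlog^2/2` so they average 1.
#' @param mito_fraction expected mitochondrial UMI percentage; `n_mito`
#'   genes named `MT-1..` share the corresponding expression mass.
#' @param n_mito number of mitochondrial genes.
#' @param temporal_programs list of `list(pattern, n_genes, amplitude)`;
#'   pattern names from [pattern_shapes()], amplitude in log2 units.
#' @param housekeeping `list(n_genes)`: near-Poisson genes (`hk_size`)
#'   placed at evenly spaced abundance quantiles, the planted "invariant"
#'   genes.
#' @param focal_gene name of the planted focal gene (FTL-like: high
#'   expression, development-up / aging-down trajectory).
#' @param focal `list(base_mean, amplitude)` for the focal gene.
#' @param signature_link `list(r, set_size, set_base_mean, loading)`;
#'   `r` is the target Pearson correlation between the focal gene and the
#'   planted signature score on the score-gated cell population (`r = NA`
#'   disables the link). `loading` is the latent factor's natural-log
#'   loading on the signature genes.
#' @param score_gate gate the correlation stage will apply (score > gate);
#'   used only to calibrate the planted latent correlation.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 2000,
    cells_per_group = c(T1 = 200, T2 = 200, T3 = 200, T4 = 200, T5 = 200),
    cell_types = list(list(name = "AT1", n_markers = 25, fold = 4),
                      list(name = "AT2", n_markers = 25, fold = 4)),
    base_mean = list(shape = 0.6, scale = 2),
    dispersion = list(base_size = 10, focal_size = 200, hk_size = 500,
                      multipliers = c(T1 = 1, T2 = 1, T3 = 1, T4 = 1, T5 = 2)),
    library_size = list(sdlog = 0.3),
    mito_fraction = 5,
    n_mito = 10,
    temporal_programs = list(list(pattern = "dev_up", n_genes = 100, amplitude = 1),
                             list(pattern = "t3_peak", n_genes = 100, amplitude = 1),
                             list(pattern = "aging_down", n_genes = 100, amplitude = 1)),
    housekeeping = list(n_genes = 0),
    focal_gene = "FTL",
    focal = list(base_mean = 50, amplitude = 1),
    signature_link = list(r = 0.8, set_size = 50, set_base_mean = 2, loading = 0.8),
    score_gate = 0.01,
    seed = 1) {
  cfg <- list(n_genes = n_genes, cells_per_group = cells_per_group,
              cell_types = cell_types, base_mean = base_mean,
              dispersion = dispersion, library_size = library_size,
              mito_fraction = mito_fraction, n_mito = n_mito,
              temporal_programs = temporal_programs,
              housekeeping = housekeeping, focal_gene = focal_gene,
              focal = focal, signature_link = signature_link,
              score_gate = score_gate, seed = seed)
  stopifnot(all(cells_per_group > 0),
            all(dispersion$multipliers >= 1),
            mito_fraction >= 0, mito_fraction < 100)
  if (!is.null(signature_link$r) && !is.na(signature_link$r)) {
    stopifnot(abs(signature_link$r) <= 1)
  }
  for (p in temporal_programs) {
    stopifnot(p$pattern %in% names(pattern_shapes()), p$amplitude >= 0)
  }
  structure(cfg, class = "simulation_config")
}

# Latent-loading calibration for the focal-gene / signature-score link.
#
# The generator plants a per-cell latent factor u: signature genes load on
# it with natural-log loading `a`, the focal gene with `a*(rho*u +
# sqrt(1-rho^2)*v)`. Downstream, the correlation stage only uses cells
# whose score exceeds the gate, which truncates the score near its mean
# and attenuates the observed correlation; count noise, the focal gene's
# own T4-vs-T5 trajectory step, and the CP10K library compression (the
# latent genes are a non-negligible share of the library, so the per-cell
# total co-varies with u; the control subtraction cancels this for scores
# but not for the focal gene) attenuate it further. The mixing coefficient
# rho is chosen by simulating the Gaussian abstraction of this chain
# (fixed internal seed, bisection on rho) so that the correlation on the
# GATED population equals the configured target r0.
plan_signature_link <- function(cfg) {
  link <- cfg$signature_link
  r0 <- link$r
  a <- link$loading
  sizes <- cfg$dispersion
  # per-gene log-noise SDs (delta method on the NB)
  var_sig <- 1 / link$set_base_mean + 1 / sizes$focal_size
  var_focal <- 1 / cfg$focal$base_mean + 1 / sizes$focal_size
  # control-average noise is of the same order as the set-average noise;
  # coefficient 3 from the design analysis of the pooled weighted draws
  sigma_s <- sqrt(3 * var_sig / link$set_size)
  # focal T4-vs-T5 trajectory step (equal-size gate groups)
  shape <- c(0, 0.5, 1, 1, 0.45) * cfg$focal$amplitude
  traj_half <- log(2) * (shape[4] - shape[5]) / 2
  # library-compression slope: d log(total) / du
  mass_sig <- link$set_size * link$set_base_mean * exp(a^2 / 2)
  mass_focal <- cfg$focal$base_mean
  mass_markers <- sum(vapply(cfg$cell_types, function(ct)
    ct$n_markers * (ct$fold - 1) / max(1, length(cfg$cell_types)), numeric(1))) *
    cfg$base_mean$shape * cfg$base_mean$scale
  total_mass <- (cfg$n_genes * cfg$base_mean$shape * cfg$base_mean$scale +
                   mass_sig + mass_focal + mass_markers) /
    (1 - cfg$mito_fraction / 100)
  kappa_c <- a * mass_sig / total_mass

  gated_cor <- function(rho) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    rs <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", rs, envir = globalenv()))
    set.seed(20240601L)
    n <- 2e5
    u <- rnorm(n); v <- rnorm(n)
    s <- a * u + rnorm(n, 0, sigma_s)
    y <- (a * rho - kappa_c) * u + a * sqrt(max(0, 1 - rho^2)) * v +
      sample(c(-traj_half, traj_half), n, replace = TRUE) +
      rnorm(n, 0, sqrt(var_focal))
    g <- s > cfg$score_gate
    cor(y[g], s[g])
  }
  lo <- 0; hi <- 1
  if (gated_cor(1) < abs(r0)) {
    warning("signature link target r = ", r0,
            " not attainable under this configuration; using full mixing")
    rho_mix <- 1
  } else {
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (gated_cor(mid) < abs(r0)) lo <- mid else hi <- mid
    }
    rho_mix <- (lo + hi) / 2
  }
  list(rho_mix = sign(r0) * rho_mix, loading = a, focal_loading = a)
}

#' Simulate an scRNA-seq dataset with planted structure
#'
#' Draws gene-by-cell UMI counts as negative binomial with cell-specific
#' lognormal size factors. Group-level mean trajectories follow each gene's
#' assigned temporal pattern evaluated at group ranks 1..5; cells of group g
#' draw with NB size divided by the configured dispersion multiplier for g
#' (dispersion inflation, not mean shift, implements aging noise so that
#' centroid positions stay put). Marker blocks are up-scaled in their cell
#' type; a latent per-cell factor links the focal gene to the planted
#' signature gene set at the configured gated correlation.
#'
#' @param cfg [simulation_config()].
#' @return list with `counts` (sparse count matrix), `annotation`
#'   (per-cell data.frame) and `truth` (ground truth: per-gene program
#'   labels, marker/signature membership, dispersion multipliers, pattern
#'   shapes, the latent factor and the target gated correlation).
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  shapes <- pattern_shapes()
  groups <- group_levels()

  # ---- gene layout ----------------------------------------------------
  link_on <- !is.null(cfg$signature_link$r) && !is.na(cfg$signature_link$r)
  n_sig <- if (link_on) cfg$signature_link$set_size else 0
  n_mark <- vapply(cfg$cell_types, function(ct) ct$n_markers, numeric(1))
  n_prog <- vapply(cfg$temporal_programs, function(p) p$n_genes, numeric(1))
  n_hk <- cfg$housekeeping$n_genes
  n_special <- 1 + n_sig + sum(n_mark) + sum(n_prog) + n_hk + cfg$n_mito
  if (n_special > cfg$n_genes) {
    stop("infeasible config: ", n_special, " special genes exceed n_genes = ", cfg$n_genes)
  }

  gene_names <- character(0)
  program <- character(0)
  add_block <- function(names, label) {
    gene_names <<- c(gene_names, names)
    program <<- c(program, rep(label, length(names)))
  }
  add_block(cfg$focal_gene, "focal")
  if (n_sig > 0) add_block(sprintf("SIG%03d", seq_len(n_sig)), "signature")
  for (ct in cfg$cell_types) {
    add_block(sprintf("MK.%s.%03d", ct$name, seq_len(ct$n_markers)), paste0("marker_", ct$name))
  }
  for (p in cfg$temporal_programs) {
    add_block(sprintf("PRG.%s.%03d", p$pattern, seq_len(p$n_genes)), p$pattern)
  }
  if (n_hk > 0) add_block(sprintf("HK%04d", seq_len(n_hk)), "housekeeping")
  if (cfg$n_mito > 0) add_block(paste0("MT-", seq_len(cfg$n_mito)), "mito")
  n_bg <- cfg$n_genes - length(gene_names)
  if (n_bg > 0) add_block(sprintf("G%05d", seq_len(n_bg)), "background")
  G <- cfg$n_genes

  # ---- base means ------------------------------------------------------
  base_mean <- rgamma(G, shape = cfg$base_mean$shape, scale = cfg$base_mean$scale)
  base_mean <- pmax(base_mean, 1e-3)
  base_mean[program == "focal"] <- cfg$focal$base_mean
  if (n_sig > 0) {
    # spread over several abundance bins so controls can be matched from
    # the surrounding background genes
    base_mean[program == "signature"] <-
      cfg$signature_link$set_base_mean * exp(rnorm(n_sig, 0, 0.75))
  }
  prog_names <- vapply(cfg$temporal_programs, function(p) p$pattern, character(1))
  in_prog <- program %in% prog_names
  if (any(in_prog)) {
    # temporal programs are planted on moderately-to-well-expressed genes:
    # trajectories of near-zero-expression genes are not recoverable from
    # pseudobulk means and are not what time-course clustering targets
    base_mean[in_prog] <- stats::qgamma(runif(sum(in_prog), 0.55, 0.995),
                                        shape = cfg$base_mean$shape,
                                        scale = cfg$base_mean$scale)
  }
  if (n_hk > 0) {
    qs <- stats::qgamma((seq_len(n_hk) - 0.5) / n_hk,
                        shape = cfg$base_mean$shape, scale = cfg$base_mean$scale)
    base_mean[program == "housekeeping"] <- pmax(qs, 0.05)
  }
  if (cfg$n_mito > 0) {
    f <- cfg$mito_fraction / 100
    non_mito_total <- sum(base_mean[program != "mito"])
    base_mean[program == "mito"] <- f / (1 - f) * non_mito_total / cfg$n_mito
  }

  # ---- per-gene temporal trajectories (log2 offsets x group) ----------
  traj <- matrix(0, nrow = G, ncol = 5, dimnames = list(gene_names, groups))
  for (p in cfg$temporal_programs) {
    idx <- program == p$pattern
    traj[idx, ] <- matrix(shapes[[p$pattern]] * p$amplitude,
                          nrow = sum(idx), ncol = 5, byrow = TRUE)
  }
  focal_shape <- c(0, 0.5, 1, 1, 0.45)   # up through development, down in aging
  traj[program == "focal", ] <- focal_shape * cfg$focal$amplitude

  # ---- cells -----------------------------------------------------------
  n_per <- cfg$cells_per_group[groups]
  n_cells <- sum(n_per)
  group <- rep(groups, times = n_per)
  barcode <- sprintf("cell%05d", seq_len(n_cells))
  type_names <- vapply(cfg$cell_types, function(ct) ct$name, character(1))
  cell_type <- sample(type_names, n_cells, replace = TRUE)
  sf <- rlnorm(n_cells, meanlog = -cfg$library_size$sdlog^2 / 2,
               sdlog = cfg$library_size$sdlog)
  latent_u <- rnorm(n_cells)
  latent_v <- rnorm(n_cells)

  # ---- mean matrix -----------------------------------------------------
  group_idx <- match(group, groups)
  log_mu <- matrix(log(base_mean), nrow = G, ncol = n_cells) +
    log(2) * traj[, group_idx, drop = FALSE]
  for (ct in cfg$cell_types) {
    rows <- program == paste0("marker_", ct$name)
    cols <- cell_type == ct$name
    log_mu[rows, cols] <- log_mu[rows, cols] + log(ct$fold)
  }
  link <- NULL
  if (link_on) {
    link <- plan_signature_link(cfg)
    sig_rows <- program == "signature"
    log_mu[sig_rows, ] <- sweep(log_mu[sig_rows, , drop = FALSE], 2,
                                link$loading * latent_u, `+`)
    focal_mix <- link$rho_mix * latent_u +
      sqrt(max(0, 1 - link$rho_mix^2)) * latent_v
    log_mu[program == "focal", ] <- log_mu[program == "focal", ] +
      link$focal_loading * focal_mix
  }
  mu <- exp(sweep(log_mu, 2, log(sf), `+`))

  # ---- dispersion and sampling ----------------------------------------
  size_gene <- rep(cfg$dispersion$base_size, G)
  size_gene[program %in% c("focal", "signature")] <- cfg$dispersion$focal_size
  size_gene[program == "housekeeping"] <- cfg$dispersion$hk_size
  mult <- cfg$dispersion$multipliers[groups][group_idx]
  size_mat <- matrix(size_gene, nrow = G, ncol = n_cells) /
    matrix(mult, nrow = G, ncol = n_cells, byrow = TRUE)
  counts <- matrix(rnbinom(G * n_cells, mu = mu, size = size_mat),
                   nrow = G, ncol = n_cells,
                   dimnames = list(gene_names, barcode))

  cm <- count_matrix(counts)
  meta <- data.frame(cell = barcode, sample = paste0(group, "_s1"),
                     group = group, cell_type = cell_type,
                     stringsAsFactors = FALSE)
  ann <- cell_annotation(cm, meta)

  truth <- list(
    gene_program = setNames(program, gene_names),
    base_mean = setNames(base_mean, gene_names),
    trajectory_log2 = traj,
    focal_gene = cfg$focal_gene,
    signature_genes = gene_names[program == "signature"],
    marker_genes = lapply(setNames(type_names, type_names), function(tn)
      gene_names[program == paste0("marker_", tn)]),
    dispersion_multipliers = cfg$dispersion$multipliers,
    latent = setNames(if (link_on) latent_u else rep(NA_real_, n_cells), barcode),
    target_gated_r = if (link_on) cfg$signature_link$r else NA_real_,
    pattern_shapes = shapes
  )
  list(counts = cm, annotation = ann, truth = truth)
}

#' Write a simulated dataset plus its ground truth
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_expression_bundle(sim$counts, sim$annotation, dir)
  gt <- data.frame(gene = names(sim$truth$gene_program),
                   program = unname(sim$truth$gene_program),
                   base_mean = unname(sim$truth$base_mean),
                   stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.tsv")
  write_results(gt, gt_path)
  invisible(c(paths, ground_truth = gt_path))
}
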