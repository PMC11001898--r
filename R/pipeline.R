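#' Read a pipeline configuration
#'
#' Plain-text YAML with one section per stage (`simulate`, `qc`, `noise`,
#' `score`, `tca`, `deg`, `correlate`) plus top-level `output_dir` and
#' either `input` (paths of an expression bundle) or a `simulate` section.
#' Every stochastic stage must carry an explicit `seed`; omitting it is a
#' configuration error, never a silent random run.
#'
#' @param path YAML file.
#' @return Named list (the config).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$output_dir)) stop("config error at 'output_dir': required")
  if (is.null(cfg$input) && is.null(cfg$simulate)) {
    stop("config error: need either 'input' or a 'simulate' section")
  }
  for (stage in c("simulate", "score", "tca")) {
    if (!is.null(cfg[[stage]]) && is.null(cfg[[stage]]$seed)) {
      stop("config error at '", stage, ".seed': stochastic stages need an explicit seed")
    }
  }
  cfg
}

stage_hash <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(character(0))
  setNames(as.character(tools::md5sum(paths)), basename(paths))
}

#' Run the pipeline from a configuration
#'
#' Executes the configured stages in dependency order
#' (simulate/load -> qc+normalize -> noise / score / tca / deg /
#' correlate), writing each stage's tables under `output_dir` and
#' returning a run manifest (config snapshot, seeds, package version,
#' per-stage output hashes, collected warnings). A stage failure halts the
#' run with a stage-tagged error; outputs of completed stages remain on
#' disk. Re-running an identical config reproduces identical hashes for
#' the deterministic stages.
#'
#' @param config path to a YAML config or a config list from
#'   [read_config()].
#' @return The manifest (list), invisibly written to
#'   `output_dir/manifest.yaml` as well.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, package_version = as.character(packageVersion("lungspan")),
                   stages = list(), warnings = character(0))
  note <- function(w) manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
  run_stage <- function(name, expr) {
    ls_log("stage: ", name)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) { note(w); invokeRestart("muffleWarning") }
    )
  }

  # ---- input ----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    data <- run_stage("simulate", {
      sc_args <- cfg$simulate
      sc_args$seed <- as.integer(sc_args$seed)
      # YAML maps arrive as named lists; the config wants numeric vectors
      if (is.list(sc_args$cells_per_group)) {
        sc_args$cells_per_group <- unlist(sc_args$cells_per_group)
      }
      if (is.list(sc_args$dispersion) && is.list(sc_args$dispersion$multipliers)) {
        sc_args$dispersion$multipliers <- unlist(sc_args$dispersion$multipliers)
      }
      sim_cfg <- do.call(simulation_config, sc_args[names(sc_args) %in%
                                                     names(formals(simulation_config))])
      sim <- simulate_dataset(sim_cfg)
      paths <- write_simulation(sim, file.path(out_dir, "simulated"))
      manifest$stages$simulate <- list(seed = sim_cfg$seed, outputs = stage_hash(paths))
      sim
    })
  } else {
    data <- run_stage("load", {
      b <- read_expression_bundle(cfg$input$mtx, cfg$input$genes,
                                  cfg$input$barcodes, cfg$input$metadata)
      manifest$stages$load <- list(outputs = stage_hash(unlist(cfg$input)))
      b
    })
  }

  # ---- qc + normalize -------------------------------------------------
  norm <- NULL; ann <- NULL
  if (!is.null(cfg$qc)) {
    qc <- run_stage("qc", {
      thr <- do.call(qc_thresholds, cfg$qc[names(cfg$qc) %in%
                                             names(formals(qc_thresholds))])
      res <- qc_filter(data$counts, data$annotation, thr)
      p <- file.path(out_dir, "qc_report.tsv")
      write_results(res$report, p)
      manifest$stages$qc <- list(outputs = stage_hash(p))
      res
    })
    ann <- qc$annotation
    norm <- run_stage("normalize", normalize_cp10k(qc$counts))
  } else {
    ann <- data$annotation
    norm <- run_stage("normalize", normalize_cp10k(data$counts))
  }

  # ---- noise ----------------------------------------------------------
  if (!is.null(cfg$noise)) {
    run_stage("noise", {
      ncfg <- do.call(noise_config, cfg$noise[names(cfg$noise) %in%
                                                names(formals(noise_config))])
      variant <- if (is.null(cfg$noise$variant)) "centroid" else cfg$noise$variant
      res <- if (variant == "invariant") {
        inv <- select_invariant_genes(norm, ncfg)
        noise_invariant_variant(norm, ann, inv)
      } else {
        noise_to_celltype_mean(norm, ann, ncfg)
      }
      p1 <- file.path(out_dir, "noise_per_cell.tsv")
      p2 <- file.path(out_dir, "noise_summary.tsv")
      write_results(res, p1)
      write_results(summarize_noise(res), p2)
      manifest$stages$noise <- list(outputs = stage_hash(c(p1, p2)))
    })
  }

  # ---- signature scores ----------------------------------------------
  scores <- NULL
  if (!is.null(cfg$score)) {
    scores <- run_stage("score", {
      sets <- read_gene_sets(cfg$score$gene_sets)
      sc <- score_gene_sets(norm, sets,
                            n_bins = cfg$score$bins %||% 25,
                            controls_per_gene = cfg$score$controls %||% 100,
                            seed = as.integer(cfg$score$seed))
      paths <- character(0)
      for (nm in names(sc)) {
        p <- file.path(out_dir, paste0("score_", nm, ".tsv"))
        write_results(sc[[nm]], p)
        paths <- c(paths, p)
      }
      manifest$stages$score <- list(seed = cfg$score$seed,
                                     outputs = stage_hash(paths))
      sc
    })
  }

  # ---- temporal modules ----------------------------------------------
  if (!is.null(cfg$tca)) {
    run_stage("tca", {
      tc <- pseudobulk_timecourse(norm, ann,
                                  cell_type_filter = cfg$tca$cell_type,
                                  gene_filter = cfg$tca$genes)
      fit <- fuzzy_cmeans(tc, k = cfg$tca$k %||% 6, m = cfg$tca$m %||% 2,
                          seed = as.integer(cfg$tca$seed),
                          restarts = cfg$tca$restarts %||% 20)
      p1 <- file.path(out_dir, "tca_centroids.tsv")
      p2 <- file.path(out_dir, "tca_membership.tsv")
      p3 <- file.path(out_dir, "tca_trends.tsv")
      write_results(data.frame(module = seq_len(nrow(fit$centroids)),
                               fit$centroids), p1)
      write_results(data.frame(gene = rownames(fit$membership),
                               module = fit$label, fit$membership), p2)
      write_results(label_modules(fit), p3)
      manifest$stages$tca <- list(seed = cfg$tca$seed,
                                   outputs = stage_hash(c(p1, p2, p3)))
    })
  }

  # ---- differential expression ---------------------------------------
  deg <- NULL
  if (!is.null(cfg$deg)) {
    deg <- run_stage("deg", {
      tab <- deg_t_test(norm, ann, cfg$deg$group_a, cfg$deg$group_b,
                        min_pct = cfg$deg$min_pct %||% 0.1,
                        logfc_threshold = cfg$deg$logfc %||% 0.25)
      p <- file.path(out_dir, "deg.tsv")
      write_results(tab, p)
      paths <- p
      if (!is.null(cfg$deg$disease_lists)) {
        lists <- lapply(cfg$deg$disease_lists, readLines)
        ov <- overlap_disease_genes(tab, lists)
        p2 <- file.path(out_dir, "deg_overlap.tsv")
        write_results(ov, p2)
        paths <- c(paths, p2)
      }
      manifest$stages$deg <- list(outputs = stage_hash(paths))
      tab
    })
  }

  # ---- score-gated correlation ---------------------------------------
  if (!is.null(cfg$correlate)) {
    run_stage("correlate", {
      if (is.null(scores)) stop("correlate requires a score stage")
      res <- score_gene_correlation(norm, ann, cfg$correlate$gene, scores,
                                    groups = cfg$correlate$groups %||% c("T4", "T5"),
                                    score_gate = cfg$correlate$gate %||% 0.01)
      p <- file.path(out_dir, "correlation.tsv")
      write_results(res, p)
      manifest$stages$correlate <- list(outputs = stage_hash(p))
    })
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
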