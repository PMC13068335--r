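#' Default pipeline configuration
#'
#' Parameters for a self-contained synthetic end-to-end run: generator sizes,
#' keepX grid, CV geometry, FDR and connectivity thresholds, and per-stage
#' seed offsets derived from one global seed.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; stage `k` runs under `seed + 100 * k`.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("larconnect_run_"),
                                    seed = 1) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_er = 15, n_dr = 20, n_genes = 770, n_housekeeping = 40,
                    n_informative = 25, effect = 1.5,
                    sc_cell_types = c("CD4 T", "CD8 T", "B", "NK", "MNP"),
                    sc_planted = c("CD4 T", "CD8 T"), sc_effect = 1.5,
                    sc_genes = 300, sc_cells = 30,
                    perturb_compounds = 60, perturb_cells = 8,
                    perturb_genes = 200, perturb_effect = 1.5),
    select_panel = list(keepX_grid = c(5, 10, 15, 20, 25, 30), ncomp = 2,
                        repeats = 20, folds = 5, auc_threshold = 0.70),
    evaluate = list(repeats = 5, folds = 5, effect = 1.2, n_background = 100,
                    datasets = list(
                      balf_severity = list(sample_type = "balf",
                                           groups = c(healthy = 15, moderate = 15,
                                                      severe = 20)))),
    scde = list(fdr = 0.20, min_cells = 10),
    connect = list(mode = "raw", threshold = 0.5, min_cells = 3),
    ora = list(q_threshold = 0.01)
  )
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_manifest <- function(dir, stage, seed, params, outputs) {
  man <- list(
    stage = stage, seed = seed,
    parameters = params,
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    version = as.character(utils::packageVersion("larconnect"))
  )
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  man
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes simulate, select_panel, evaluate, scde, connect and ora in order
#' on synthetic data, each stage writing its tables plus a JSON manifest
#' (parameters, seed, md5 checksums) into the configured output directory.
#' Reruns with an identical config reproduce identical checksums. A stage
#' failure halts the run with the failing stage named; outputs of completed
#' stages are retained.
#'
#' @param config A configuration list ([default_pipeline_config()]) or the
#'   path to a YAML file holding one.
#' @return Invisibly, the run manifest: list of per-stage manifests plus key
#'   results (`panel`, `eval`, `de_summary`, `connectivity`, `ora`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (f in c("seed", "out_dir")) if (is.null(config[[f]]))
    stop("config missing field: ", f)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifests <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifests[[name]] <<- res$manifest
    res
  }

  # -- simulate ---------------------------------------------------------------
  sim <- run_stage("simulate", function() {
    p <- config$simulate
    cohort <- gen_challenge_cohort(
      n_er = p$n_er, n_dr = p$n_dr, n_genes = p$n_genes,
      n_housekeeping = p$n_housekeeping, n_informative = p$n_informative,
      effect = p$effect, seed = seed + 100)
    f1 <- file.path(config$out_dir, "challenge_counts.tsv")
    write_matrix_delim(cohort$expression, f1, seed = seed + 100)
    f2 <- write_tsv(classify_responders(cohort$spirometry),
                    file.path(config$out_dir, "responder_calls.tsv"))
    man <- stage_manifest(config$out_dir, "simulate", seed + 100, p, c(f1, f2))
    list(cohort = cohort, manifest = man)
  })

  # -- select_panel -----------------------------------------------------------
  sel <- run_stage("select_panel", function() {
    p <- config$select_panel
    cohort <- sim$cohort
    kept <- filter_low_abundance(cohort$expression, cohort$genes)
    logm <- log2_clip(cohort$expression)
    X <- t(logm$values[kept, , drop = FALSE])
    y <- factor(cohort$samples$group, levels = c("ER", "DR"))
    tuning <- repeated_cv_auc(X, y, keepX_grid = p$keepX_grid, ncomp = p$ncomp,
                              repeats = p$repeats, folds = p$folds,
                              seed = seed + 200)
    chosen <- select_panel(tuning, auc_threshold = p$auc_threshold)
    f1 <- write_tsv(tuning[, c("config", "n_transcripts", "mean_auc", "sd_auc")],
                    file.path(config$out_dir, "tuning.tsv"))
    if (is.null(chosen)) {
      panel <- character(0)
      outs <- f1
    } else {
      fit <- fit_splsda(X, y, ncomp = p$ncomp, keepX = chosen$keepX[[1]])
      panel <- panel_genes(fit)
      f2 <- write_tsv(data.frame(gene = panel), file.path(config$out_dir, "panel.tsv"))
      outs <- c(f1, f2)
    }
    published <- gen_biomarker_panels()
    merged <- merge_panels(c(list(PanCancer_synthetic = panel), published[-1]))
    man <- stage_manifest(config$out_dir, "select_panel", seed + 200, p, outs)
    list(panel = panel, merged = merged, tuning = tuning, chosen = chosen,
         manifest = man)
  })

  # -- evaluate ---------------------------------------------------------------
  ev <- run_stage("evaluate", function() {
    p <- config$evaluate
    panel <- if (length(sel$panel) >= 5) sel$panel else sel$merged$panel
    cohorts <- gen_bulk_cohorts(design = p$datasets, panel = panel,
                                n_background = p$n_background,
                                effect = p$effect, seed = seed + 300)
    truth <- cohorts$truth
    cohorts$truth <- NULL
    results <- list()
    for (ds in names(cohorts)) {
      spec <- p$datasets[[ds]]
      grps <- names(spec$groups)
      comparisons <- if (length(grps) >= 3)
        c(paste(grps[1], "vs", grps[3]), paste(grps[2], "vs", grps[3]))
      else paste(grps[1], "vs", grps[2])
      for (comp in comparisons) for (clf in c("plsda", "random_forest")) {
        cell <- list(dataset = ds, comparison = comp, stratum = "combined",
                     classifier = clf, panel = "combined", panel_genes = panel)
        r <- evaluate_cell(cohorts[[ds]]$expression, cohorts[[ds]]$samples,
                           cell, repeats = p$repeats, folds = p$folds,
                           seed = seed + 300)
        results[[length(results) + 1L]] <- r
      }
    }
    long <- do.call(rbind, lapply(Filter(Negate(is.null), results), function(r)
      data.frame(dataset = r$dataset, comparison = r$comparison,
                 stratum = r$stratum, classifier = r$classifier,
                 mean_auc = r$mean_auc, sd_auc = r$sd_auc,
                 n_samples = r$n_samples, stringsAsFactors = FALSE)))
    ranks <- aggregate_ranks(results, auc_min = 0.70)
    f1 <- write_tsv(long, file.path(config$out_dir, "evaluation.tsv"))
    f2 <- write_tsv(ranks, file.path(config$out_dir, "biomarker_ranks.tsv"))
    man <- stage_manifest(config$out_dir, "evaluate", seed + 300,
                          p[setdiff(names(p), "datasets")], c(f1, f2))
    list(results = results, long = long, ranks = ranks, truth = truth,
         manifest = man)
  })

  # -- scde -------------------------------------------------------------------
  de <- run_stage("scde", function() {
    p <- config$scde
    ps <- config$simulate
    panel <- if (length(sel$panel) >= 5) sel$panel else sel$merged$panel
    planted <- stats::setNames(
      lapply(ps$sc_planted, function(ct) panel[seq_len(min(20, length(panel)))]),
      ps$sc_planted)
    sc <- gen_sc_biopsy(cell_types = ps$sc_cell_types, planted_sets = planted,
                        effect = ps$sc_effect, n_genes = ps$sc_genes,
                        cells_per_stratum = ps$sc_cells, seed = seed + 400)
    res <- de_by_celltype(sc$dataset, biomarkers = panel,
                          group = "allergic_asthma", fdr = p$fdr,
                          min_cells = p$min_cells)
    f1 <- write_tsv(res$table, file.path(config$out_dir, "scde.tsv"))
    f2 <- write_tsv(res$summary, file.path(config$out_dir, "scde_summary.tsv"))
    man <- stage_manifest(config$out_dir, "scde", seed + 400, p, c(f1, f2))
    list(de = res, sets = signature_sets(res), planted = planted, manifest = man)
  })

  # -- connect ----------------------------------------------------------------
  conn <- run_stage("connect", function() {
    p <- config$connect
    ps <- config$simulate
    sets <- de$sets
    if (!length(sets$up) && !length(sets$down))
      stop("no significant signature genes to match against")
    screen <- gen_perturbation(
      n_compounds = ps$perturb_compounds, target_sets = sets,
      cell_types = c("CD4 T", "CD8 T", "Myeloid", "B", "NK"),
      effect = ps$perturb_effect, n_genes = ps$perturb_genes,
      cells_per_stratum = ps$perturb_cells, seed = seed + 500)
    sig <- build_drug_signatures(screen$dataset, vehicle = screen$truth$vehicle,
                                 min_cells = p$min_cells)
    cmap <- c("CD4 T" = "CD4 T", "CD8 T" = "CD8 T", "MNP" = "Myeloid",
              "B" = "B", "NK" = "NK")
    res <- score_all(sig, sets$up, sets$down, celltype_map = cmap,
                     report_threshold = p$threshold, mode = p$mode,
                     seed = seed + 500,
                     exclude = screen$truth$positive_controls)
    f1 <- write_tsv(res$table, file.path(config$out_dir, "connectivity.tsv"))
    f2 <- write_tsv(res$summary, file.path(config$out_dir, "connectivity_summary.tsv"))
    man <- stage_manifest(config$out_dir, "connect", seed + 500, p, c(f1, f2))
    list(result = res, truth = screen$truth, manifest = man)
  })

  # -- ora --------------------------------------------------------------------
  orares <- run_stage("ora", function() {
    p <- config$ora
    panel <- if (length(sel$panel) >= 5) sel$panel else sel$merged$panel
    universe <- unique(c(panel, sprintf("BG%04d", 1:400)))
    lib <- withr::with_seed(seed + 600, {
      sets <- c(
        list(panel_enriched = sample(panel, min(25, length(panel)))),
        stats::setNames(lapply(1:10, function(i) sample(universe, 30)),
                        sprintf("random_set_%02d", 1:10))
      )
      gene_set_library("synthetic_library", sets)
    })
    res <- ora(panel, universe, lib, q_threshold = p$q_threshold)
    f1 <- write_tsv(res[setdiff(names(res), "genes")],
                    file.path(config$out_dir, "ora.tsv"))
    man <- stage_manifest(config$out_dir, "ora", seed + 600, p, f1)
    list(result = res, manifest = man)
  })

  invisible(list(
    stages = manifests,
    panel = sel$panel, merged = sel$merged, tuning = sel$tuning,
    evaluation = ev$long, ranks = ev$ranks,
    de_summary = de$de$summary, connectivity = conn$result,
    connectivity_truth = conn$truth, ora = orares$result,
    out_dir = config$out_dir
  ))
}
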