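# End-to-end orchestration: simulate (or load) -> quantile normalize ->
# collapse probes -> per-study SAM -> signature + overlap tests ->
# pathway enrichment + enrichment map -> multi-condition consensus
# validation. Every intermediate is written to disk; the run summary is a
# machine-readable JSON. Stage seeds are derived from the global seed with
# fixed offsets, so adding a stage never perturbs earlier stages.

#' Default pipeline run configuration
#'
#' A nested list understood by [run_all()]; any part can be overridden by
#' the user's YAML/list config. Exactly one of `simulation` or `inputs`
#' (paths to expression/metadata/probe-map TSVs per study, plus a GMT) must
#' be present; the default simulates.
#'
#' @param seed Global seed.
#' @return Nested config list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    simulation = list(n_studies = 3, genes_master = 2000, universe_frac = 0.7,
                      n_per_group = 6, signature_size = 100,
                      private_de_per_study = 150, effect_size = 3.0,
                      noise_sd = 0.25),
    multicondition = list(groups = list(air = 6, lps = 5, smoke = 6,
                                        lps_smoke = 5),
                          effects = list(air = 0, lps = 2, smoke = 4,
                                         lps_smoke = 2),
                          noise_sd = 0.25),
    pathways = list(n_pathways = 50, size_min = 10, size_max = 100,
                    planted_overlap_frac = 1.0),
    sam = list(n_permutations = 200, target_fdr = 0.05,
               delta_grid_step = 0.05, pi0_mode = "one"),
    enrichment = list(alpha = 0.05, top_n = 20, similarity_threshold = 0.25),
    consensus = list(frac = 0.8, reps = 1000, n_random = 1000,
                     reps_per_signature = 50),
    collapse_method = "max_mean")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [default_run_config()].
#' @return Config list merged over the defaults.
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

log_stage <- function(logfile, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
}

#' Run the full cross-study signature pipeline
#'
#' Executes simulate/load, normalization, probe collapsing, per-study SAM,
#' signature intersection with overlap tests, pathway enrichment with
#' enrichment-map export, and consensus-clustering validation of the
#' signature on the multi-condition study. All intermediates land under
#' `out_dir`; a stage failure aborts with the failing stage named, keeping
#' partial outputs.
#'
#' @param config Path to a YAML config, or a config list (see
#'   [default_run_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the run summary list (also written as
#'   `run_summary.json`).
#' @export
run_all <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- merge_config(default_run_config(), config)
  if (!is.null(config$simulation) && !is.null(config$inputs))
    stopf("config must contain exactly one of 'simulation' or 'inputs'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  if (file.exists(logfile)) unlink(logfile)
  seed <- config$seed
  stage <- "setup"
  summary <- list(seed = seed, stages = character(0))
  res <- tryCatch({
    # ---- stage 1: data ----
    stage <- "data"
    if (!is.null(config$inputs)) {
      studies <- lapply(config$inputs$studies, function(s)
        read_study(s$expr, s$meta, s$map, s$id))
      names(studies) <- vapply(studies, function(x) x$study_id, character(1))
      truth <- NULL
      log_stage(logfile, "[data] loaded %d studies from disk", length(studies))
    } else {
      sc <- config$simulation
      cfg <- sim_config(n_studies = sc$n_studies,
                        genes_master = sc$genes_master,
                        universe_frac = sc$universe_frac,
                        n_per_group = unlist(sc$n_per_group),
                        signature_size = sc$signature_size,
                        private_de_per_study = sc$private_de_per_study,
                        effect_size = sc$effect_size, noise_sd = sc$noise_sd,
                        seed = stage_seed(seed, "simulate"))
      sim <- generate_multistudy(cfg)
      studies <- sim$studies
      truth <- sim$truth
      write_simulation(sim, file.path(out_dir, "data"))
      log_stage(logfile, "[data] simulated %d studies (%d master genes)",
                length(studies), sc$genes_master)
    }

    # ---- stage 2: preprocess ----
    stage <- "preprocess"
    gene_mats <- lapply(studies, function(st) {
      norm <- quantile_normalize(st$exprs)
      st$exprs <- norm
      collapse_probes(st, method = config$collapse_method)
    })
    for (id in names(gene_mats))
      write_expression_tsv(gene_mats[[id]],
                           file.path(out_dir, paste0(id, "_gene_matrix.tsv")))
    log_stage(logfile, "[preprocess] quantile-normalized and collapsed %d studies (%s)",
              length(gene_mats), config$collapse_method)

    # ---- stage 3: per-study SAM ----
    stage <- "sam"
    sam_cfg_base <- config$sam
    fits <- list()
    for (i in seq_along(gene_mats)) {
      id <- names(gene_mats)[i]
      scfg <- sam_config(n_permutations = sam_cfg_base$n_permutations,
                         target_fdr = sam_cfg_base$target_fdr,
                         delta_grid_step = sam_cfg_base$delta_grid_step,
                         pi0_mode = sam_cfg_base$pi0_mode,
                         seed = stage_seed(seed, "sam") + i)
      fits[[id]] <- sam_fit(gene_mats[[id]], studies[[id]]$groups, scfg)
      write_sam_result(fits[[id]],
                       file.path(out_dir, paste0("sam_", id, ".tsv")),
                       file.path(out_dir, paste0("sam_", id, ".json")))
      log_stage(logfile, "[sam] %s: %d called at delta %.2f (FDR %.4f)",
                id, sum(fits[[id]]$genes$called), fits[[id]]$delta_selected,
                fits[[id]]$fdr_estimate)
    }

    # ---- stage 4: signature + overlap ----
    stage <- "integrate"
    universes <- lapply(studies, study_universe)
    background <- build_common_background(universes)
    called <- lapply(fits, called_genes)
    signature <- intersect_signature(called, background,
                                     provenance = lapply(fits, function(f)
                                       list(delta = f$delta_selected,
                                            fdr = f$fdr_estimate)))
    report <- overlap_report(signature, universes)
    sym <- key_symbol_map(lapply(studies, function(s) s$probe_map))
    write_signature(signature, report, out_dir, symbol_map = sym)
    log_stage(logfile, "[integrate] signature: %d genes on a %d-gene background",
              length(signature$genes), length(background))

    # ---- stage 5: enrichment ----
    stage <- "enrichment"
    pw <- config$pathways
    gmt <- if (!is.null(config$inputs$gmt)) read_gmt(config$inputs$gmt)
    else generate_pathway_db(
      background, n_pathways = pw$n_pathways,
      size_range = c(pw$size_min, pw$size_max),
      planted = list(list(name = "PLANTED_SIGNATURE_PATHWAY",
                          source = signature$genes,
                          overlap_frac = pw$planted_overlap_frac)),
      seed = stage_seed(seed, "pathways"))
    write_gmt(gmt, file.path(out_dir, "pathways.gmt"))
    enr <- list()
    for (id in names(fits)) {
      enr[[id]] <- hypergeom_enrich(intersect(called[[id]], universes[[id]]),
                                    universes[[id]], gmt)
      utils::write.table(enr[[id]],
                         file.path(out_dir, paste0("enrichment_", id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    emap <- merge_top_terms(enr, gmt, top_n = config$enrichment$top_n,
                            alpha = config$enrichment$alpha,
                            similarity_threshold =
                              config$enrichment$similarity_threshold)
    write_enrichment_map(emap, out_dir)
    log_stage(logfile, "[enrichment] %d map terms, %d edges across %d studies",
              nrow(emap$nodes), nrow(emap$edges), length(enr))

    # ---- stage 6: consensus validation ----
    stage <- "evaluate"
    mcc <- config$multicondition
    mc <- generate_multicondition(
      signature = if (length(signature$genes) >= 5) signature$genes
      else utils::head(background, 50),  # degenerate fallback keeps stage runnable
      groups = unlist(mcc$groups), effects = unlist(mcc$effects),
      noise_sd = mcc$noise_sd, seed = stage_seed(seed, "multicondition"))
    mc_mat <- collapse_probes(mc, method = config$collapse_method)
    cons_sig <- if (length(signature$genes) >= 5) signature$genes
    else utils::head(background, 50)
    cc <- config$consensus
    cons <- consensus_cluster(mc_mat, mc$groups, cons_sig, frac = cc$frac,
                              reps = cc$reps,
                              seed = stage_seed(seed, "consensus"))
    base <- random_signature_baseline(
      mc_mat, mc$groups, size = length(intersect(cons_sig, rownames(mc_mat))),
      n_signatures = cc$n_random,
      reps_per_signature = cc$reps_per_signature, frac = cc$frac,
      seed = stage_seed(seed, "baseline"))
    utils::write.table(
      data.frame(sample_id = rownames(cons$consensus_matrix),
                 cons$consensus_matrix, check.names = FALSE),
      file.path(out_dir, "consensus_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    fc <- fold_change_table(mc_mat, mc$groups,
                            cons_sig, reference = names(mcc$groups)[1])
    write_expression_tsv(fc, file.path(out_dir, "fold_change_table.tsv"))
    hm <- center_genes(mc_mat[intersect(cons_sig, rownames(mc_mat)), ,
                              drop = FALSE])
    write_expression_tsv(hm, file.path(out_dir, "heatmap_matrix.tsv"))
    jsonlite::write_json(
      list(signature_accuracy = cons$signature_accuracy,
           mean_within_consensus = cons$mean_within_consensus,
           mean_baseline = base$mean_baseline,
           config = cons$config),
      file.path(out_dir, "consensus_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage(logfile, "[evaluate] signature accuracy %.4f vs baseline %.4f",
              cons$signature_accuracy, base$mean_baseline)

    # ---- summary ----
    stage <- "summary"
    summary <- list(
      seed = seed,
      studies = names(studies),
      de_counts = lapply(fits, function(f) sum(f$genes$called)),
      sam = lapply(fits, function(f)
        list(s0 = f$s0, delta = f$delta_selected, fdr = f$fdr_estimate)),
      background_size = length(background),
      signature_size = length(signature$genes),
      overlap_tests = lapply(report$tests, function(t)
        list(label = t$label, arity = t$arity, universe_N = t$universe_N,
             observed_t = t$observed_t, p_value = t$p_value,
             log10_p = t$log10_p)),
      top_pathways = lapply(enr, function(tb) utils::head(tb$pathway, 5)),
      consensus = list(signature_accuracy = cons$signature_accuracy,
                       mean_baseline = base$mean_baseline),
      signature_recovery = if (!is.null(truth))
        length(intersect(signature$genes, truth$signature_genes)) /
          length(truth$signature_genes) else NULL,
      package_version = as.character(utils::packageVersion("endosig")))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage(logfile, "[summary] run_summary.json written")
    summary
  }, error = function(e) {
    stopf("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
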