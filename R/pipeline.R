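# End-to-end pipeline: simulate -> (correct | pca) -> select -> evaluate,
# driven by a YAML/list config with a master seed and per-stage derived
# seeds, writing a deterministic artifact tree plus a resolved-config copy
# and a seed manifest.

.pipeline_defaults <- function() {
  list(
    out_dir = "batchbench_run",
    seed = 1L,
    n_proteins = 1500L,
    samples_per_class = 4L,
    diff_fraction = 0.20,
    class_menu = effect_menu_default(),
    batch_menu = effect_menu_default(),
    correction = "combat",          # combat | quantile | linear | none
    preselect_fraction = 0.20,
    n_components = 5L,
    n_pseudo = 101L,
    purity = 1.0,
    methods = c("sp", "sp_fdr", "he", "snet", "fsnet"),
    fdr = 0.05,
    alpha_top = 0.10,
    alpha_lo = 0.20,
    beta = 0.5,
    n_permutations = 1000L,
    alpha_sig = 0.05
  )
}

# per-stage seeds derived from the master seed by a fixed counter scheme,
# so stages can be rerun independently
.stage_seeds <- function(seed) {
  stats::setNames(as.integer(seed) + c(0L, 100L, 200L, 300L),
                  c("simulate", "pseudocomplexes", "select", "extra"))
}

#' Validate and resolve a pipeline configuration
#'
#' Unknown keys are rejected with a nearest-key suggestion; missing keys take
#' their defaults.
#'
#' @param config named list (e.g. from [yaml::read_yaml()]).
#' @return resolved config list with all keys present.
#' @export
resolve_config <- function(config = list()) {
  defaults <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    d <- utils::adist(unknown[1], names(defaults))
    stop("unknown config key '", unknown[1], "'; did you mean '",
         names(defaults)[which.min(d)], "'?", call. = FALSE)
  }
  utils::modifyList(defaults, config)
}

#' Run the full benchmark pipeline
#'
#' Simulates a clean/noisy dataset pair, applies the configured correction,
#' runs the PCA diagnosis (association table, component scores, cluster
#' assignments after dropping batch-dominated components), runs the
#' configured selectors against pseudo-complex ground truth, and writes all
#' stage outputs as tab-delimited files under `out_dir` together with
#' `config.yaml` and `seed_manifest.json`. On error a `FAILED` marker file
#' is left next to any partial outputs.
#'
#' @param config named list or path to a YAML file.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- resolve_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- .stage_seeds(cfg$seed)
  ok <- FALSE
  on.exit(if (!ok) file.create(file.path(out, "FAILED")))

  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  jsonlite::write_json(as.list(seeds), file.path(out, "seed_manifest.json"),
                       auto_unbox = TRUE)

  scfg <- sim_config(n_proteins = cfg$n_proteins,
                     samples_per_class = cfg$samples_per_class,
                     diff_fraction = cfg$diff_fraction,
                     class_menu = cfg$class_menu, batch_menu = cfg$batch_menu,
                     seed = seeds[["simulate"]])
  ds <- simulate_dataset(scfg)
  write_dataset(ds$clean, ds$meta, ds$truth, file.path(out, "clean"))
  write_dataset(ds$noisy, ds$meta, ds$truth, file.path(out, "noisy"))

  corrected <- correct_batch(ds$noisy, ds$meta, cfg$correction)
  write_expression_table(corrected, file.path(out, "corrected.tsv"))

  xr <- variance_preselect(ds$noisy, cfg$preselect_fraction)
  p <- run_pca(xr)
  assoc <- pc_association(p, ds$meta, cfg$n_components)
  utils::write.table(assoc$table, file.path(out, "pc_association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assoc$long, file.path(out, "pc_scores_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  drop <- assoc$table$component[assoc$table$dominant_factor == "batch"]
  if (!length(drop) && assoc$table$dominant_factor[1] %in% c("batch", "both"))
    drop <- 1L
  feats <- remove_pcs(p, drop)
  cl <- cluster_samples(feats, k = length(unique(ds$meta$class)))
  utils::write.table(
    data.frame(sample_id = names(cl$labels), cluster = cl$labels),
    file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  rb <- rbna_config(cfg$alpha_top, cfg$alpha_lo, cfg$beta,
                    cfg$n_permutations, cfg$alpha_sig)
  cset <- make_pseudocomplexes(ds$clean, ds$truth, n = cfg$n_pseudo,
                               purity = cfg$purity,
                               seed = seeds[["pseudocomplexes"]])
  write_complexes(cset, file.path(out, "pseudocomplexes.tsv"))

  metrics <- list()
  sp_fdr_ids <- NULL
  for (method in cfg$methods) {
    sel <- switch(method,
      sp = sp_select(ds$noisy, ds$meta, fdr = NA),
      sp_fdr = sp_select(ds$noisy, ds$meta, fdr = cfg$fdr),
      he = {
        if (is.null(sp_fdr_ids))
          sp_fdr_ids <- selected_ids(sp_select(ds$noisy, ds$meta, fdr = cfg$fdr))
        he_select(sp_fdr_ids, cset, rownames(ds$noisy), rb$alpha_sig)
      },
      snet = rbna_select(ds$noisy, ds$meta, cset, rb, fuzzy = FALSE,
                         seed = seeds[["select"]]),
      fsnet = rbna_select(ds$noisy, ds$meta, cset, rb, fuzzy = TRUE,
                          seed = seeds[["select"]]),
      stop("unknown method: ", method, call. = FALSE))
    if (method == "sp_fdr") sp_fdr_ids <- selected_ids(sel)
    utils::write.table(sel$table,
                       file.path(out, paste0("selection_", method, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    m <- if (sel$level == "protein")
      precision_recall_f(selected_ids(sel), ds$truth$protein_id, "protein")
    else complex_level_eval(sel, cset)
    metrics[[method]] <- cbind(data.frame(method = method), m)
  }
  utils::write.table(do.call(rbind, metrics), file.path(out, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- TRUE
  invisible(out)
}
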