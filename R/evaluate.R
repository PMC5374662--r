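#' Precision, recall and F-score of a feature set
#'
#' With zero selected features, precision is reported as 1 (flagged via
#' `n_selected = 0`), recall as 0 and F as 0.
#'
#' @param selected character vector of selected feature ids.
#' @param truth character vector of true feature ids (non-empty).
#' @param level `"protein"` or `"complex"` (bookkeeping only).
#' @return a one-row `data.frame`: `precision`, `recall`, `f_score`,
#'   `n_selected`, `n_truth`, `level`.
#' @export
precision_recall_f <- function(selected, truth, level = "protein") {
  if (!length(truth)) stop("empty truth set", call. = FALSE)
  selected <- unique(selected); truth <- unique(truth)
  tp <- length(intersect(selected, truth))
  precision <- if (length(selected)) tp / length(selected) else 1
  recall <- tp / length(truth)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  data.frame(precision = precision, recall = recall, f_score = f,
             n_selected = length(selected), n_truth = length(truth),
             level = level, stringsAsFactors = FALSE)
}

#' Jaccard coefficient of two feature sets
#'
#' @param a,b character vectors; their union must be non-empty.
#' @return |a n b| / |a u b|.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("both sets are empty", call. = FALSE)
  length(intersect(a, b)) / u
}

#' Complex-level evaluation against TP/TN labels
#'
#' @param sel a complex-level `selection_result`.
#' @param complexes the labelled `complex_set` it was computed on; every
#'   selected complex must carry a TP or TN label.
#' @return an `EvalMetrics` row (see [precision_recall_f()]).
#' @export
complex_level_eval <- function(sel, complexes) {
  stopifnot(inherits(sel, "selection_result"))
  if (sel$level != "complex")
    stop("expected a complex-level selection result", call. = FALSE)
  ids <- selected_ids(sel)
  labels <- complexes$truth_label[match(ids, complexes$complex_id)]
  if (any(is.na(labels)) || any(labels == "unknown"))
    stop("selected complex(es) without TP/TN label", call. = FALSE)
  truth <- complexes$complex_id[complexes$truth_label == "TP"]
  precision_recall_f(ids, truth, level = "complex")
}

#' Benchmark configuration
#'
#' @param replicates number of simulated replicate datasets.
#' @param sim a [sim_config()] template; each replicate uses
#'   `seed = sim$seed + replicate - 1`.
#' @param conditions data conditions: any of `"no_batch"`, `"batch"`,
#'   `"combat"`, `"quantile"`, `"linear"` (corrections apply to the noisy
#'   matrix).
#' @param methods any of `"sp"`, `"sp_fdr"`, `"he"`, `"snet"`, `"fsnet"`.
#' @param purities TP pseudo-complex purity levels.
#' @param n_pseudo pseudo-complexes per label.
#' @param rbna an [rbna_config()].
#' @param fdr SP FDR cutoff for the `"sp_fdr"` method and for HE's input set.
#' @return a list of class `benchmark_config`.
#' @export
benchmark_config <- function(replicates = 20L, sim = sim_config(),
                             conditions = c("no_batch", "batch", "combat",
                                            "quantile", "linear"),
                             methods = c("sp", "sp_fdr", "he", "snet", "fsnet"),
                             purities = c(1, 0.75, 0.5), n_pseudo = 101L,
                             rbna = rbna_config(), fdr = 0.05) {
  structure(list(replicates = as.integer(replicates), sim = sim,
                 conditions = conditions, methods = methods,
                 purities = purities, n_pseudo = as.integer(n_pseudo),
                 rbna = rbna, fdr = fdr),
            class = "benchmark_config")
}

.condition_matrix <- function(ds, condition) {
  switch(condition,
    no_batch = ds$clean,
    batch = ds$noisy,
    combat = correct_batch(ds$noisy, ds$meta, "combat"),
    quantile = quantile_normalize(ds$noisy),
    linear = linear_scale(ds$noisy),
    stop("unknown condition: ", condition, call. = FALSE))
}

#' Run the replicate benchmark
#'
#' For every replicate x condition x method (x purity, for complex-based
#' methods) computes protein-level and, where applicable, complex-level
#' precision/recall/F against the simulated ground truth. Complex-based
#' methods use pseudo-complexes built from the clean matrix, so the same
#' complex vector is evaluated under every condition.
#'
#' @param config a [benchmark_config()].
#' @param verbose print per-replicate progress.
#' @return a long-format `data.frame` with one row per metric evaluation
#'   (`replicate`, `condition`, `method`, `purity`, `level`, `precision`,
#'   `recall`, `f_score`, `n_selected`, `n_truth`).
#' @export
run_benchmark <- function(config = benchmark_config(), verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  rows <- list()
  add <- function(rep, condition, method, purity, metrics) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(replicate = rep, condition = condition, method = method,
                 purity = purity, stringsAsFactors = FALSE), metrics)
  }
  complex_methods <- intersect(config$methods, c("he", "snet", "fsnet"))
  for (r in seq_len(config$replicates)) {
    cfg <- config$sim
    cfg$seed <- config$sim$seed + r - 1L
    ds <- simulate_dataset(cfg)
    truth_ids <- ds$truth$protein_id
    cpx <- if (length(complex_methods)) {
      lapply(config$purities, function(pu)
        make_pseudocomplexes(ds$clean, ds$truth, n = config$n_pseudo,
                             purity = pu, seed = cfg$seed + 700L))
    }
    for (condition in config$conditions) {
      x <- .condition_matrix(ds, condition)
      sp_fdr_sel <- NULL
      for (method in intersect(config$methods, c("sp", "sp_fdr"))) {
        sel <- sp_select(x, ds$meta, fdr = if (method == "sp") NA else config$fdr)
        if (method == "sp_fdr") sp_fdr_sel <- selected_ids(sel)
        add(r, condition, method, NA_real_,
            precision_recall_f(selected_ids(sel), truth_ids, "protein"))
      }
      if (length(complex_methods) && is.null(sp_fdr_sel))
        sp_fdr_sel <- selected_ids(sp_select(x, ds$meta, fdr = config$fdr))
      for (pi in seq_along(config$purities)) {
        pu <- config$purities[pi]
        if (!length(complex_methods)) break
        cset <- cpx[[pi]]
        tp_proteins <- unique(unlist(
          cset$members[cset$truth_label == "TP"], use.names = FALSE))
        for (method in complex_methods) {
          sel <- switch(method,
            he = he_select(sp_fdr_sel, cset, rownames(x),
                           alpha_sig = config$rbna$alpha_sig),
            snet = rbna_select(x, ds$meta, cset, config$rbna, fuzzy = FALSE,
                               seed = cfg$seed + 31L),
            fsnet = rbna_select(x, ds$meta, cset, config$rbna, fuzzy = TRUE,
                                seed = cfg$seed + 31L))
          add(r, condition, method, pu, complex_level_eval(sel, cset))
          prot <- proteins_from_complexes(sel, cset)
          add(r, condition, method, pu,
              precision_recall_f(prot, intersect(tp_proteins, truth_ids),
                                 "protein"))
        }
      }
    }
    if (verbose) message("replicate ", r, "/", config$replicates, " done")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round a benchmark table for reporting
#'
#' @param tab a [run_benchmark()] table.
#' @param digits decimal places (default 2, the conventional presentation).
#' @return the table with metric columns rounded.
#' @export
format_benchmark <- function(tab, digits = 2L) {
  for (col in c("precision", "recall", "f_score"))
    tab[[col]] <- round(tab[[col]], digits)
  tab
}
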