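#' Variance-based protein preselection
#'
#' Keeps the `ceil(fraction * n_proteins)` proteins with the highest
#' across-sample variance, preserving input row order. Ties at the cutoff are
#' broken by protein id (lexicographic).
#'
#' @param x expression matrix.
#' @param fraction fraction of proteins to retain (0 < fraction <= 1).
#' @return the reduced expression matrix.
#' @export
variance_preselect <- function(x, fraction = 0.20) {
  validate_expression_matrix(x)
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(x))
  v <- apply(x, 1, stats::var)
  ord <- order(-v, rownames(x))
  keep <- sort(ord[seq_len(k)])
  x[keep, , drop = FALSE]
}

#' Principal component analysis of samples
#'
#' SVD of the per-protein-centered matrix with samples as observations. No
#' unit-variance scaling is applied by default, so that the variance ranking
#' used for preselection carries through to the components.
#'
#' @param x expression matrix (proteins x samples).
#' @param center center each protein across samples (default `TRUE`).
#' @param scale divide each protein by its standard deviation (default
#'   `FALSE`).
#' @return an object of class `pca_result` with `scores` (samples x
#'   components), `loadings` (proteins x components, unit-norm columns),
#'   `variance_explained`, and `retained_protein_ids`.
#' @export
run_pca <- function(x, center = TRUE, scale = FALSE) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L) stop("PCA needs >= 2 samples", call. = FALSE)
  obs <- t(x)                      # samples x proteins
  obs <- scale(obs, center = center, scale = scale)
  if (all(abs(obs) < 1e-12))
    stop("matrix is constant after centering; PCA undefined", call. = FALSE)
  sv <- svd(obs)
  d2 <- sv$d^2
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  loadings <- sv$v
  rownames(loadings) <- rownames(x)
  colnames(loadings) <- colnames(scores)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = d2 / sum(d2),
                 retained_protein_ids = rownames(x),
                 center = attr(obs, "scaled:center"),
                 scale = attr(obs, "scaled:scale")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", nrow(x$loadings),
      "proteins;", "variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_explained, 3)),
            collapse = ", "), "...\n")
  invisible(x)
}

.group_test_p <- function(score, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("grouping factor has a single level", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  if (stats::sd(score) < 1e-12) return(list(stat = 0, p = 1))
  gm <- tapply(score, g, mean)
  gs <- tapply(score, g, stats::sd)
  if (all(gs < 1e-12)) {
    # degenerate: no within-group spread; perfect separation when means differ
    if (diff(range(gm)) > 1e-12) return(list(stat = Inf, p = 0))
    return(list(stat = 0, p = 1))
  }
  if (nlevels(g) == 2L) {
    tt <- tryCatch(stats::t.test(score ~ g), error = function(e) NULL)
    if (is.null(tt)) return(list(stat = 0, p = 1))
    list(stat = unname(tt$statistic), p = tt$p.value)
  } else {
    ow <- tryCatch(stats::oneway.test(score ~ g), error = function(e) NULL)
    if (is.null(ow) || is.na(ow$p.value)) return(list(stat = 0, p = 1))
    list(stat = unname(ow$statistic), p = ow$p.value)
  }
}

#' Class/batch association of principal components
#'
#' For each of the first `n_components` components, tests the sample scores
#' split by class and split by batch (two-sample t-test; Welch ANOVA when
#' more than two batches), and classifies the dominant factor: a factor with
#' p < `alpha` while the other has p >= `alpha` dominates; both below gives
#' `"both"`, otherwise `"neither"`. This automates the reading of paired
#' per-component boxplots.
#'
#' @param p a [run_pca()] result.
#' @param meta sample metadata covering the scored samples.
#' @param n_components number of leading components to test.
#' @param alpha dominance significance threshold (default 0.01).
#' @return list with `table` (per-component statistics, p-values,
#'   `dominant_factor`) and `long` (boxplot-ready long table: component,
#'   sample, score, class, batch).
#' @export
pc_association <- function(p, meta, n_components = 5L, alpha = 0.01) {
  stopifnot(inherits(p, "pca_result"))
  ids <- rownames(p$scores)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- meta[match(ids, meta$sample_id), ]
  n_components <- min(n_components, ncol(p$scores))
  rows <- lapply(seq_len(n_components), function(j) {
    s <- p$scores[, j]
    cl <- .group_test_p(s, meta$class)
    ba <- .group_test_p(s, meta$batch)
    dominant <-
      if (cl$p < alpha && ba$p >= alpha) "class"
      else if (ba$p < alpha && cl$p >= alpha) "batch"
      else if (cl$p < alpha && ba$p < alpha) "both"
      else "neither"
    data.frame(component = j, class_stat = cl$stat, class_p = cl$p,
               batch_stat = ba$stat, batch_p = ba$p,
               variance_explained = p$variance_explained[j],
               dominant_factor = dominant, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, lapply(seq_len(n_components), function(j)
    data.frame(component = j, sample_id = ids, score = p$scores[, j],
               class = meta$class, batch = meta$batch,
               stringsAsFactors = FALSE)))
  rownames(long) <- NULL
  list(table = do.call(rbind, rows), long = long)
}

#' Remove principal components
#'
#' Drops the given score columns (typically batch-dominated leading
#' components) and returns the remaining scores as a samples x features
#' matrix for clustering or prediction.
#'
#' @param p a [run_pca()] result.
#' @param drop integer indices of components to remove (may be empty).
#' @return score matrix without the dropped columns; attributes `"dropped"`
#'   and `"dropped_variance"` record what was removed.
#' @export
remove_pcs <- function(p, drop = integer(0)) {
  stopifnot(inherits(p, "pca_result"))
  drop <- as.integer(drop)
  if (length(drop) && (any(drop < 1L) || any(drop > ncol(p$scores))))
    stop("invalid component index in 'drop'", call. = FALSE)
  keep <- setdiff(seq_len(ncol(p$scores)), drop)
  if (!length(keep)) stop("cannot drop all components", call. = FALSE)
  out <- p$scores[, keep, drop = FALSE]
  attr(out, "dropped") <- sort(unique(drop))
  attr(out, "dropped_variance") <- sum(p$variance_explained[unique(drop)])
  out
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering (Ward's linkage on Euclidean distances) of a
#' samples x features matrix, cut at `k` clusters.
#'
#' @param features numeric matrix, samples in rows.
#' @param k number of clusters.
#' @return list with `labels` (named integer cluster assignment) and `tree`
#'   (the `hclust` object).
#' @export
cluster_samples <- function(features, k = 2L) {
  features <- as.matrix(features)
  if (k > nrow(features)) stop("k exceeds the number of samples", call. = FALSE)
  tree <- stats::hclust(stats::dist(features), method = "ward.D2")
  list(labels = stats::cutree(tree, k = k), tree = tree)
}

#' Trace proteins behind a principal component
#'
#' Returns the proteins that load strongly and exclusively on a component:
#' strength means |loading| exceeds the mean of the absolute loadings on
#' that component by more than `strength_sd` standard deviations (default 0,
#' i.e. above-average |loading|); exclusivity means the component holds the
#' protein's maximal variance contribution (|loading| scaled by the
#' component's singular value — loadings are unit-norm per component, so raw
#' loadings are not comparable across components) among the first
#' `n_exclusive` components.
#'
#' @param p a [run_pca()] result.
#' @param component component index.
#' @param strength_sd strength threshold in SD units above the mean
#'   absolute loading (default 0).
#' @param n_exclusive number of leading components competing for exclusivity
#'   (default `min(5, n_components)`).
#' @return character vector of protein ids (possibly empty).
#' @export
traceback_proteins <- function(p, component = 1L, strength_sd = 0,
                               n_exclusive = 5L) {
  stopifnot(inherits(p, "pca_result"))
  if (component < 1L || component > ncol(p$loadings))
    stop("invalid component", call. = FALSE)
  al <- abs(p$loadings)
  strong <- al[, component] > mean(al[, component]) + strength_sd * stats::sd(al[, component])
  k <- min(n_exclusive, ncol(al))
  sv <- sqrt(colSums(p$scores^2))        # component singular values
  contrib <- sweep(al[, seq_len(k), drop = FALSE], 2, sv[seq_len(k)], `*`)
  exclusive <- max.col(contrib, ties.method = "first") == component
  rownames(p$loadings)[strong & exclusive]
}

#' Feature set from the recomputed first component
#'
#' Traces the proteins behind the original (typically batch-dominated) first
#' component, removes them from the matrix, reruns PCA, and traces the new
#' first component. The returned set targets the class signal that surfaces
#' once the dominant technical component is stripped.
#'
#' @param x expression matrix (apply [variance_preselect()] beforehand if
#'   desired).
#' @param strength_sd,n_exclusive traceback thresholds.
#' @return character vector of protein ids; the original first-component set
#'   is attached as attribute `"pc1_set"`.
#' @export
minus_pc1_features <- function(x, strength_sd = 0, n_exclusive = 5L) {
  p1 <- run_pca(x)
  set1 <- traceback_proteins(p1, 1L, strength_sd, n_exclusive)
  remaining <- setdiff(rownames(x), set1)
  if (length(remaining) < 3L)
    stop("fewer than 3 proteins remain after removing the first-component set",
         call. = FALSE)
  p2 <- run_pca(x[remaining, , drop = FALSE])
  set2 <- traceback_proteins(p2, 1L, strength_sd, n_exclusive)
  attr(set2, "pc1_set") <- set1
  set2
}

#' Top proteins by class t-statistic
#'
#' Ranks proteins by descending absolute two-sample t-statistic across
#' classes and returns the top `n` (ties broken by protein id).
#'
#' @param x expression matrix.
#' @param meta sample metadata with two classes.
#' @param n number of proteins to return.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return character vector of `n` protein ids.
#' @export
top_n_by_tstat <- function(x, meta, n, var_equal = TRUE) {
  stopifnot(n <= nrow(x))
  meta <- match_metadata(x, meta)
  tt <- row_t_test(x, meta$class == unique(meta$class)[1], var_equal = var_equal)
  st <- abs(tt$statistic)
  st[is.na(st)] <- 0
  ord <- order(-st, rownames(x))
  rownames(x)[ord[seq_len(n)]]
}

#' Predict class labels by co-clustering with labelled samples
#'
#' Pools known and unknown samples, preselects high-variance proteins, runs
#' PCA, drops batch-dominated leading components (batch association uses all
#' samples, class association only the labelled ones), clusters the
#' remaining component scores, and assigns each unknown sample the majority
#' class of the labelled samples in its cluster.
#'
#' @param known expression matrix of labelled samples.
#' @param known_meta metadata for `known` (class + batch).
#' @param unknown expression matrix of unlabelled samples (same proteins).
#' @param unknown_batch batch label(s) for the unknown samples.
#' @param preselect variance preselection fraction.
#' @param log2_transform analyse log2(x+1) (default `TRUE`).
#' @param n_components leading components examined for batch dominance.
#' @param alpha dominance threshold.
#' @return named character vector of predicted labels for the unknown
#'   samples (`"unresolved"` for clusters without labelled members).
#' @export
predict_labels_by_coclustering <- function(known, known_meta, unknown,
                                           unknown_batch = "new",
                                           preselect = 0.20,
                                           log2_transform = TRUE,
                                           n_components = 5L, alpha = 0.01) {
  if (!ncol(unknown)) return(stats::setNames(character(0), character(0)))
  if (!identical(rownames(known), rownames(unknown)))
    stop("known and unknown matrices must share the protein space", call. = FALSE)
  known_meta <- match_metadata(known, known_meta)
  pooled <- cbind(known, unknown)
  meta_all <- rbind(known_meta,
                    sample_metadata(colnames(unknown),
                                    rep_len("?", ncol(unknown)),
                                    rep_len(unknown_batch, ncol(unknown))))
  if (log2_transform) pooled <- log2(pooled + 1)
  xr <- variance_preselect(pooled, preselect)
  p <- run_pca(xr)
  n_components <- min(n_components, ncol(p$scores))
  is_known <- rownames(p$scores) %in% known_meta$sample_id
  drop <- integer(0)
  for (j in seq_len(n_components)) {
    s <- p$scores[, j]
    ba <- .group_test_p(s, meta_all$batch)
    cl <- .group_test_p(s[is_known],
                        known_meta$class[match(rownames(p$scores)[is_known],
                                               known_meta$sample_id)])
    if (ba$p < alpha && cl$p >= alpha) drop <- c(drop, j)
  }
  feats <- remove_pcs(p, drop)
  k <- length(unique(known_meta$class))
  cl <- cluster_samples(feats, k = k)
  preds <- character(0)
  for (cluster in unique(cl$labels)) {
    members <- names(cl$labels)[cl$labels == cluster]
    lab_known <- known_meta$class[known_meta$sample_id %in% members]
    lab <- if (length(lab_known)) names(which.max(table(lab_known))) else "unresolved"
    unk <- setdiff(members, known_meta$sample_id)
    preds[unk] <- lab
  }
  preds[colnames(unknown)]
}

#' Variance preselection + PCA workflow
#'
#' The standard entry into the component-level analysis: optional log2(x+1)
#' transform (multiplicative class and batch effects are additive on the log
#' scale, so the leading components align with them), variance-based
#' preselection, then PCA.
#'
#' @param x expression matrix (abundance scale).
#' @param preselect_fraction fraction of top-variance proteins retained.
#' @param log2_transform analyse log2(x+1) instead of raw abundances
#'   (default `TRUE`).
#' @return a [run_pca()] result on the preselected (transformed) matrix.
#' @export
pca_workflow <- function(x, preselect_fraction = 0.20, log2_transform = TRUE) {
  if (log2_transform) x <- log2(x + 1)
  run_pca(variance_preselect(x, preselect_fraction))
}

#' t-test feature selection within a protein set
#'
#' Applies the class t-test only to the given proteins (typically a
#' component traceback set) and keeps those with p below `alpha`. Restricting
#' the test to component-associated proteins screens out features whose
#' variation is technical: proteins tracing a batch component carry no class
#' signal and are eliminated here, which is what gives component-restricted
#' selection its high precision.
#'
#' @param x expression matrix.
#' @param meta sample metadata with two classes.
#' @param proteins candidate protein ids (subset of `rownames(x)`).
#' @param alpha raw p-value cutoff (default 0.05).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return protein-level `selection_result` over the candidate set.
#' @export
pc_feature_select <- function(x, meta, proteins, alpha = 0.05,
                              var_equal = TRUE) {
  proteins <- intersect(proteins, rownames(x))
  if (length(proteins) < 1L)
    return(.selection_result(
      data.frame(feature_id = character(0), statistic = numeric(0),
                 p = numeric(0), p_adj = numeric(0), selected = logical(0)),
      "protein"))
  meta <- match_metadata(x, meta)
  classes <- unique(meta$class)
  tt <- suppressWarnings(row_t_test(x[proteins, , drop = FALSE],
                                    meta$class == classes[1],
                                    var_equal = var_equal))
  tab <- data.frame(feature_id = proteins, statistic = tt$statistic,
                    p = tt$p, p_adj = stats::p.adjust(tt$p, "BH"),
                    selected = tt$p <= alpha, stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, tab$feature_id), ]
  rownames(tab) <- NULL
  .selection_result(tab, "protein")
}
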