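#' Row-wise two-sample t-test
#'
#' Vectorized per-protein t-test between two sample groups. Proteins with
#' zero variance in both groups get statistic 0 and p = 1 (with a warning
#' from the callers that care).
#'
#' @param x expression matrix.
#' @param group1 logical vector marking the first group's columns.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame with `statistic`, `df`, `p`.
#' @export
row_t_test <- function(x, group1, var_equal = TRUE) {
  stopifnot(length(group1) == ncol(x))
  a <- x[, group1, drop = FALSE]
  b <- x[, !group1, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples", call. = FALSE)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(stat), df)
  zero <- se == 0
  stat[zero] <- 0
  p[zero] <- 1
  data.frame(statistic = stat, df = df, p = p, row.names = rownames(x))
}

.selection_result <- function(table, level, scores = NULL) {
  structure(list(table = table, level = level, scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result (", x$level, " level): ", nrow(x$table),
      " features, ", sum(x$table$selected), " selected\n", sep = "")
  invisible(x)
}

#' Selected feature ids
#' @param sel a `selection_result`.
#' @return character vector of selected feature ids.
#' @export
selected_ids <- function(sel) {
  stopifnot(inherits(sel, "selection_result"))
  sel$table$feature_id[sel$table$selected]
}

#' Single-protein t-test selection (SP)
#'
#' Per-protein two-sample t-test across classes with optional
#' Benjamini-Hochberg FDR control.
#'
#' @param x expression matrix.
#' @param meta sample metadata with two classes.
#' @param fdr BH-adjusted significance cutoff, or `NA` to select on the raw
#'   p-value at 0.05.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return protein-level `selection_result`, ranked by p-value.
#' @export
sp_select <- function(x, meta, fdr = 0.05, var_equal = TRUE) {
  meta <- match_metadata(x, meta)
  classes <- unique(meta$class)
  if (length(classes) != 2L) stop("SP needs exactly two classes", call. = FALSE)
  tt <- row_t_test(x, meta$class == classes[1], var_equal = var_equal)
  if (any(tt$p == 1 & tt$statistic == 0))
    warning("protein(s) with zero variance in both classes: p set to 1",
            call. = FALSE)
  p_adj <- stats::p.adjust(tt$p, method = "BH")
  selected <- if (is.na(fdr)) tt$p <= 0.05 else p_adj <= fdr
  tab <- data.frame(feature_id = rownames(x), statistic = tt$statistic,
                    p = tt$p, p_adj = p_adj, selected = selected,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, tab$feature_id), ]
  rownames(tab) <- NULL
  .selection_result(tab, "protein")
}

#' Hypergeometric enrichment selection (HE)
#'
#' Tests each complex for over-representation of a differential protein set:
#' upper-tail hypergeometric p-value of the observed overlap between the
#' complex members (intersected with the background) and the differential
#' set, BH-adjusted across complexes.
#'
#' @param diff_proteins character vector of differential protein ids (subset
#'   of `background`); typically SP's FDR-selected set.
#' @param complexes a `complex_set`.
#' @param background character vector of all quantified protein ids.
#' @param alpha_sig BH-adjusted significance cutoff.
#' @return complex-level `selection_result`.
#' @export
he_select <- function(diff_proteins, complexes, background, alpha_sig = 0.05) {
  if (!length(background)) stop("empty background", call. = FALSE)
  extra <- setdiff(diff_proteins, background)
  if (length(extra))
    stop("differential protein(s) outside the background: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  N <- length(background)
  K <- length(diff_proteins)
  res <- lapply(seq_along(complexes$complex_id), function(i) {
    members <- intersect(complexes$members[[i]], background)
    m <- length(members)
    k <- length(intersect(members, diff_proteins))
    p <- if (m == 0) 1 else stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    data.frame(feature_id = complexes$complex_id[i], overlap = k, size = m,
               p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$selected <- tab$p_adj <= alpha_sig
  tab$statistic <- tab$overlap
  tab <- tab[order(tab$p, tab$feature_id),
             c("feature_id", "statistic", "overlap", "size", "p", "p_adj", "selected")]
  rownames(tab) <- NULL
  .selection_result(tab, "complex")
}

#' Rank-based network algorithm configuration
#'
#' @param alpha_top percentile cutoff for full ("highly ranked") membership;
#'   SNET's binary cutoff.
#' @param alpha_lo percentile beyond which FSNET's fuzzy membership reaches
#'   zero (`alpha_top <= alpha_lo`).
#' @param beta minimum class weight for a protein to contribute to a complex
#'   score.
#' @param n_permutations class-label permutations for the null.
#' @param alpha_sig permutation-p significance cutoff.
#' @return a list of class `rbna_config`.
#' @export
rbna_config <- function(alpha_top = 0.10, alpha_lo = 0.20, beta = 0.5,
                        n_permutations = 1000L, alpha_sig = 0.05) {
  stopifnot(alpha_top > 0, alpha_top <= alpha_lo, alpha_lo < 1,
            beta >= 0, beta <= 1, n_permutations >= 1)
  structure(list(alpha_top = alpha_top, alpha_lo = alpha_lo, beta = beta,
                 n_permutations = as.integer(n_permutations),
                 alpha_sig = alpha_sig),
            class = "rbna_config")
}

#' Within-sample rank membership scores
#'
#' Per sample, proteins are ranked by descending abundance and converted to
#' percentiles (ties share the mean percentile of their run). SNET
#' (`fuzzy = FALSE`): score 1 if the percentile is at most `alpha_top`, else
#' 0. FSNET (`fuzzy = TRUE`): 1 up to `alpha_top`, 0 beyond `alpha_lo`,
#' linear in between. Scores depend only on within-sample ranks, which is
#' the mechanism of batch resistance when a batch distorts a sample
#' monotonically.
#'
#' @param x expression matrix.
#' @param config an [rbna_config()].
#' @param fuzzy graded (FSNET) or binary (SNET) membership.
#' @return proteins x samples matrix of scores in \[0, 1\].
#' @export
rank_scores <- function(x, config = rbna_config(), fuzzy = FALSE) {
  pct <- apply(x, 2, function(col) rank(-col, ties.method = "average") / length(col))
  if (!fuzzy) {
    s <- (pct <= config$alpha_top) * 1
  } else {
    s <- (config$alpha_lo - pct) / (config$alpha_lo - config$alpha_top)
    s <- pmin(pmax(s, 0), 1)
  }
  dimnames(s) <- dimnames(x)
  s
}

# Complex score statistic for one complex under many label assignments.
# S: members x samples score matrix; assign: samples x n_assign logical
# matrix, TRUE = class D. Returns the t statistic of the per-sample paired
# difference score(s|D) - score(s|D*) contrasted between the two groups, for
# every assignment (0 when degenerate).
.complex_stat <- function(S, assign, beta) {
  nD <- colSums(assign)
  nDs <- nrow(assign) - nD
  wD <- (S %*% assign) / rep(nD, each = nrow(S))
  wDs <- (S %*% (!assign)) / rep(nDs, each = nrow(S))
  wD[wD < beta] <- 0
  wDs[wDs < beta] <- 0
  sD <- crossprod(S, wD)    # samples x n_assign: score of s against class D
  sDs <- crossprod(S, wDs)
  d <- sD - sDs
  mD <- colSums(d * assign) / nD
  mDs <- colSums(d * (!assign)) / nDs
  vD <- (colSums(d^2 * assign) - nD * mD^2) / (nD - 1)
  vDs <- (colSums(d^2 * (!assign)) - nDs * mDs^2) / (nDs - 1)
  sp2 <- ((nD - 1) * vD + (nDs - 1) * vDs) / (nD + nDs - 2)
  se <- sqrt(sp2 * (1 / nD + 1 / nDs))
  stat <- (mD - mDs) / se          # +-Inf for separations with zero
  stat[is.nan(stat)] <- 0          # within-group variance; 0 when constant
  stat
}

#' Rank-based network selection (SNET / FSNET)
#'
#' Scores each complex per sample against each class: proteins are weighted
#' by the fraction (fuzzy mean) of that class's samples in which they are
#' highly ranked, proteins below weight `beta` are dropped, and the sample's
#' membership scores of the remaining members are summed with those weights.
#' The test statistic contrasts the per-sample difference of the two
#' class-referenced scores between the classes; significance comes from a
#' class-label permutation null,
#' p = (1 + #\{|T_perm| >= |T_obs|\}) / (1 + n_permutations).
#'
#' @param x expression matrix.
#' @param meta sample metadata with two classes.
#' @param complexes a `complex_set`.
#' @param config an [rbna_config()].
#' @param fuzzy `TRUE` for FSNET, `FALSE` for SNET.
#' @param seed permutation seed or `NULL`.
#' @param exhaustive enumerate all distinct label assignments instead of
#'   sampling (feasible for small sample counts).
#' @return complex-level `selection_result`; `$scores` holds per-sample
#'   class-referenced complex score matrices (`vs_D`, `vs_Dstar`).
#' @export
rbna_select <- function(x, meta, complexes, config = rbna_config(),
                        fuzzy = FALSE, seed = NULL, exhaustive = FALSE) {
  meta <- match_metadata(x, meta)
  classes <- sort(unique(meta$class))
  if (length(classes) != 2L) stop("RBNA needs exactly two classes", call. = FALSE)
  if (!length(complexes$complex_id)) stop("empty complex set", call. = FALSE)
  if (any(table(meta$class) < 2L))
    stop("each class needs >= 2 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  S_all <- rank_scores(x, config, fuzzy = fuzzy)
  n <- ncol(x)
  obs <- matrix(meta$class == classes[1], ncol = 1)

  if (exhaustive) {
    nD <- sum(obs)
    combos <- utils::combn(n, nD)
    perm <- matrix(FALSE, n, ncol(combos))
    perm[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = nD))] <- TRUE
    # drop the observed assignment and its complement-equivalent duplicates:
    # keep all; p below uses the standard add-one estimator over them
  } else {
    perm <- vapply(seq_len(config$n_permutations),
                   function(i) sample(obs[, 1]), logical(n))
  }

  ids <- rownames(x)
  ncpx <- length(complexes$complex_id)
  stat_obs <- numeric(ncpx)
  pvals <- numeric(ncpx)
  vs_D <- matrix(0, ncpx, n, dimnames = list(complexes$complex_id, colnames(x)))
  vs_Ds <- vs_D
  for (i in seq_len(ncpx)) {
    members <- intersect(complexes$members[[i]], ids)
    if (length(members) < 1L) { stat_obs[i] <- 0; pvals[i] <- 1; next }
    S <- S_all[members, , drop = FALSE]
    t_obs <- .complex_stat(S, obs, config$beta)
    # per-sample class-referenced scores under the observed labels
    wD <- rowMeans(S[, obs[, 1], drop = FALSE])
    wDs <- rowMeans(S[, !obs[, 1], drop = FALSE])
    wD[wD < config$beta] <- 0
    wDs[wDs < config$beta] <- 0
    vs_D[i, ] <- crossprod(S, wD)
    vs_Ds[i, ] <- crossprod(S, wDs)
    if (all(wD == 0) && all(wDs == 0)) { stat_obs[i] <- 0; pvals[i] <- 1; next }
    t_perm <- .complex_stat(S, perm, config$beta)
    stat_obs[i] <- t_obs
    pvals[i] <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + length(t_perm))
  }
  tab <- data.frame(feature_id = complexes$complex_id, statistic = stat_obs,
                    p = pvals, p_adj = stats::p.adjust(pvals, method = "BH"),
                    selected = pvals <= config$alpha_sig,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, -abs(tab$statistic), tab$feature_id), ]
  rownames(tab) <- NULL
  .selection_result(tab, "complex",
                    scores = list(vs_D = vs_D, vs_Dstar = vs_Ds,
                                  class_D = classes[1], class_Dstar = classes[2]))
}

#' Member proteins of selected complexes
#'
#' @param sel a complex-level `selection_result`.
#' @param complexes the `complex_set` it was computed on.
#' @return character vector: union of member proteins of selected complexes.
#' @export
proteins_from_complexes <- function(sel, complexes) {
  stopifnot(inherits(sel, "selection_result"))
  if (sel$level != "complex")
    stop("expected a complex-level selection result", call. = FALSE)
  ids <- selected_ids(sel)
  if (!length(ids)) return(character(0))
  unique(unlist(complexes$members[ids], use.names = FALSE))
}
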