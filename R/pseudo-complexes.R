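# Pseudo-complex construction: labelled ground-truth complexes built from a
# simulated dataset, so that complex-level selectors can be scored.

.split_ordered <- function(ids, n) {
  m <- length(ids)
  base <- m %/% n
  r <- m - n * base
  sizes <- c(rep(base + 1L, r), rep(base, n - r))
  end <- cumsum(sizes)
  start <- end - sizes + 1L
  lapply(seq_len(n), function(i) ids[start[i]:end[i]])
}

#' True-positive pseudo-complexes
#'
#' Clusters the differential proteins by Euclidean distance of their sample
#' vectors (Ward's linkage), reorders them by dendrogram leaf order so that
#' co-expressed proteins are adjacent, and splits the ordered list into `n`
#' contiguous blocks of near-equal size (larger blocks first).
#'
#' @param x expression matrix containing the truth proteins.
#' @param truth ground truth (see [ground_truth()]); needs >= 2n proteins.
#' @param n number of pseudo-complexes (default 101).
#' @return a `complex_set` with `n` TP-labelled complexes covering all truth
#'   proteins.
#' @export
make_tp_pseudocomplexes <- function(x, truth, n = 101L) {
  ids <- intersect(truth$protein_id, rownames(x))
  if (length(ids) < length(truth$protein_id))
    stop("truth protein(s) absent from matrix", call. = FALSE)
  if (length(ids) < 2L * n)
    stop("need at least 2n = ", 2L * n, " differential proteins (have ",
         length(ids), "); use a smaller n", call. = FALSE)
  tree <- stats::hclust(stats::dist(x[ids, , drop = FALSE]), method = "ward.D2")
  ordered <- ids[tree$order]
  members <- .split_ordered(ordered, n)
  complex_set(sprintf("TP%03d", seq_len(n)), sprintf("tp_pseudo_%03d", seq_len(n)),
              members, "TP")
}

#' True-negative pseudo-complexes
#'
#' Randomly samples as many non-differential proteins as the TP complexes
#' contain, reorders them by expression correlation (Ward's linkage on
#' 1 - Pearson correlation), and splits as for the TP set.
#'
#' @param x expression matrix.
#' @param truth ground truth; its proteins are excluded from the pool.
#' @param n number of pseudo-complexes.
#' @param seed sampling seed or `NULL`.
#' @return a `complex_set` with `n` TN-labelled complexes, disjoint from the
#'   truth proteins.
#' @export
make_tn_pseudocomplexes <- function(x, truth, n = 101L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(rownames(x), truth$protein_id)
  m <- length(intersect(truth$protein_id, rownames(x)))
  if (length(pool) < m)
    stop("not enough non-differential proteins (need ", m, ", have ",
         length(pool), ")", call. = FALSE)
  sel <- sample(pool, m)
  cm <- suppressWarnings(stats::cor(t(x[sel, , drop = FALSE])))
  cm[!is.finite(cm)] <- 0     # constant proteins: maximal distance
  tree <- stats::hclust(stats::as.dist(1 - cm), method = "ward.D2")
  ordered <- sel[tree$order]
  members <- .split_ordered(ordered, n)
  complex_set(sprintf("TN%03d", seq_len(n)), sprintf("tn_pseudo_%03d", seq_len(n)),
              members, "TN")
}

#' Adjust the purity of true-positive pseudo-complexes
#'
#' In each TP complex independently, `round((1 - purity) * size)` members
#' are replaced by distinct random non-differential proteins, so that the
#' realized fraction of differential members equals `purity` up to rounding.
#' Complex count and sizes are preserved; replacements are drawn without
#' replacement across the whole set.
#'
#' @param tp a TP-labelled `complex_set` (purity 1).
#' @param truth ground truth.
#' @param pool character vector of candidate non-differential protein ids.
#' @param purity target fraction of differential members in (0, 1].
#' @param seed sampling seed or `NULL`.
#' @return the adjusted `complex_set`.
#' @export
adjust_purity <- function(tp, truth, pool, purity, seed = NULL) {
  stopifnot(purity > 0, purity <= 1)
  if (purity == 1) return(tp)
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(pool, truth$protein_id)
  sizes <- vapply(tp$members, length, 1L)
  n_repl <- round((1 - purity) * sizes)
  if (sum(n_repl) > length(pool))
    stop("replacement pool exhausted: need ", sum(n_repl), ", have ",
         length(pool), call. = FALSE)
  draws <- sample(pool, sum(n_repl))
  offset <- 0L
  members <- tp$members
  for (i in seq_along(members)) {
    if (n_repl[i] == 0L) next
    out_idx <- sample(seq_along(members[[i]]), n_repl[i])
    members[[i]][out_idx] <- draws[offset + seq_len(n_repl[i])]
    offset <- offset + n_repl[i]
  }
  complex_set(tp$complex_id, tp$name, members, tp$truth_label)
}

#' Build the combined evaluation complex vector
#'
#' Convenience wrapper: TP pseudo-complexes (optionally purity-adjusted)
#' plus an equal number of TN pseudo-complexes, concatenated.
#'
#' @param x expression matrix (typically the clean matrix of a pair, so that
#'   the same complex vector is used for clean and noisy evaluation).
#' @param truth ground truth.
#' @param n complexes per label.
#' @param purity purity of the TP complexes.
#' @param seed seed for TN sampling and purity replacement.
#' @return a `complex_set` of 2n complexes with TP/TN labels.
#' @export
make_pseudocomplexes <- function(x, truth, n = 101L, purity = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tp <- make_tp_pseudocomplexes(x, truth, n)
  tn <- make_tn_pseudocomplexes(x, truth, n, seed = NULL)
  tn_used <- unique(unlist(tn$members, use.names = FALSE))
  pool <- setdiff(rownames(x), c(truth$protein_id, tn_used))
  tp <- adjust_purity(tp, truth, pool, purity, seed = NULL)
  complex_set(c(tp$complex_id, tn$complex_id), c(tp$name, tn$name),
              c(tp$members, tn$members), c(tp$truth_label, tn$truth_label))
}
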