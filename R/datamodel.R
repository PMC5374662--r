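#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of non-negative, finite
#' abundances (spectral counts or intensities) with unique protein ids as
#' rownames and unique sample ids as colnames.
#'
#' @param x numeric matrix, proteins in rows, samples in columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have protein ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (any(x < 0))
    stop("expression matrix contains negative values", call. = FALSE)
  invisible(x)
}

#' Construct sample metadata
#'
#' Per-sample class (phenotype, e.g. "D" vs "D*") and batch assignments.
#'
#' @param sample_id character vector of unique sample ids.
#' @param class class label per sample.
#' @param batch batch label per sample.
#' @return a `data.frame` with columns `sample_id`, `class`, `batch`.
#' @export
sample_metadata <- function(sample_id, class, batch) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "), call. = FALSE)
  if (length(class) != length(sample_id) || length(batch) != length(sample_id))
    stop("class and batch must have one entry per sample", call. = FALSE)
  data.frame(sample_id = sample_id, class = as.character(class),
             batch = as.character(batch), stringsAsFactors = FALSE)
}

#' Check that metadata covers a matrix
#'
#' @param x expression matrix.
#' @param meta sample metadata (see [sample_metadata()]).
#' @return the metadata, reordered to match `colnames(x)`, invisibly.
#' @export
match_metadata <- function(x, meta) {
  missing <- setdiff(colnames(x), meta$sample_id)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  invisible(meta[match(colnames(x), meta$sample_id), , drop = FALSE])
}

#' Construct a protein complex set
#'
#' @param complex_id unique complex identifiers.
#' @param name human-readable complex names.
#' @param members list of character vectors of member protein ids (each of
#'   length >= 2).
#' @param truth_label `"TP"`, `"TN"` or `"unknown"` per complex; pseudo-
#'   complexes carry TP/TN labels, real (e.g. CORUM) complexes are "unknown".
#' @return an object of class `complex_set`.
#' @export
complex_set <- function(complex_id, name = complex_id, members,
                        truth_label = "unknown") {
  complex_id <- as.character(complex_id)
  if (anyDuplicated(complex_id))
    stop("duplicate complex id(s)", call. = FALSE)
  if (length(members) != length(complex_id))
    stop("one member vector required per complex", call. = FALSE)
  truth_label <- rep_len(as.character(truth_label), length(complex_id))
  bad <- !truth_label %in% c("TP", "TN", "unknown")
  if (any(bad))
    stop("truth_label must be TP, TN or unknown", call. = FALSE)
  small <- vapply(members, length, 1L) < 2L
  if (any(small))
    stop("complex(es) with fewer than 2 members: ",
         paste(complex_id[small], collapse = ", "), call. = FALSE)
  members <- lapply(members, as.character)
  names(members) <- complex_id
  structure(list(complex_id = complex_id,
                 name = rep_len(as.character(name), length(complex_id)),
                 members = members,
                 truth_label = truth_label),
            class = "complex_set")
}

#' @export
length.complex_set <- function(x) length(x$complex_id)

#' @export
print.complex_set <- function(x, ...) {
  sizes <- vapply(x$members, length, 1L)
  cat("complex_set with", length(x), "complexes;",
      "member counts", min(sizes), "-", max(sizes), "\n")
  tl <- table(x$truth_label)
  cat("truth labels:", paste(names(tl), tl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset a complex set
#'
#' @param x a `complex_set`.
#' @param i index vector (logical, integer or complex ids).
#' @param ... unused.
#' @export
`[.complex_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$complex_id)
  complex_set(x$complex_id[i], x$name[i], x$members[i], x$truth_label[i])
}

#' Construct ground truth for a simulated dataset
#'
#' @param protein_id differential protein ids.
#' @param level_pct inserted effect size per protein as percentage increase
#'   (e.g. 100 means the D* values were doubled).
#' @return a `data.frame` with columns `protein_id`, `level_pct`,
#'   `multiplier` (= 1 + level_pct/100).
#' @export
ground_truth <- function(protein_id, level_pct) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id))
    stop("duplicate protein id(s) in ground truth", call. = FALSE)
  level_pct <- as.numeric(level_pct)
  if (any(!is.finite(level_pct)) || any(level_pct <= 0))
    stop("effect levels must be finite and > 0", call. = FALSE)
  data.frame(protein_id = protein_id, level_pct = level_pct,
             multiplier = 1 + level_pct / 100, stringsAsFactors = FALSE)
}
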