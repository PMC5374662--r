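# Tab-delimited readers/writers for expression tables, sample metadata,
# complex membership files and simulated-dataset directories.
# Dialect: UTF-8, tab-delimited, '.' decimal separator, no quoting,
# complete data (empty cells are an error).

.read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  strsplit(lines, "\t", fixed = TRUE)
}

.fmt_num <- function(v) {
  # full-precision, locale-independent formatting; integers print bare
  ifelse(v == round(v) & abs(v) < 2^53, format(round(v), scientific = FALSE),
         sprintf("%.17g", v))
}

#' Read an expression table
#'
#' Reads a tab-delimited abundance table with a header row of sample ids and
#' a first column of protein ids (or the transpose, per `orientation`).
#'
#' @param path file path.
#' @param orientation `"proteins"` if rows are proteins (default, the
#'   proteomics convention) or `"samples"` if rows are samples.
#' @return a validated expression matrix (proteins x samples).
#' @export
read_expression_table <- function(path, orientation = c("proteins", "samples")) {
  orientation <- match.arg(orientation)
  cells <- .read_tsv_lines(path)
  header <- cells[[1]]
  ncol_expect <- length(header)
  body <- cells[-1]
  for (i in seq_along(body)) {
    if (length(body[[i]]) != ncol_expect)
      stop("ragged row at line ", i + 1L, ": expected ", ncol_expect,
           " fields, found ", length(body[[i]]), call. = FALSE)
  }
  row_ids <- vapply(body, `[[`, "", 1L)
  col_ids <- header[-1]
  vals <- lapply(body, function(r) {
    v <- r[-1]
    if (any(!nzchar(v)))
      stop("empty cell in row '", r[[1]], "' (missing values are not supported)",
           call. = FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num)))
      stop("non-numeric cell '", v[which(is.na(num))[1]], "' in row '", r[[1]], "'",
           call. = FALSE)
    num
  })
  m <- do.call(rbind, vals)
  rownames(m) <- row_ids
  colnames(m) <- col_ids
  if (orientation == "samples") m <- t(m)
  validate_expression_matrix(m)
  m
}

#' Write an expression table
#'
#' @param x expression matrix (proteins x samples).
#' @param path output file path.
#' @export
write_expression_table <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("protein_id", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], .fmt_num(x[i, ])), collapse = "\t"), "")
  writeLines(body, con)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path a tab-delimited file with header `sample_id  class  batch`.
#' @return a metadata `data.frame` (see [sample_metadata()]).
#' @export
read_metadata <- function(path) {
  cells <- .read_tsv_lines(path)
  if (!identical(cells[[1]][1:3], c("sample_id", "class", "batch")))
    stop("metadata header must be 'sample_id\\tclass\\tbatch'", call. = FALSE)
  body <- cells[-1]
  for (i in seq_along(body))
    if (length(body[[i]]) != 3L)
      stop("ragged row at line ", i + 1L, call. = FALSE)
  sample_metadata(vapply(body, `[[`, "", 1L),
                  vapply(body, `[[`, "", 2L),
                  vapply(body, `[[`, "", 3L))
}

#' Write sample metadata
#' @param meta metadata `data.frame`.
#' @param path output file path.
#' @export
write_metadata <- function(meta, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("sample_id\tclass\tbatch", con)
  writeLines(paste(meta$sample_id, meta$class, meta$batch, sep = "\t"), con)
  invisible(path)
}

#' Read a complex-membership file
#'
#' One complex per line: `complex_id  name  member1;member2;...` with an
#' optional fourth `truth_label` column (TP/TN/unknown). Singleton complexes
#' are dropped with a warning.
#'
#' @param path file path.
#' @return a `complex_set`.
#' @export
read_complexes <- function(path) {
  cells <- .read_tsv_lines(path)
  if (identical(cells[[1]][1], "complex_id")) cells <- cells[-1]
  ids <- character(0); nms <- character(0); mem <- list(); tl <- character(0)
  for (i in seq_along(cells)) {
    r <- cells[[i]]
    if (length(r) < 3L || length(r) > 4L)
      stop("malformed complex line ", i, ": expected 3 or 4 fields", call. = FALSE)
    members <- strsplit(r[[3]], ";", fixed = TRUE)[[1]]
    members <- members[nzchar(members)]
    if (!length(members))
      stop("empty member list for complex '", r[[1]], "' at line ", i, call. = FALSE)
    if (length(members) == 1L) {
      warning("dropping singleton complex '", r[[1]], "'", call. = FALSE)
      next
    }
    ids <- c(ids, r[[1]]); nms <- c(nms, r[[2]])
    mem <- c(mem, list(members))
    tl <- c(tl, if (length(r) == 4L) r[[4]] else "unknown")
  }
  if (!length(ids)) stop("no complexes with >= 2 members in ", path, call. = FALSE)
  complex_set(ids, nms, mem, tl)
}

#' Write a complex-membership file
#' @param complexes a `complex_set`.
#' @param path output file path.
#' @export
write_complexes <- function(complexes, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("complex_id\tname\tmembers\ttruth_label", con)
  writeLines(paste(complexes$complex_id, complexes$name,
                   vapply(complexes$members, paste, "", collapse = ";"),
                   complexes$truth_label, sep = "\t"), con)
  invisible(path)
}

#' Write a dataset directory
#'
#' Writes `expression.tsv`, `metadata.tsv` and (when ground truth is given)
#' `truth.tsv` into `dir`, readable by the corresponding readers.
#'
#' @param x expression matrix.
#' @param meta sample metadata covering all samples of `x`.
#' @param truth ground truth `data.frame` or `NULL`.
#' @param dir output directory (created if absent).
#' @export
write_dataset <- function(x, meta, truth = NULL, dir) {
  match_metadata(x, meta)
  extra <- setdiff(meta$sample_id, colnames(x))
  if (length(extra))
    stop("metadata has sample(s) absent from matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(x, file.path(dir, "expression.tsv"))
  write_metadata(meta, file.path(dir, "metadata.tsv"))
  if (!is.null(truth)) {
    con <- file(file.path(dir, "truth.tsv"), open = "wt", encoding = "UTF-8")
    writeLines("protein_id\tlevel_pct", con)
    writeLines(paste(truth$protein_id, .fmt_num(truth$level_pct), sep = "\t"), con)
    close(con)
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a list with `x` (matrix), `meta`, and `truth` (or `NULL`).
#' @export
read_dataset <- function(dir) {
  x <- read_expression_table(file.path(dir, "expression.tsv"))
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  tpath <- file.path(dir, "truth.tsv")
  truth <- NULL
  if (file.exists(tpath)) {
    cells <- .read_tsv_lines(tpath)
    body <- cells[-1]
    truth <- ground_truth(vapply(body, `[[`, "", 1L),
                          as.numeric(vapply(body, `[[`, "", 2L)))
  }
  list(x = x, meta = meta, truth = truth)
}
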