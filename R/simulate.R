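#' Effect-size menus
#'
#' Inserted class and batch effects are multiplicative increases whose sizes
#' are drawn from a menu of five percentage levels. `effect_menu_default()`
#' is (20, 50, 80, 100, 200)%; `effect_menu_mild()` is the alternative
#' (10, 30, 50, 70, 90)% menu used for combined-dataset experiments where the
#' two halves carry different batch effects.
#'
#' @return numeric vector of five percentage levels.
#' @export
effect_menu_default <- function() c(20, 50, 80, 100, 200)

#' @rdname effect_menu_default
#' @export
effect_menu_mild <- function() c(10, 30, 50, 70, 90)

.check_menu <- function(menu) {
  if (length(menu) != 5L || any(!is.finite(menu)) || any(menu <= 0))
    stop("an effect menu must be five positive percentage levels", call. = FALSE)
  as.numeric(menu)
}

#' Simulation configuration
#'
#' Bundles the parameters of the benchmark generator: a negative-binomial
#' spectral-count base matrix, class effects inserted into a random subset of
#' proteins of the D* samples, and batch effects applied to every protein of
#' one batch.
#'
#' @param n_proteins number of proteins.
#' @param samples_per_class samples in each of classes D and D* (>= 2; each
#'   class is split evenly between batches 1 and 2).
#' @param diff_fraction fraction of proteins receiving class effects.
#' @param class_menu,batch_menu five-level percentage effect menus.
#' @param affected_batch batch receiving the batch effects.
#' @param base_mean_range per-protein negative-binomial mean is drawn
#'   log-uniformly from this range.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion). The
#'   default 0.05 emulates technical-replicate-grade spectral counting noise
#'   (CV about 22% at high abundance), matching base data in which the
#'   samples of a class are replicate draws of one specimen; raise it (e.g.
#'   0.2) to emulate biological between-subject variability.
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1500L, samples_per_class = 4L,
                       diff_fraction = 0.20,
                       class_menu = effect_menu_default(),
                       batch_menu = effect_menu_default(),
                       affected_batch = "2",
                       base_mean_range = c(5, 500), dispersion = 0.05,
                       seed = 1L) {
  stopifnot(n_proteins >= 1, samples_per_class >= 2,
            diff_fraction > 0, diff_fraction < 1,
            length(base_mean_range) == 2, base_mean_range[1] > 0,
            base_mean_range[2] >= base_mean_range[1], dispersion > 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 samples_per_class = as.integer(samples_per_class),
                 diff_fraction = diff_fraction,
                 class_menu = .check_menu(class_menu),
                 batch_menu = .check_menu(batch_menu),
                 affected_batch = as.character(affected_batch),
                 base_mean_range = as.numeric(base_mean_range),
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a single-class spectral-count base matrix
#'
#' Counts are i.i.d. negative-binomial across samples within each protein;
#' per-protein means are drawn log-uniformly from `mean_range`, emulating the
#' wide dynamic range of spectral-count data. All samples are exchangeable
#' until effects are inserted.
#'
#' @param n_proteins,n_samples matrix dimensions.
#' @param mean_range log-uniform range for per-protein means.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return expression matrix of non-negative integer counts with protein ids
#'   `P0001, ...` and sample ids `S1, ...`; the drawn per-protein means are
#'   attached as attribute `"mu"`.
#' @export
generate_base_matrix <- function(n_proteins, n_samples,
                                 mean_range = c(5, 500), dispersion = 0.05,
                                 seed = NULL) {
  stopifnot(n_proteins >= 1, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- exp(stats::runif(n_proteins, log(mean_range[1]), log(mean_range[2])))
  m <- matrix(stats::rnbinom(n_proteins * n_samples,
                             mu = rep(mu, times = n_samples),
                             size = 1 / dispersion),
              nrow = n_proteins, ncol = n_samples)
  rownames(m) <- sprintf("P%0*d", max(4L, nchar(n_proteins)), seq_len(n_proteins))
  colnames(m) <- paste0("S", seq_len(n_samples))
  attr(m, "mu") <- mu
  m
}

#' Insert class effects
#'
#' Selects `round(diff_fraction * n_proteins)` proteins uniformly at random;
#' for each, one menu level is drawn and the protein's values in the D*
#' samples are multiplied by (1 + level/100). Class D samples are untouched.
#'
#' @param base expression matrix.
#' @param meta sample metadata with classes `"D"` and `"D*"`.
#' @param diff_fraction fraction of proteins made differential.
#' @param menu five-level percentage menu.
#' @param seed integer seed or `NULL`.
#' @param target_class class receiving the increase (default `"D*"`).
#' @return list with `x` (matrix with effects) and `truth` (ground truth).
#' @export
insert_class_effects <- function(base, meta, diff_fraction = 0.20,
                                 menu = effect_menu_default(), seed = NULL,
                                 target_class = "D*") {
  meta <- match_metadata(base, meta)
  menu <- .check_menu(menu)
  if (!target_class %in% meta$class)
    stop("target class '", target_class, "' absent from metadata", call. = FALSE)
  if (length(unique(meta$class)) < 2L)
    stop("both classes must be present", call. = FALSE)
  n_diff <- round(diff_fraction * nrow(base))
  if (n_diff < 1)
    stop("diff_fraction * n_proteins < 1: no proteins to perturb", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(nrow(base), n_diff))
  levels_pct <- sample(menu, n_diff, replace = TRUE)
  x <- base
  cols <- meta$class == target_class
  x[idx, cols] <- x[idx, cols] * (1 + levels_pct / 100)
  list(x = x, truth = ground_truth(rownames(base)[idx], levels_pct))
}

#' Insert batch effects
#'
#' For every protein one menu level is sampled independently and the
#' protein's values in all samples of `affected_batch` are multiplied by
#' (1 + level/100). Because the level differs from protein to protein, the
#' batch effect is uneven across variables and cannot be undone by global
#' normalization.
#'
#' @param x expression matrix.
#' @param meta sample metadata with at least two batches.
#' @param menu five-level percentage menu.
#' @param affected_batch batch label receiving the effects.
#' @param seed integer seed or `NULL`.
#' @return the perturbed matrix, with the per-protein sampled levels attached
#'   as attribute `"batch_levels"`.
#' @export
insert_batch_effects <- function(x, meta, menu = effect_menu_default(),
                                 affected_batch = "2", seed = NULL) {
  meta <- match_metadata(x, meta)
  menu <- .check_menu(menu)
  if (length(unique(meta$batch)) < 2L)
    stop("batch effects require at least two batches in metadata", call. = FALSE)
  if (!affected_batch %in% meta$batch)
    stop("affected batch '", affected_batch, "' absent from metadata", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  levels_pct <- sample(menu, nrow(x), replace = TRUE)
  cols <- meta$batch == affected_batch
  out <- x
  out[, cols] <- out[, cols] * (1 + levels_pct / 100)
  attr(out, "batch_levels") <- stats::setNames(levels_pct, rownames(x))
  out
}

#' Simulate a clean/noisy benchmark dataset pair
#'
#' Composes [generate_base_matrix()], [insert_class_effects()] and
#' [insert_batch_effects()]. Each class is split evenly between batches 1 and
#' 2. The `clean` matrix carries class effects only; the `noisy` matrix
#' additionally carries batch effects on the affected batch, so the pair
#' shares ground truth and the unaffected batch is identical between the two.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `clean`, `noisy`,
#'   `meta`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$samples_per_class
  ids <- c(paste0("D", seq_len(k)), paste0("Ds", seq_len(k)))
  half <- rep(c("1", "2"), each = ceiling(k / 2), length.out = k)
  meta <- sample_metadata(ids, rep(c("D", "D*"), each = k), c(half, half))
  base <- generate_base_matrix(config$n_proteins, 2L * k,
                               mean_range = config$base_mean_range,
                               dispersion = config$dispersion, seed = NULL)
  colnames(base) <- ids
  ce <- insert_class_effects(base, meta, config$diff_fraction,
                             config$class_menu, seed = NULL)
  noisy <- insert_batch_effects(ce$x, meta, config$batch_menu,
                                config$affected_batch, seed = NULL)
  structure(list(clean = ce$x, noisy = noisy, meta = meta,
                 truth = ce$truth, config = config,
                 mu = attr(base, "mu")),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$clean), "proteins x", ncol(x$clean), "samples;",
      nrow(x$truth), "differential proteins\n")
  invisible(x)
}

#' Combine two simulated datasets sharing ground truth
#'
#' Column-concatenates two datasets carrying the same differential feature
#' set but (typically) different batch effects, emulating the pooling of two
#' studies of the same disease. Sample ids are prefixed with a dataset tag
#' and batch labels become dataset-qualified (A1, A2, B1, B2).
#'
#' @param a,b `sim_dataset` objects with identical protein ids and truth.
#' @param tags length-2 character vector of dataset tags.
#' @param use `"noisy"` (default) or `"clean"` matrices.
#' @return list with `x` (combined matrix) and `meta`.
#' @export
combine_datasets <- function(a, b, tags = c("A", "B"), use = "noisy") {
  stopifnot(inherits(a, "sim_dataset"), inherits(b, "sim_dataset"))
  if (!identical(rownames(a$clean), rownames(b$clean)))
    stop("protein ids differ between datasets", call. = FALSE)
  if (!identical(a$truth$protein_id, b$truth$protein_id) ||
      !identical(a$truth$level_pct, b$truth$level_pct))
    stop("ground truth differs between datasets", call. = FALSE)
  ma <- a[[use]]; mb <- b[[use]]
  colnames(ma) <- paste0(tags[1], "_", colnames(ma))
  colnames(mb) <- paste0(tags[2], "_", colnames(mb))
  x <- cbind(ma, mb)
  attr(x, "batch_levels") <- NULL
  meta <- rbind(
    sample_metadata(colnames(ma), a$meta$class, paste0(tags[1], a$meta$batch)),
    sample_metadata(colnames(mb), b$meta$class, paste0(tags[2], b$meta$batch)))
  list(x = x, meta = meta)
}

#' Re-simulate a dataset with the same truth but fresh batch effects
#'
#' Produces a second dataset emulating a new acquisition of the same study:
#' the per-protein baseline means and the differential proteins with their
#' effect sizes are those of `a`, but the counts are fresh draws and the
#' batch effects follow `batch_menu`.
#'
#' @param a a `sim_dataset` to share truth with.
#' @param batch_menu percentage menu for the new batch effects.
#' @param seed integer seed.
#' @return a `sim_dataset`.
#' @export
resimulate_with_truth <- function(a, batch_menu = effect_menu_mild(), seed) {
  stopifnot(inherits(a, "sim_dataset"))
  cfg <- a$config
  set.seed(seed)
  k <- cfg$samples_per_class
  n <- 2L * k
  base <- matrix(stats::rnbinom(cfg$n_proteins * n,
                                mu = rep(a$mu, times = n),
                                size = 1 / cfg$dispersion),
                 nrow = cfg$n_proteins, ncol = n,
                 dimnames = list(rownames(a$clean), a$meta$sample_id))
  clean <- base
  cols <- a$meta$class == "D*"
  idx <- match(a$truth$protein_id, rownames(base))
  clean[idx, cols] <- clean[idx, cols] * a$truth$multiplier
  noisy <- insert_batch_effects(clean, a$meta, batch_menu,
                                cfg$affected_batch, seed = NULL)
  structure(list(clean = clean, noisy = noisy, meta = a$meta,
                 truth = a$truth, config = cfg),
            class = "sim_dataset")
}

#' Re-insert fresh batch effects into an existing dataset
#'
#' Returns a dataset with the same clean matrix and ground truth as `a` but
#' a fresh, independent draw of per-protein batch-effect levels (optionally
#' from a different menu). Combining such a pair emulates pooling two
#' acquisitions of one study that suffered different batch effects.
#'
#' @param a a `sim_dataset`.
#' @param batch_menu percentage menu for the new batch effects.
#' @param seed integer seed.
#' @return a `sim_dataset` sharing `clean`, `meta` and `truth` with `a`.
#' @export
rebatch_dataset <- function(a, batch_menu = effect_menu_mild(), seed) {
  stopifnot(inherits(a, "sim_dataset"))
  noisy <- insert_batch_effects(a$clean, a$meta, batch_menu,
                                a$config$affected_batch, seed = seed)
  structure(list(clean = a$clean, noisy = noisy, meta = a$meta,
                 truth = a$truth, config = a$config),
            class = "sim_dataset")
}
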