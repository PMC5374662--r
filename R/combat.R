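# Parametric empirical-Bayes location/scale batch adjustment.
#
# Per protein g and batch i the model is
#   y_gij = alpha_g + X beta_g + gamma_ig + delta_ig * e_gij
# with gamma_ig ~ N(gamma_i, tau_i^2) and delta_ig^2 ~ InvGamma(lambda_i,
# theta_i). Hyperparameters are estimated by method of moments from the
# per-batch empirical effects; posteriors (gamma*, delta*) are obtained by a
# fixed-point iteration and used to shrink then remove the batch effects.

.design_matrix <- function(meta, covariate) {
  batch <- factor(meta$batch)
  design <- stats::model.matrix(~ -1 + batch)
  if (covariate && length(unique(meta$class)) > 1L) {
    cls <- stats::model.matrix(~ factor(meta$class))[, -1, drop = FALSE]
    design <- cbind(design, cls)
  }
  if (qr(design)$rank < ncol(design))
    stop("class is perfectly confounded with batch; batch effects are not identifiable",
         call. = FALSE)
  list(design = design, batch = batch, n_batch = nlevels(batch))
}

.row_vars <- function(m) {
  n <- ncol(m)
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

#' Fit the empirical-Bayes batch model
#'
#' Estimates per-protein grand mean and pooled variance, per-batch
#' location/scale effects, and their shrunken (posterior) versions under
#' parametric priors. Operates on the scale of `x` as given; for abundance
#' data use the log2 scale (see [combat_correct()]).
#'
#' @param x expression-scale or log-scale numeric matrix (proteins x samples).
#' @param meta sample metadata; >= 2 batches with >= 2 samples each.
#' @param covariate include the class label as a covariate so that class
#'   effects are protected during standardization (default `TRUE`).
#' @param conv relative convergence tolerance of the posterior iteration.
#' @param max_iter iteration cap.
#' @return an object of class `combat_fit`.
#' @export
combat_fit <- function(x, meta, covariate = TRUE, conv = 1e-6, max_iter = 500L) {
  meta <- match_metadata(x, meta)
  d <- .design_matrix(meta, covariate)
  design <- d$design; batch <- d$batch; n_batch <- d$n_batch
  if (n_batch < 2L) stop("need >= 2 batches", call. = FALSE)
  n_per <- table(batch)
  if (any(n_per < 2L)) stop("every batch needs >= 2 samples", call. = FALSE)
  n_array <- ncol(x)

  B_hat <- solve(crossprod(design), crossprod(design, t(x)))
  grand_mean <- crossprod(as.numeric(n_per) / n_array,
                          B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- as.numeric(((x - t(design %*% B_hat))^2) %*%
                             rep(1 / n_array, n_array))
  if (any(var_pooled <= 0))
    stop("protein(s) with zero pooled variance: ",
         paste(utils::head(rownames(x)[var_pooled <= 0], 3), collapse = ", "),
         call. = FALSE)

  stand_mean <- matrix(grand_mean, nrow(x), n_array)
  tmp <- design; tmp[, seq_len(n_batch)] <- 0
  stand_mean <- stand_mean + t(tmp %*% B_hat)
  s_data <- (x - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, n_batch, nrow(x))
  delta_hat <- matrix(NA_real_, n_batch, nrow(x))
  for (i in seq_len(n_batch)) {
    cols <- batch == levels(batch)[i]
    gamma_hat[i, ] <- rowMeans(s_data[, cols, drop = FALSE])
    delta_hat[i, ] <- .row_vars(s_data[, cols, drop = FALSE])
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1, stats::var)
  m <- rowMeans(delta_hat)
  s2 <- apply(delta_hat, 1, stats::var)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(n_batch)) {
    cols <- batch == levels(batch)[i]
    sd_b <- s_data[, cols, drop = FALSE]
    n_i <- sum(cols)
    g_old <- gamma_hat[i, ]; d_old <- delta_hat[i, ]
    g_hat <- gamma_hat[i, ]
    iter <- 0L
    repeat {
      g_new <- (n_i * tau2[i] * g_hat + d_old * gamma_bar[i]) /
        (n_i * tau2[i] + d_old)
      sum2 <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n_i / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      iter <- iter + 1L
      if (is.na(change) || change < conv || iter >= max_iter) break
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }

  structure(list(batch_levels = levels(batch), batch = batch,
                 protein_ids = rownames(x), sample_ids = colnames(x),
                 stand_mean = stand_mean, var_pooled = var_pooled,
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 gamma_star = gamma_star, delta_star = delta_star,
                 gamma_bar = gamma_bar, tau2 = tau2,
                 a_prior = a_prior, b_prior = b_prior,
                 covariate = covariate),
            class = "combat_fit")
}

#' Apply a fitted empirical-Bayes batch adjustment
#'
#' Standardizes `x` with the fit's per-protein mean and pooled variance,
#' removes the shrunken batch location effect and rescales by the shrunken
#' batch scale, then restores the fitted mean structure.
#'
#' @param x matrix the fit was computed on (same proteins and samples).
#' @param fit a [combat_fit()] object.
#' @return adjusted matrix on the scale of `x`.
#' @export
combat_apply <- function(x, fit) {
  stopifnot(inherits(fit, "combat_fit"))
  if (!identical(rownames(x), fit$protein_ids) ||
      !identical(colnames(x), fit$sample_ids))
    stop("matrix dimensions/ids do not match the fit", call. = FALSE)
  s_data <- (x - fit$stand_mean) / sqrt(fit$var_pooled)
  out <- s_data
  for (i in seq_along(fit$batch_levels)) {
    cols <- fit$batch == fit$batch_levels[i]
    out[, cols] <- (s_data[, cols, drop = FALSE] - fit$gamma_star[i, ]) /
      sqrt(fit$delta_star[i, ])
  }
  out <- out * sqrt(fit$var_pooled) + fit$stand_mean
  if (any(!is.finite(out))) stop("non-finite adjusted values", call. = FALSE)
  out
}

#' Empirical-Bayes batch correction of an abundance matrix
#'
#' Convenience wrapper: log2(x + 1) transform (optional), [combat_fit()] +
#' [combat_apply()], back-transform, clip at zero.
#'
#' @inheritParams combat_fit
#' @param log2_transform model batch effects additively on the log2(x+1)
#'   scale (default `TRUE`; multiplicative batch effects are additive there).
#' @return corrected matrix on the scale of `x`.
#' @export
combat_correct <- function(x, meta, covariate = TRUE, log2_transform = TRUE) {
  y <- if (log2_transform) log2(x + 1) else x
  fit <- combat_fit(y, meta, covariate = covariate)
  adj <- combat_apply(y, fit)
  if (log2_transform) pmax(2^adj - 1, 0) else adj
}
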