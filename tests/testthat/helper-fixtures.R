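# Shared fixtures and independent oracles.

toy_matrix <- function(vals = 1:6, nr = 2, proteins = NULL, samples = NULL) {
  m <- matrix(as.numeric(vals), nrow = nr)
  rownames(m) <- proteins %||% paste0("P", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_meta <- function(x, classes = NULL, batches = NULL) {
  n <- ncol(x)
  sample_metadata(colnames(x),
                  classes %||% rep(c("D", "D*"), each = n / 2),
                  batches %||% rep(c("1", "2"), times = n / 2))
}

small_dataset <- function(seed = 1, n_proteins = 300) {
  simulate_dataset(sim_config(n_proteins = n_proteins, seed = seed))
}

# brute-force quantile normalization: rank-and-average, one column at a time
oracle_quantile <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    out[, j] <- (target[floor(r)] + target[ceiling(r)]) / 2
  }
  out
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# O(n^3) Ward (ward.D2 update) agglomeration; returns merge heights and the
# partition at every k, which are orientation-invariant summaries of the tree
oracle_ward <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  labels <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]; b <- active[j]
      if (d2[a, b] < bestv) { bestv <- d2[a, b]; best <- c(b, a) }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, sqrt(bestv))
    # Lance-Williams update for ward.D2 on squared distances
    for (c_ in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nc <- sizes[c_]
      d2[a, c_] <- d2[c_, a] <-
        ((na + nc) * d2[a, c_] + (nb + nc) * d2[b, c_] - nc * d2[a, b]) /
        (na + nb + nc)
    }
    sizes[a] <- sizes[a] + sizes[b]
    groups[[a]] <- c(groups[[a]], groups[[b]])
    active <- setdiff(active, b)
    part <- integer(n)
    for (g in seq_along(active)) part[groups[[active[g]]]] <- g
    partitions[[length(partitions) + 1]] <- part
  }
  list(heights = heights, partitions = rev(partitions))
}

# canonical form of a partition for label-free comparison
canon_partition <- function(p) {
  match(p, unique(p))
}

# independent per-complex RBNA statistic for the exhaustive oracle:
# recomputes weights and scores from scratch for one label assignment
oracle_complex_stat <- function(S, is_d, beta) {
  wD <- rowMeans(S[, is_d, drop = FALSE])
  wDs <- rowMeans(S[, !is_d, drop = FALSE])
  wD[wD < beta] <- 0; wDs[wDs < beta] <- 0
  sD <- as.numeric(t(S) %*% wD)
  sDs <- as.numeric(t(S) %*% wDs)
  d <- sD - sDs
  g1 <- d[is_d]; g2 <- d[!is_d]
  sp2 <- ((length(g1) - 1) * stats::var(g1) + (length(g2) - 1) * stats::var(g2)) /
    (length(g1) + length(g2) - 2)
  se <- sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  st <- (mean(g1) - mean(g2)) / se
  if (is.nan(st)) 0 else st
}
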