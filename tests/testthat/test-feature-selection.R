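test_that("single-protein selection ranks, adjusts and flags correctly", {
  ds <- small_dataset(seed = 2, n_proteins = 200)
  sel <- suppressWarnings(sp_select(ds$noisy, ds$meta, fdr = 0.05))
  expect_s3_class(sel, "selection_result")
  expect_equal(sel$level, "protein")
  expect_true(!is.unsorted(sel$table$p))
  # adjusted p monotone in p
  expect_true(!is.unsorted(sel$table$p_adj))
  # BH equals the brute-force step-up oracle
  expect_equal(sel$table$p_adj[order(sel$table$feature_id)],
               oracle_bh(sel$table$p[order(sel$table$feature_id)]))

  # planted extreme protein gets the minimal p-value
  x <- ds$clean
  x["P0001", ds$meta$class == "D*"] <- x["P0001", ds$meta$class == "D*"] + 1e4
  sel2 <- suppressWarnings(sp_select(x, ds$meta, fdr = NA))
  expect_identical(sel2$table$feature_id[1], "P0001")

  # zero-variance proteins are guarded with a warning
  z <- toy_matrix(c(rep(5, 8), rnorm(8, 50, 3)), nr = 2, samples = paste0("S", 1:8))
  z <- t(toy_matrix(c(rep(5, 8), rnorm(8, 50, 3)), nr = 8))
  rownames(z) <- c("P1", "P2"); colnames(z) <- paste0("S", 1:8)
  meta <- toy_meta(z, classes = rep(c("D", "D*"), each = 4),
                   batches = rep(c("1", "2"), 4))
  expect_warning(szv <- sp_select(z, meta), "zero variance")
  expect_equal(szv$table$p[szv$table$feature_id == "P1"], 1)
})

test_that("hypergeometric enrichment equals the closed form", {
  bg <- paste0("P", 1:1000)
  diff <- paste0("P", 1:100)
  cs <- complex_set(c("C1", "C2"), members = list(paste0("P", 1:10),
                                                  paste0("P", 900:909)))
  sel <- he_select(diff, cs, bg)
  p_c1 <- sel$table$p[sel$table$feature_id == "C1"]
  expect_equal(p_c1, choose(100, 10) * choose(900, 0) / choose(1000, 10))
  # zero overlap -> upper tail at 0 is 1
  expect_equal(sel$table$p[sel$table$feature_id == "C2"], 1)
  # diff = background forces every overlap, p = 1
  sel_all <- he_select(bg, cs, bg)
  expect_true(all(sel_all$table$p == 1))
  expect_error(he_select(c(diff, "X1"), cs, bg), "outside the background")
  expect_error(he_select(diff, cs, character(0)), "empty background")
})

test_that("rank membership scores follow the cutoffs and tie rules", {
  cfg <- rbna_config(alpha_top = 0.1, alpha_lo = 0.2)
  x <- toy_matrix(c(10:1, 1:10), nr = 10,
                  proteins = paste0("P", 1:10), samples = c("S1", "S2"))
  s <- rank_scores(x, cfg, fuzzy = FALSE)
  expect_equal(colSums(s), c(S1 = 1, S2 = 1))
  expect_equal(s["P1", "S1"], 1)   # highest value in S1
  expect_equal(s["P10", "S2"], 1)

  # fuzzy midpoint: percentile (alpha_top + alpha_lo)/2 scores 0.5
  x20 <- toy_matrix(20:1, nr = 20, proteins = paste0("P", 1:20), samples = "S1")
  x20 <- cbind(x20, x20); colnames(x20) <- c("S1", "S2")
  sf <- rank_scores(x20, cfg, fuzzy = TRUE)
  expect_equal(sf["P3", "S1"], 0.5)   # rank 3/20 = 0.15 = midpoint
  expect_equal(sf["P2", "S1"], 1)     # 0.10 boundary: full membership
  expect_equal(sf["P4", "S1"], 0)     # 0.20 boundary: zero

  # strictly monotone within-sample transforms leave scores unchanged
  ds <- small_dataset(seed = 3, n_proteins = 100)
  s0 <- rank_scores(ds$noisy, cfg, fuzzy = TRUE)
  tr <- ds$noisy
  tr[, 1] <- tr[, 1]^1.7
  tr[, 2] <- log1p(tr[, 2])
  tr[, 3] <- tr[, 3] * 17 + 2
  expect_identical(rank_scores(tr, cfg, fuzzy = TRUE), s0)
})

test_that("complex scoring detects a planted extreme complex", {
  set.seed(4)
  ds <- small_dataset(seed = 4, n_proteins = 120)
  x <- ds$clean
  # members pushed to the top ranks of D* samples, bottom of D samples
  members <- paste0("P", sprintf("%04d", 1:5))
  x[members, ds$meta$class == "D*"] <- 1e5
  x[members, ds$meta$class == "D"] <- 0.01
  cs <- complex_set(c("CX", "CN"), members = list(members, c("P0100", "P0101")))
  cfg <- rbna_config(n_permutations = 200)
  sel <- rbna_select(x, ds$meta, cs, cfg, fuzzy = FALSE, seed = 1)
  row <- sel$table[sel$table$feature_id == "CX", ]
  expect_true(row$selected)
  expect_equal(row$p, min(sel$table$p))
  expect_equal(max(abs(sel$table$statistic)), abs(row$statistic))
})

test_that("permutation p equals exhaustive enumeration on 3-vs-3", {
  set.seed(11)
  x <- toy_matrix(rpois(60, 40), nr = 10, samples = paste0("S", 1:6))
  meta <- toy_meta(x, classes = rep(c("D", "D*"), each = 3),
                   batches = rep(c("1", "2"), 3))
  cs <- complex_set("C1", members = list(c("P1", "P2", "P3")))
  cfg <- rbna_config(alpha_top = 0.3, alpha_lo = 0.5, beta = 0.3,
                     n_permutations = 10L)
  sel <- rbna_select(x, meta, cs, cfg, fuzzy = TRUE, exhaustive = TRUE)

  # independent oracle: enumerate all 20 label splits from scratch
  S <- rank_scores(x, cfg, fuzzy = TRUE)[c("P1", "P2", "P3"), ]
  obs <- oracle_complex_stat(S, meta$class == "D", cfg$beta)
  combos <- combn(6, 3)
  perms <- apply(combos, 2, function(ix) {
    is_d <- rep(FALSE, 6); is_d[ix] <- TRUE
    oracle_complex_stat(S, is_d, cfg$beta)
  })
  p_oracle <- (1 + sum(abs(perms) >= abs(obs))) / (1 + length(perms))
  expect_equal(sel$table$p, p_oracle)
  expect_equal(sel$table$statistic, obs)
})

test_that("complexes without contributing members are degenerate", {
  ds <- small_dataset(seed = 6, n_proteins = 100)
  # lowest-abundance proteins never reach the top ranks
  lows <- names(sort(rowMeans(ds$clean)))[1:3]
  cs <- complex_set("CL", members = list(lows))
  sel <- rbna_select(ds$clean, ds$meta, cs, rbna_config(n_permutations = 50),
                     fuzzy = FALSE, seed = 2)
  expect_equal(sel$table$statistic, 0)
  expect_equal(sel$table$p, 1)
  expect_false(sel$table$selected)
})

test_that("selected-complex membership unions deduplicate", {
  cs <- complex_set(c("C1", "C2"), members = list(c("A", "B"), c("B", "C")))
  tab <- data.frame(feature_id = c("C1", "C2"), statistic = c(5, 4),
                    p = c(0.001, 0.002), p_adj = c(0.002, 0.002),
                    selected = c(TRUE, TRUE), stringsAsFactors = FALSE)
  sel <- batchbench:::.selection_result(tab, "complex")
  expect_setequal(proteins_from_complexes(sel, cs), c("A", "B", "C"))
  tab$selected <- FALSE
  sel0 <- batchbench:::.selection_result(tab, "complex")
  expect_length(proteins_from_complexes(sel0, cs), 0L)
})

test_that("RBNA output is invariant under per-sample monotone transforms", {
  ds <- small_dataset(seed = 7, n_proteins = 150)
  cs <- make_pseudocomplexes(ds$clean, ds$truth, n = 10, seed = 3)
  cfg <- rbna_config(n_permutations = 100)
  sel1 <- rbna_select(ds$noisy, ds$meta, cs, cfg, fuzzy = TRUE, seed = 5)
  tr <- ds$noisy
  for (j in seq_len(ncol(tr))) tr[, j] <- tr[, j]^(1 + j / 10) + j
  sel2 <- rbna_select(tr, ds$meta, cs, cfg, fuzzy = TRUE, seed = 5)
  expect_equal(sel1$table, sel2$table)
})
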