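test_that("precision/recall/F covers exact, printed and guarded cases", {
  m <- precision_recall_f(c("A", "B"), c("A", "B"))
  expect_equal(unlist(m[c("precision", "recall", "f_score")]),
               c(precision = 1, recall = 1, f_score = 1))

  # printed two-decimal F values follow from the harmonic mean
  expect_equal(round(2 * 1 * 0.35 / (1 + 0.35), 2), 0.52)
  m2 <- precision_recall_f(paste0("T", 1:35), paste0("T", 1:100))
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 0.35)
  expect_equal(round(m2$f_score, 2), 0.52)
  expect_equal(round(2 * 0.93 * 0.43 / (0.93 + 0.43), 2), 0.59)

  # zero-selection convention: precision 1 with explicit flag, F 0
  z <- precision_recall_f(character(0), c("A"))
  expect_equal(z$precision, 1)
  expect_equal(z$recall, 0)
  expect_equal(z$f_score, 0)
  expect_equal(z$n_selected, 0L)
  expect_error(precision_recall_f("A", character(0)), "empty truth")
})

test_that("jaccard handles boundaries and the printed magnitude", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  # |intersection| 30 over |union| 49 reproduces the printed 0.61
  a <- paste0("p", 1:40); b <- c(paste0("p", 11:40), paste0("q", 1:9))
  expect_equal(jaccard(a, b), 30 / 49)
  expect_error(jaccard(character(0), character(0)), "empty")
})

test_that("complex-level evaluation respects TP/TN labels", {
  cs <- complex_set(c("T1", "T2", "N1", "N2"),
                    members = list(c("a", "b"), c("c", "d"),
                                   c("e", "f"), c("g", "h")),
                    truth_label = c("TP", "TP", "TN", "TN"))
  mk <- function(ids) {
    tab <- data.frame(feature_id = cs$complex_id, statistic = 1,
                      p = ifelse(cs$complex_id %in% ids, 0.01, 0.9),
                      p_adj = NA_real_,
                      selected = cs$complex_id %in% ids,
                      stringsAsFactors = FALSE)
    batchbench:::.selection_result(tab, "complex")
  }
  all_tp <- complex_level_eval(mk(c("T1", "T2")), cs)
  expect_equal(unlist(all_tp[c("precision", "recall", "f_score")]),
               c(precision = 1, recall = 1, f_score = 1))
  everything <- complex_level_eval(mk(cs$complex_id), cs)
  expect_equal(everything$precision, 0.5)
  expect_equal(everything$recall, 1)
  expect_equal(everything$f_score, 2 / 3)

  cs_u <- cs; cs_u$truth_label[1] <- "unknown"
  expect_error(complex_level_eval(mk("T1"), cs_u), "label")
})

test_that("random selectors are half-right on balanced labels on average", {
  set.seed(12)
  cs <- complex_set(paste0("C", 1:40),
                    members = rep(list(c("a", "b")), 40),
                    truth_label = rep(c("TP", "TN"), each = 20))
  prec <- replicate(300, {
    picked <- cs$complex_id[runif(40) < 0.3]
    if (!length(picked)) return(NA)
    mean(picked %in% cs$complex_id[cs$truth_label == "TP"])
  })
  expect_equal(mean(prec, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("the benchmark table has the configured shape and wiring", {
  cfg <- benchmark_config(replicates = 2L,
                          sim = sim_config(n_proteins = 150, seed = 40),
                          conditions = c("no_batch", "batch", "linear"),
                          methods = "sp", purities = 1)
  tab <- suppressWarnings(run_benchmark(cfg))
  expect_equal(nrow(tab), 2L * 3L)
  expect_setequal(unique(tab$condition), c("no_batch", "batch", "linear"))

  # no-batch rows use the clean matrix of the pair
  ds <- simulate_dataset(sim_config(n_proteins = 150, seed = 40))
  direct <- precision_recall_f(
    selected_ids(suppressWarnings(sp_select(ds$clean, ds$meta, fdr = NA))),
    ds$truth$protein_id)
  row <- tab[tab$replicate == 1 & tab$condition == "no_batch", ]
  expect_equal(row$f_score, direct$f_score)

  # bitwise reproducibility given the config
  tab2 <- suppressWarnings(run_benchmark(cfg))
  expect_identical(tab, tab2)

  # emitted rows satisfy the harmonic-mean identity and bounds
  with(tab, {
    expect_true(all(precision >= 0 & precision <= 1))
    expect_true(all(recall >= 0 & recall <= 1))
    pr <- precision + recall
    expect_equal(f_score[pr > 0], (2 * precision * recall / pr)[pr > 0])
  })

  rounded <- format_benchmark(tab)
  expect_true(all(rounded$f_score == round(rounded$f_score, 2)))
})

test_that("batch effects do not raise the median SP F-score", {
  cfg <- benchmark_config(replicates = 20L,
                          sim = sim_config(n_proteins = 200, seed = 60),
                          conditions = c("no_batch", "batch"),
                          methods = "sp_fdr", purities = 1)
  tab <- suppressWarnings(run_benchmark(cfg))
  med <- tapply(tab$f_score, tab$condition, median)
  expect_lte(med[["batch"]], med[["no_batch"]])
})
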