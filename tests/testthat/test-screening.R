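test_that("class statistics match hand arithmetic on an 8-sample toy", {
  st <- class_stats(hand_stats_cohort())
  g1 <- as.list(st[st$gene == "G1", ])
  expect_equal(g1$mean_n, 2.5)
  expect_equal(g1$mean_t, 6.5)
  expect_equal(g1$sd_t, sd(c(5, 6, 7, 8)))
  expect_equal(g1$rc_mean, abs(6.5 - 2.5) / 2.5)
  expect_equal(g1$sharpe_t, 6.5 / sd(c(5, 6, 7, 8)))
  expect_equal(g1$rc_sharpe,
               abs(6.5 / sd(5:8) - 2.5 / sd(1:4)) / (2.5 / sd(1:4)))
})

test_that("a gene with equal class means has zero mean change", {
  x <- cbind(G1 = c(1, 3, 2, 2), G2 = c(5, 5, 7, 7))
  co <- cohort(x, c(0L, 0L, 1L, 1L), cohort_id = "eq")
  st <- class_stats(co)
  expect_equal(st$rc_mean[st$gene == "G1"], 0)
})

test_that("constant genes are excluded from the Sharpe ranking but kept for means", {
  st <- class_stats(hand_stats_cohort())
  g2 <- st[st$gene == "G2", ]   # constant within each class
  expect_false(g2$sharpe_defined)
  expect_true(is.na(g2$rc_sharpe))
  expect_false(is.na(g2$rc_mean))
  kept <- percentile_screen(st, screening_config(pct_sharpe = 100, pct_mean = 100))
  expect_false("G2" %in% kept$sharpe)
  expect_true("G2" %in% kept$mean)
})

test_that("single-class cohorts are rejected", {
  x <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(class_stats(cohort(x, rep(1L, 4))), "classes")
})

test_that("percentile tails select ceil-sized sets that match a sort oracle", {
  set.seed(105)
  n <- 200
  st <- tibble::tibble(
    gene = sprintf("G%03d", 1:n),
    rc_mean = runif(n), rc_sd = runif(n), rc_sharpe = runif(n),
    sharpe_defined = TRUE
  )
  kept <- percentile_screen(st, screening_config())
  expect_length(kept$sharpe, 10)            # top 5% of 200
  expect_setequal(kept$sharpe, st$gene[order(-st$rc_sharpe)][1:10])
  expect_length(kept$sd, 30)                # top 15%
  expect_length(kept$mean, 2)               # bottom 1%
  expect_setequal(kept$mean, st$gene[order(st$rc_mean)][1:2])
})

test_that("all-equal changes fill the tail in gene-identifier order", {
  st <- tibble::tibble(
    gene = sprintf("G%02d", 1:10),
    rc_mean = 1, rc_sd = 1, rc_sharpe = 1,
    sharpe_defined = TRUE
  )
  kept <- percentile_screen(st, screening_config(pct_sharpe = 30))
  expect_identical(kept$sharpe, c("G01", "G02", "G03"))
})

test_that("separation filter keeps cleanly separated genes and drops null ones", {
  set.seed(106)
  n <- 40
  lab <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(
    SEP = ifelse(lab == 1L, 10, 0) + rnorm(n, sd = 0.3),  # fully separated
    NUL = rnorm(n)                                        # identical classes
  )
  co <- cohort(x, lab, cohort_id = "sep")
  expect_identical(separation_filter(co, c("SEP", "NUL"), 0.5), "SEP")
  expect_identical(separation_filter(co, character(0), 0.5), character(0))
})

test_that("separation threshold comparison is inclusive, against a hand count", {
  # 10 controls max = 10; exactly 5 of 10 tumors above it
  x <- cbind(G = c(1:10, c(11, 12, 13, 14, 15, 5, 6, 7, 8, 9)))
  co <- cohort(x, rep(c(0L, 1L), each = 10), cohort_id = "edge")
  expect_identical(separation_filter(co, "G", 0.5), "G")
  expect_identical(separation_filter(co, "G", 0.51), character(0))
})

test_that("the full screen recovers planted strongly separated genes", {
  sim <- generate_cohort(sim_config(K = 1, seed = 301), 1)
  cands <- candidate_genes(mvs_cgs(sim$cohort))
  expect_true(all(sim$truth$causal_genes %in% cands))
  expect_lte(length(setdiff(cands, sim$truth$causal_genes)), 3)
})

test_that("a null cohort yields an empty or near-empty candidate set", {
  sim <- generate_cohort(sim_config(K = 1, n_causal = 0, n = 200, seed = 302), 1)
  cands <- candidate_genes(mvs_cgs(sim$cohort))
  expect_lte(length(cands), 2)
})

test_that("vacuous configuration keeps every gene with defined statistics", {
  co <- separable_cohort()
  cfg <- screening_config(pct_mean = 100, pct_sd = 100, pct_sharpe = 100,
                          sep_sharpe = 0, sep_mean = 0, sep_sd = 0)
  cands <- candidate_genes(mvs_cgs(co, cfg))
  expect_setequal(cands, co$gene_ids)
})

test_that("screening is invariant to sample and gene order", {
  sim <- generate_cohort(sim_config(K = 1, n = 120, n_genes = 40, seed = 303), 1)
  co <- sim$cohort
  set.seed(1)
  perm_s <- sample(nrow(co$expression))
  perm_g <- sample(ncol(co$expression))
  co2 <- cohort(co$expression[perm_s, perm_g], co$labels[perm_s],
                cohort_id = "perm")
  expect_setequal(candidate_genes(mvs_cgs(co)), candidate_genes(mvs_cgs(co2)))
})

test_that("positive rescaling of a cohort leaves the screen unchanged", {
  sim <- generate_cohort(sim_config(K = 1, n = 120, n_genes = 40, seed = 304), 1)
  co <- sim$cohort
  co_scaled <- cohort(co$expression * 37.5, co$labels, cohort_id = "scaled")
  st <- class_stats(co); st2 <- class_stats(co_scaled)
  expect_equal(st2$sharpe_t, st$sharpe_t)
  expect_equal(st2$rc_mean, st$rc_mean)
  expect_equal(st2$rc_sd, st$rc_sd)
  expect_setequal(candidate_genes(mvs_cgs(co)), candidate_genes(mvs_cgs(co_scaled)))
})

test_that("candidate set shrinks with stricter separation and grows with wider tails", {
  sim <- generate_cohort(sim_config(K = 1, n = 150, n_genes = 60, seed = 305), 1)
  co <- sim$cohort
  loose <- candidate_genes(mvs_cgs(co, screening_config(sep_sharpe = 0.3, sep_mean = 0.3, sep_sd = 0.3)))
  strict <- candidate_genes(mvs_cgs(co, screening_config(sep_sharpe = 0.9, sep_mean = 0.9, sep_sd = 0.9)))
  expect_true(all(strict %in% loose))
  narrow <- candidate_genes(mvs_cgs(co, screening_config(pct_sharpe = 2)))
  wide <- candidate_genes(mvs_cgs(co, screening_config(pct_sharpe = 50)))
  expect_true(all(narrow %in% wide))
})

test_that("the squared-transform pass intersects candidate sets", {
  sim <- generate_cohort(sim_config(K = 1, seed = 306), 1)
  plain <- candidate_genes(mvs_cgs(sim$cohort))
  common <- candidate_genes(mvs_cgs(sim$cohort, screening_config(squared_transform = TRUE)))
  expect_true(all(common %in% plain))
})
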