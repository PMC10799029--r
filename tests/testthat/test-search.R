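test_that("partition draws are forced, deterministic under a seed, and uniform", {
  set.seed(1)
  forced <- draw_partition(c("A", "B", "C"), 3)
  expect_setequal(forced[[1]], c("A", "B", "C"))
  set.seed(42); d1 <- draw_partition(letters[1:10], c(3, 2))
  set.seed(42); d2 <- draw_partition(letters[1:10], c(3, 2))
  expect_identical(d1, d2)
  expect_error(draw_partition(c("A"), 2), "candidate")
  # inclusion frequency of draws of 3 from 10 is ~0.3
  set.seed(43)
  counts <- table(unlist(replicate(4000, draw_partition(letters[1:10], 3)[[1]])))
  phat <- as.numeric(counts) / 4000
  se <- sqrt(0.3 * 0.7 / 4000)
  expect_true(all(abs(phat - 0.3) < 3 * se))
})

test_that("a separable single-factor toy fits to zero training errors", {
  co <- separable_cohort()
  fits <- fit_max_logistic(co, list(c("A", "B")))
  expect_equal(misclassification_count(fits[[1]], co), 0)
})

test_that("two factors solve the two-cluster geometry a single factor cannot", {
  co <- xor_cohort()
  one <- fit_max_logistic(co, list(c("A", "B")))
  two <- fit_max_logistic(co, list(c("A", "B"), c("A", "B")))
  expect_gt(misclassification_count(one[[1]], co), 0)
  expect_equal(misclassification_count(two[[1]], co), 0)
})

test_that("the surrogate fit attains the lattice-optimal 0-1 loss on a tiny instance", {
  set.seed(107)
  x <- matrix(rnorm(16, sd = 2), 8, 2, dimnames = list(NULL, c("A", "B")))
  lab <- as.integer(x[, "A"] + 0.5 * x[, "B"] + rnorm(8, sd = 0.5) > 0)
  if (length(unique(lab)) < 2) lab[1] <- 1L - lab[1]
  co <- cohort(x, lab, cohort_id = "grid")
  # coarse lattice oracle over single-factor coefficients
  grid <- seq(-3, 3, by = 0.5)
  best <- Inf
  for (b0 in grid) for (b1 in grid) for (b2 in grid) {
    p <- plogis(b0 + b1 * x[, "A"] + b2 * x[, "B"])
    best <- min(best, sum((p > 0.5) != lab))
  }
  fits <- fit_max_logistic(co, list(c("A", "B")))
  expect_lte(misclassification_count(fits[[1]], co), best)
})

test_that("degenerate single-class cohorts are rejected by the fitter", {
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("A", "B")))
  co <- cohort(x, rep(1L, 5))
  expect_error(fit_max_logistic(co, list(c("A"))), "single class")
})

test_that("recording screen: vacuous levels record every drawn gene", {
  co <- separable_cohort()
  cfg <- search_config(group_size = 1, n_draws = 30, sen = 1e-6, spe = 1e-6)
  set.seed(108)
  rec <- screen_draws(co, c("A", "B"), cfg)
  expect_setequal(rec$gene, c("A", "B"))
  expect_equal(sum(rec$times_recorded), 30)
})

test_that("recording screen: null data records nothing, with a warning", {
  sim <- generate_cohort(sim_config(K = 1, n = 100, n_genes = 20, n_causal = 0,
                                    seed = 307), 1)
  set.seed(109)
  expect_warning(
    rec <- screen_draws(sim$cohort, sim$cohort$gene_ids,
                        search_config(group_size = 2, n_draws = 25)),
    "No draw"
  )
  expect_equal(nrow(rec), 0)
})

test_that("recording screen finds planted genes and respects the candidate pool", {
  sim <- generate_multicohort(sim_config(seed = 308, n = 200))
  causal <- sim$truth[[1]]$causal_genes
  pool <- c(causal, paste0("G0", 50:53))
  set.seed(110)
  rec <- screen_draws(sim$cohorts, pool,
                      search_config(group_size = 2, n_draws = 120))
  expect_true(all(rec$gene %in% pool))
  expect_true(all(causal %in% rec$gene))
})

test_that("raising the recording levels never enlarges the recorded set", {
  sim <- generate_multicohort(sim_config(seed = 309, n = 150))
  pool <- sim$truth[[1]]$causal_genes
  set.seed(111)
  lo <- screen_draws(sim$cohorts, pool, search_config(group_size = 2, n_draws = 60,
                                                      sen = 0.5, spe = 0.5))
  set.seed(111)
  hi <- screen_draws(sim$cohorts, pool, search_config(group_size = 2, n_draws = 60,
                                                      sen = 0.9, spe = 0.95))
  expect_true(all(hi$gene %in% lo$gene))
})

test_that("Monte-Carlo search equals exhaustive enumeration on a tiny instance", {
  sim <- generate_cohort(sim_config(K = 1, n = 80, n_genes = 6, seed = 310), 1)
  co <- sim$cohort
  cands <- co$gene_ids  # 6 genes: 4 causal + 2 null
  oracle <- exhaustive_minimum(co, cands, G = 2, size = 2)
  set.seed(112)
  res <- monte_carlo_search(co, search_config(G = 2, group_size = 2, n_draws = 250),
                            candidates = cands)
  expect_equal(res$objective, oracle, tolerance = 1e-12)
})

test_that("a dominant sparsity penalty selects the smallest zero-error union", {
  co <- separable_cohort()  # gene A alone separates
  set.seed(113)
  res <- monte_carlo_search(
    co,
    search_config(G = 1, group_size = 1, n_draws = 30,
                  penalty = penalty_config(lambda1 = 0, lambda2 = 1e6)),
    candidates = c("A", "B")
  )
  expect_identical(gene_union(res$classifiers[[1]]), "A")
})

test_that("the search trace is reproducible from the seed", {
  sim <- generate_cohort(sim_config(K = 1, n = 100, n_genes = 10, seed = 311), 1)
  cfg <- search_config(G = 2, group_size = 2, n_draws = 40)
  set.seed(114)
  r1 <- monte_carlo_search(sim$cohort, cfg, candidates = sim$cohort$gene_ids)
  set.seed(114)
  r2 <- monte_carlo_search(sim$cohort, cfg, candidates = sim$cohort$gene_ids)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$partition, r2$partition)
  expect_identical(tidy(r1$classifiers[[1]]), tidy(r2$classifiers[[1]]))
})

test_that("criteria checker reproduces the published-report pattern", {
  pub <- published_classifiers()
  pub <- pub[pub$dataset != "total", ]
  # final per-dataset metrics: the combined "Max" row where present,
  # otherwise the dataset's single classifier (dataset 4 uses its
  # stage-1 single-gene factor)
  metrics <- dplyr::bind_rows(lapply(unique(pub$dataset), function(d) {
    rows <- pub[pub$dataset == d, ]
    r <- if (any(rows$factor == "Max")) {
      rows[rows$factor == "Max", ]
    } else if (any(rows$factor == "CF1")) {
      rows[rows$factor == "CF1", ]
    } else {
      rows[1, ]
    }
    tibble::tibble(id = d, n = r$n_tumor + r$n_control, accuracy = r$accuracy,
                   sensitivity = r$sensitivity, specificity = r$specificity)
  }))
  classifiers <- lapply(unique(pub$dataset), function(d) {
    published_classifier_for(d, include_stage = d == "4")
  })
  rep <- check_critical_criteria(metrics, classifiers)
  passes <- rep$report$pass
  expect_true(passes[1])  # 4 genes <= 15
  expect_true(passes[2])  # >= 3 cohorts at >= 95% totaling >= 1000 subjects
  expect_true(passes[3])  # GSE9348: 100% at 82 subjects
  expect_true(passes[4])  # consistent signs exist
  expect_true(passes[5])  # every cohort >= 80% with sens or spec > 75%
  expect_true(is.na(passes[6]) && is.na(passes[7]))
  expect_match(rep$report$evidence[4], "CXCL8")
  expect_match(rep$report$evidence[4], "PSMC2")
})

test_that("criteria boundaries are inclusive where the rules say at least", {
  cls <- max_logistic(competing_factor(-1, c(A = 1)))
  m9 <- tibble::tibble(id = "tiny", n = 9, accuracy = 100,
                       sensitivity = 100, specificity = 100)
  expect_false(check_critical_criteria(m9, cls)$report$pass[3])
  m10 <- dplyr::mutate(m9, n = 10)
  expect_true(check_critical_criteria(m10, cls)$report$pass[3])
  m3 <- tibble::tibble(
    id = c("a", "b", "c"), n = c(400, 300, 300),
    accuracy = 95, sensitivity = 90, specificity = 90
  )
  expect_true(check_critical_criteria(m3, cls)$report$pass[2])
  expect_false(check_critical_criteria(dplyr::mutate(m3, n = c(399, 300, 300)),
                                       cls)$report$pass[2])
})

test_that("sign consistency fails when a gene flips direction across cohorts", {
  cls_pos <- max_logistic(competing_factor(-1, c(A = 1, B = 2)))
  cls_flip <- max_logistic(competing_factor(-1, c(A = -1, B = 2)))
  m <- tibble::tibble(id = c("k1", "k2"), n = c(50, 50), accuracy = 99,
                      sensitivity = 99, specificity = 99)
  rep_ok <- check_critical_criteria(m, list(cls_pos, cls_pos))
  rep_flip <- check_critical_criteria(m, list(cls_pos, cls_flip))
  expect_true(rep_ok$report$pass[4])
  expect_true(rep_flip$report$pass[4])          # B still consistent
  expect_match(rep_flip$report$evidence[4], "B")
  expect_false(grepl("A", rep_flip$report$evidence[4]))
})
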