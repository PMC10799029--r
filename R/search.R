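#' Search configuration
#'
#' Settings for the Monte-Carlo subset search: the number of competing
#' factors `G` drawn in the final stage, genes per draw, draw counts,
#' the sensitivity/specificity recording levels of the gene-screening
#' stage, the recorded-gene shrink target, and the penalty weights. The
#' published procedure uses 50,000 draws per round; tests and examples
#' pass smaller counts explicitly.
#'
#' @param G Number of factor groups in the final search stage (default 1).
#' @param group_size Genes drawn per group (default 3).
#' @param n_draws Random draws per round (default 50000).
#' @param sen,spe Recording levels on sensitivity/specificity as
#'   proportions (defaults 0.6 and 0.90); a draw is recorded only when it
#'   exceeds both levels in every cohort.
#' @param shrink_target Maximum recorded genes before levels are raised
#'   (default 30).
#' @param level_step Increment added to both levels per shrink round
#'   (default 0.05).
#' @param penalty A [penalty_config()].
#' @param max_iter Iteration cap of the coefficient fitter (default 25).
#' @return A list of class `cfmax_search_config`.
#' @export
search_config <- function(G = 1, group_size = 3, n_draws = 50000,
                          sen = 0.6, spe = 0.90, shrink_target = 30,
                          level_step = 0.05, penalty = penalty_config(),
                          max_iter = 25) {
  stopifnot(G >= 1, group_size >= 1, n_draws >= 1,
            sen > 0, sen < 1, spe > 0, spe < 1, shrink_target >= 1)
  structure(
    list(G = G, group_size = group_size, n_draws = n_draws,
         sen = sen, spe = spe, shrink_target = shrink_target,
         level_step = level_step, penalty = penalty, max_iter = max_iter),
    class = "cfmax_search_config"
  )
}

#' Draw a random gene partition
#'
#' Each group is drawn uniformly without replacement from the candidate
#' pool; groups are drawn independently, so the same gene may appear in
#' several factors (shared genes across factors are a feature of the
#' model, not an error).
#'
#' @param candidates Character vector of candidate genes.
#' @param sizes Integer vector of per-group sizes.
#' @return List of character vectors (the partition groups).
#' @export
draw_partition <- function(candidates, sizes) {
  if (length(candidates) < max(sizes)) {
    abort(sprintf(
      "Need at least %d candidate genes for a group, got %d.",
      max(sizes), length(candidates)
    ))
  }
  map(sizes, function(g) sample(candidates, g))
}

# logistic fit of the given tumor rows vs all controls on a gene group
fit_one_factor <- function(expr, y, tumor_rows, ctrl_rows, genes) {
  if (length(tumor_rows) == 0) return(inactive_factor())
  idx <- c(tumor_rows, ctrl_rows)
  X <- cbind(`(Intercept)` = 1, expr[idx, genes, drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(X, y[idx], family = stats::binomial())
  )
  b <- fit$coefficients
  b[is.na(b)] <- 0
  competing_factor(b[1], stats::setNames(b[-1], genes))
}

# deterministic initial hard assignment of tumors to G factors
init_assignment <- function(expr_union, tumor_rows, G) {
  if (G == 1L || length(tumor_rows) < 2 * G) {
    return(rep(1L, length(tumor_rows)))
  }
  x <- scale(expr_union[tumor_rows, , drop = FALSE])
  x[is.nan(x)] <- 0
  stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = G)
}

#' Fit max-logistic coefficients on a fixed gene partition
#'
#' Per cohort, finds factor coefficients that locally minimize the 0-1
#' loss by alternating hard assignment with a smooth surrogate: tumors are
#' first split across factors by Ward clustering on the partition genes
#' (all tumors to the single factor when `G = 1`), each factor is fitted
#' by logistic regression of its assigned tumors against all controls,
#' then the loop reassigns every tumor to its best-scoring factor and
#' refits, accepting an iterate only when it strictly reduces the
#' misclassification count. The accept step makes the error count
#' monotonically non-increasing; the procedure involves no randomness.
#'
#' @param cohorts A [cohort()] or list of cohorts.
#' @param partition List of gene-identifier character vectors, one per
#'   factor group (shared across cohorts).
#' @param threshold Probability cutoff of the fitted classifiers.
#' @param max_iter Reassignment iteration cap (default 25). If the loop is
#'   still improving at the cap, the best iterate is returned with a
#'   warning.
#' @param init Optional warm start: a `cfmax_classifier` on the same
#'   partition (or a per-cohort list of them) used as the incumbent
#'   iterate, so the fit never ends worse than the starting coefficients.
#' @return Named list of per-cohort `cfmax_classifier` objects.
#' @export
fit_max_logistic <- function(cohorts, partition, threshold = 0.5,
                             max_iter = 25, init = NULL) {
  cohorts <- as_cohort_list(cohorts)
  partition <- map(partition, toupper)
  if (inherits(init, "cfmax_classifier")) {
    init <- rep(list(init), length(cohorts))
  }
  out <- map(seq_along(cohorts), function(k) {
    co <- cohorts[[k]]
    if (length(unique(co$labels)) < 2) {
      abort(sprintf("Cohort '%s' has a single class; cannot fit.", co$cohort_id))
    }
    fit_cohort_factors(co, partition, threshold, max_iter, init[[k]])
  })
  names(out) <- names(cohorts)
  out
}

fit_cohort_factors <- function(co, groups, threshold, max_iter, init = NULL) {
  union_genes <- unique(unlist(groups))
  expr <- cohort_genes(co, union_genes)
  y <- co$labels
  tum <- which(y == 1L)
  ctrl <- which(y == 0L)
  G <- length(groups)

  assign0 <- init_assignment(expr, tum, G)
  factors <- map(seq_len(G), function(j) {
    fit_one_factor(co$expression, y, tum[assign0 == j], ctrl, groups[[j]])
  })
  cls <- max_logistic(factors, threshold, cohort_id = co$cohort_id)
  best_cnt <- misclassification_count(cls, co)
  if (!is.null(init)) {
    init_cnt <- misclassification_count(init, co)
    if (init_cnt < best_cnt) {
      cls <- max_logistic(init$factors, threshold, cohort_id = co$cohort_id)
      best_cnt <- init_cnt
    }
  }

  improved_at_cap <- FALSE
  for (it in seq_len(max_iter)) {
    s <- factor_scores(expr, cls)
    winner <- max.col(s, ties.method = "first")
    factors_new <- map(seq_len(G), function(j) {
      fit_one_factor(co$expression, y, tum[winner[tum] == j], ctrl, groups[[j]])
    })
    if (!any(map_lgl(factors_new, is_active))) break
    cand <- max_logistic(factors_new, threshold, cohort_id = co$cohort_id)
    cnt <- misclassification_count(cand, co)
    if (cnt < best_cnt) {
      cls <- cand
      best_cnt <- cnt
      improved_at_cap <- it == max_iter
    } else {
      break
    }
  }
  if (improved_at_cap) {
    warn(sprintf(
      "Coefficient fit on cohort '%s' hit the iteration cap while still improving; returning the best iterate.",
      co$cohort_id
    ))
  }
  cls
}

# per-cohort sensitivity/specificity of a fitted classifier list
cohort_senspe <- function(classifiers, cohorts) {
  bind_rows(map(seq_along(cohorts), function(k) {
    sc <- score_samples(cohorts[[k]], classifiers[[k]])
    confusion_metrics(sc$pred, sc$label, id = cohorts[[k]]$cohort_id)
  }))
}

#' Screen random gene draws by sensitivity and specificity
#'
#' The gene-filtering stage of the search: draws single-factor gene sets,
#' fits them on every cohort, and records the drawn genes whenever the
#' fitted classifier's sensitivity and specificity both exceed the
#' configured levels in every cohort. If the distinct recorded genes
#' outnumber `shrink_target`, both levels are raised by `level_step` and
#' the draws repeat restricted to the recorded genes, until the recorded
#' set is small enough.
#'
#' @param cohorts A cohort or list of cohorts.
#' @param candidates Candidate gene pool (e.g. from [candidate_genes()]).
#' @param config A [search_config()].
#' @return A tibble (`gene`, `times_recorded`) sorted by recording
#'   frequency, with the final `sen`/`spe` levels and a per-round trace as
#'   attributes. Empty (with a warning) when no draw passes the initial
#'   levels.
#' @export
screen_draws <- function(cohorts, candidates, config = search_config()) {
  cohorts <- as_cohort_list(cohorts)
  if (length(candidates) == 0) abort("`candidates` is empty.")
  candidates <- toupper(candidates)
  sen <- config$sen
  spe <- config$spe
  pool <- candidates
  trace <- list()
  recorded <- character(0)
  repeat {
    tally <- integer(0)
    for (d in seq_len(config$n_draws)) {
      genes <- sample(pool, min(config$group_size, length(pool)))
      fits <- fit_max_logistic(cohorts, list(genes),
                               max_iter = config$max_iter)
      m <- cohort_senspe(fits, cohorts)
      ok <- all(m$sensitivity > 100 * sen, na.rm = FALSE) &&
        all(m$specificity > 100 * spe, na.rm = FALSE) &&
        !anyNA(c(m$sensitivity, m$specificity))
      if (ok) {
        for (g in genes) {
          tally[g] <- if (is.na(tally[g])) 1L else tally[g] + 1L
        }
      }
    }
    recorded <- names(tally)
    trace[[length(trace) + 1]] <- tibble(
      round = length(trace) + 1L, sen = sen, spe = spe,
      n_recorded = length(recorded)
    )
    if (length(recorded) == 0) {
      warn("No draw exceeded the recording levels; returning an empty record (consider lowering `sen`/`spe`).")
      break
    }
    if (length(recorded) <= config$shrink_target) break
    sen <- min(sen + config$level_step, 0.99)
    spe <- min(spe + config$level_step, 0.99)
    pool <- recorded
  }
  out <- tibble(
    gene = names(tally) %||% character(0),
    times_recorded = as.integer(unname(tally))
  ) |>
    arrange(desc(.data$times_recorded), .data$gene)
  attr(out, "levels") <- c(sen = sen, spe = spe)
  attr(out, "trace") <- bind_rows(trace)
  out
}

#' Monte-Carlo search for the penalized-objective minimizer
#'
#' Draws `n_draws` random partitions of `G` groups among the candidate
#' genes, fits max-logistic coefficients on every cohort for each, scores
#' each fitted set by the penalized 0-1-loss objective, and returns the
#' minimizer together with its critical-criteria report. Ties in the
#' objective are broken by draw order, so results are reproducible from
#' the RNG seed set before the call. When `candidates` is `NULL` the
#' recording screen ([screen_draws()]) supplies them first.
#'
#' @param cohorts A cohort or list of cohorts.
#' @param config A [search_config()].
#' @param candidates Optional candidate genes; computed by [screen_draws()]
#'   when missing.
#' @return A list of class `cfmax_search`: `classifiers` (per cohort),
#'   `partition`, `objective` (log domain), `metrics` (per-cohort tibble),
#'   `criteria` (a `cfmax_criteria` report), `trace` (per-draw objective),
#'   `recorded` (the screen's gene record, when run).
#' @export
monte_carlo_search <- function(cohorts, config = search_config(),
                               candidates = NULL) {
  cohorts <- as_cohort_list(cohorts)
  recorded <- NULL
  if (is.null(candidates)) {
    recorded <- screen_draws(cohorts, unique(unlist(map(cohorts, "gene_ids"))),
                             config)
    candidates <- recorded$gene
  }
  candidates <- toupper(candidates)
  if (length(candidates) < config$group_size) {
    abort("Too few candidate genes for the configured group size.")
  }
  best <- NULL
  trace <- vector("list", config$n_draws)
  for (d in seq_len(config$n_draws)) {
    part <- draw_partition(candidates, rep(config$group_size, config$G))
    fits <- fit_max_logistic(cohorts, part, max_iter = config$max_iter)
    obj <- penalized_objective(fits, cohorts, config$penalty)
    trace[[d]] <- tibble(
      draw = d, objective = obj,
      su = length(gene_union(fits[[1]]))
    )
    if (is.null(best) || obj < best$objective) {
      best <- list(classifiers = fits, partition = part, objective = obj)
    }
  }
  metrics <- cohort_senspe(best$classifiers, cohorts)
  criteria <- check_critical_criteria(metrics, best$classifiers)
  structure(
    c(best, list(metrics = metrics, criteria = criteria,
                 trace = bind_rows(trace), recorded = recorded)),
    class = "cfmax_search"
  )
}

#' @export
print.cfmax_search <- function(x, ...) {
  cat(sprintf(
    "<cfmax_search>  best objective (log) %.4f, gene union {%s}\n",
    x$objective, paste(gene_union(x$classifiers[[1]]), collapse = ", ")
  ))
  print(x$criteria)
  invisible(x)
}

#' Check the critical-gene-set criteria
#'
#' Evaluates the seven acceptance rules a candidate signature must meet:
#' (1) the gene union has at most 15 genes; (2) accuracy of at least 95%
#' in at least three cohorts whose combined size is at least 1000
#' subjects; (3) accuracy of 100% in at least one cohort of at least 10
#' subjects; (4) at least one gene carries the same coefficient sign in
#' every cohort; (5) every cohort reaches at least 80% accuracy with
#' sensitivity or specificity above 75%; (6) and (7) — minimal gene and
#' factor counts among tied solutions — are reported as tie-break
#' metadata, not pass/fail. Thresholds in (2) and (3) are inclusive.
#'
#' @param metrics Per-cohort tibble with columns `id`, `n`, `accuracy`,
#'   `sensitivity`, `specificity` (percent scale).
#' @param classifiers Per-cohort list of `cfmax_classifier` sharing one
#'   partition (used for the union size and sign consistency).
#' @return A `cfmax_criteria` object: tibble `report` plus `overall`
#'   (pass iff criteria 1-5 all pass).
#' @export
check_critical_criteria <- function(metrics, classifiers) {
  if (inherits(classifiers, "cfmax_classifier")) classifiers <- list(classifiers)
  su <- gene_union(classifiers[[1]])
  n_factors <- sum(map_lgl(classifiers[[1]]$factors, is_active))

  # per-gene coefficient signs per cohort; a gene is sign-consistent when it
  # carries a single sign in every cohort in which it appears (cohorts whose
  # classifier omits the gene do not disqualify it)
  sign_tbl <- map(classifiers, function(cl) {
    tidy(cl) |>
      filter(.data$term != "(Intercept)", .data$estimate != 0) |>
      distinct(.data$term, sign = sign(.data$estimate))
  })
  consistent <- map_lgl(su, function(g) {
    signs <- map(sign_tbl, function(tb) unique(tb$sign[tb$term == g]))
    signs <- signs[map_int(signs, length) > 0L]
    if (length(signs) == 0 || any(map_int(signs, length) > 1L)) return(FALSE)
    length(unique(unlist(signs))) == 1L
  })

  hi <- metrics |> filter(.data$accuracy >= 95)
  c1 <- length(su) <= 15
  c2 <- nrow(hi) >= 3 && sum(hi$n) >= 1000
  c3 <- any(metrics$accuracy >= 100 - 1e-9 & metrics$n >= 10)
  c4 <- any(consistent)
  c5 <- all(metrics$accuracy >= 80 &
              (metrics$sensitivity > 75 | metrics$specificity > 75),
            na.rm = FALSE) && !anyNA(metrics$accuracy)
  report <- tibble(
    criterion = 1:7,
    rule = c(
      "gene union has <= 15 genes",
      "accuracy >= 95% in >= 3 cohorts totaling >= 1000 subjects",
      "accuracy = 100% in >= 1 cohort with >= 10 subjects",
      ">= 1 gene with a consistent coefficient sign in every cohort",
      "every cohort: accuracy >= 80% and sensitivity or specificity > 75%",
      "minimal gene count among tied solutions (tie-break)",
      "minimal factor count among tied solutions (tie-break)"
    ),
    pass = c(c1, c2, c3, c4, c5, NA, NA),
    evidence = c(
      sprintf("|S_u| = %d", length(su)),
      sprintf("%d cohort(s) at >= 95%%, totaling %d subjects", nrow(hi), sum(hi$n)),
      sprintf("%d cohort(s) at 100%% with n >= 10",
              sum(metrics$accuracy >= 100 - 1e-9 & metrics$n >= 10)),
      sprintf("sign-consistent genes: %s",
              if (any(consistent)) paste(su[consistent], collapse = ", ") else "none"),
      sprintf("min accuracy %.2f%%", min(metrics$accuracy)),
      sprintf("%d genes", length(su)),
      sprintf("%d active factor(s)", n_factors)
    )
  )
  structure(
    list(report = report, overall = all(report$pass[1:5])),
    class = "cfmax_criteria"
  )
}

#' @export
print.cfmax_criteria <- function(x, ...) {
  cat(sprintf("<critical-criteria report>  overall: %s\n",
              if (x$overall) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$report))) {
    r <- x$report[i, ]
    cat(sprintf(
      "  [%s] (%d) %s — %s\n",
      if (is.na(r$pass)) "·" else if (r$pass) "x" else " ",
      r$criterion, r$rule, r$evidence
    ))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cfmax_criteria <- function(x, ...) x$report
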