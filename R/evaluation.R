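#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity (in percent, full precision; use
#' [fmt_pct()] for the 2-decimal display convention) together with the raw
#' confusion counts. When a class is absent its conditional metric is
#' reported as `NA` rather than 0 or 100.
#'
#' @param pred Binary predictions (0/1).
#' @param labels Binary truth (0/1), same length.
#' @param id Optional cohort/stratum identifier carried into the row.
#' @return One-row tibble: `id`, `n`, `tp`, `fn`, `tn`, `fp`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(pred, labels, id = NULL) {
  pred <- as.integer(pred); labels <- as.integer(labels)
  if (length(pred) != length(labels)) {
    abort("`pred` and `labels` must have equal length.")
  }
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  n <- length(labels)
  tibble(
    id = id %||% NA_character_,
    n = n, tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = 100 * (tp + tn) / n,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  )
}

#' Format a percent metric for display
#'
#' Two decimals, half-up rounding — the convention used in published
#' per-cohort performance tables.
#'
#' @param x Percent values.
#' @param digits Decimals (default 2).
#' @return Character vector like `"97.74%"`.
#' @export
fmt_pct <- function(x, digits = 2) {
  ifelse(is.na(x), NA_character_,
         paste0(formatC(round_half_up(x, digits), format = "f", digits = digits), "%"))
}

#' Subgroup label from per-factor scores
#'
#' A tumor sample's subgroup is the set of competing factors whose
#' individual score exceeds 0 — equivalently whose per-factor probability
#' exceeds 0.5. Samples with no positive factor get the empty label `""`
#' (predicted normal), so a sample is predicted tumor exactly when its
#' subgroup is non-empty.
#'
#' @param scores Numeric matrix (samples x factors) or vector (one sample).
#' @return Character vector of labels like `"CF1&CF3"`.
#' @export
subgroup_assignment <- function(scores) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1, dimnames = list(NULL, names(scores)))
  nm <- colnames(scores) %||% paste0("CF", seq_len(ncol(scores)))
  unname(apply(scores, 1L, function(s) paste(nm[s > 0], collapse = "&")))
}

#' Evaluate a classifier on a cohort
#'
#' Scores the cohort, computes confusion metrics, and tabulates detected
#' tumors by subgroup (the Venn breakdown of which factor combinations
#' detect each patient).
#'
#' @param classifier A [max_logistic()] classifier.
#' @param cohort A [cohort()].
#' @return A list of class `cfmax_eval`: `metrics` (one-row tibble),
#'   `subgroups` (tibble of tumor counts per detecting combination),
#'   `scores` (the per-sample score tibble).
#' @export
evaluate_cohort <- function(classifier, cohort) {
  stopifnot(is_cohort(cohort))
  sc <- score_samples(cohort, classifier)
  metrics <- confusion_metrics(sc$pred, sc$label, id = cohort$cohort_id)
  subgroups <- sc |>
    filter(.data$label == 1L, .data$subgroup != "") |>
    count(.data$subgroup, name = "n_tumors") |>
    arrange(.data$subgroup)
  structure(
    list(metrics = metrics, subgroups = subgroups, scores = sc),
    class = "cfmax_eval"
  )
}

#' @export
print.cfmax_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<cfmax_eval '%s'>  n=%d  accuracy %s  sensitivity %s  specificity %s\n",
    m$id, m$n, fmt_pct(m$accuracy), fmt_pct(m$sensitivity), fmt_pct(m$specificity)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cfmax_eval <- function(x, ...) x$metrics

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::glance
glance.cfmax_eval <- function(x, ...) {
  x$metrics |>
    select("id", "n", "accuracy", "sensitivity", "specificity")
}

#' Stratified evaluation
#'
#' Evaluates a classifier within each stratum of a cohort. With
#' `refit = FALSE` the given coefficients are applied unchanged per stratum
#' (a direct check of transferability); with `refit = TRUE` the factor
#' coefficients are refitted on the same gene partition within each stratum
#' before evaluation, so refit metrics bound direct metrics from above on
#' the training data.
#'
#' @param cohort A [cohort()] with `strata`.
#' @param classifier A [max_logistic()] classifier.
#' @param refit Refit coefficients within each stratum (default `FALSE`).
#' @param ... Passed to [fit_max_logistic()] when refitting.
#' @return A tibble with one row per stratum plus an `overall` row; strata
#'   with a single class keep their conditional metric as `NA`.
#' @export
stratified_evaluate <- function(cohort, classifier, refit = FALSE, ...) {
  stopifnot(is_cohort(cohort))
  if (is.null(cohort$strata)) abort("Cohort has no strata.")
  partition <- map(classifier$factors, function(f) names(f$coefficients))
  rows <- map(sort(unique(cohort$strata)), function(st) {
    idx <- cohort$strata == st
    sub <- cohort(cohort$expression[idx, , drop = FALSE],
                  cohort$labels[idx], cohort_id = st)
    cls <- classifier
    if (refit) {
      if (length(unique(sub$labels)) < 2) {
        warn(sprintf("Stratum '%s' has one class; applying the classifier directly.", st))
      } else {
        # warm-started at the supplied coefficients, so in-stratum training
        # metrics never fall below direct application
        cls <- fit_max_logistic(sub, partition, init = classifier, ...)[[1]]
      }
    }
    sc <- score_samples(sub, cls)
    confusion_metrics(sc$pred, sc$label, id = st)
  })
  sc_all <- score_samples(cohort, classifier)
  overall <- confusion_metrics(sc_all$pred, sc_all$label, id = "overall")
  strata_tbl <- bind_rows(rows)
  if (refit) {
    # overall of the refitted models = sum of per-stratum counts
    overall <- strata_tbl |>
      summarise(across(c("n", "tp", "fn", "tn", "fp"), sum)) |>
      mutate(
        id = "overall",
        accuracy = 100 * (.data$tp + .data$tn) / .data$n,
        sensitivity = ifelse(.data$tp + .data$fn > 0, 100 * .data$tp / (.data$tp + .data$fn), NA_real_),
        specificity = ifelse(.data$tn + .data$fp > 0, 100 * .data$tn / (.data$tn + .data$fp), NA_real_)
      ) |>
      select(dplyr::all_of(names(strata_tbl)))
  }
  bind_rows(strata_tbl, overall)
}

#' Pool per-cohort evaluation reports
#'
#' Sums confusion counts across cohorts and recomputes the percent metrics
#' on the pooled counts (the "Total" row of a multi-cohort performance
#' table). Pooling is order-invariant.
#'
#' @param reports A list of `cfmax_eval` objects or a tibble of metric rows
#'   carrying the raw counts.
#' @return One-row tibble of pooled metrics with `id = "pooled"`.
#' @export
pooled_metrics <- function(reports) {
  rows <- if (is.data.frame(reports)) reports else bind_rows(map(reports, tidy))
  need <- c("tp", "fn", "tn", "fp")
  if (!all(need %in% names(rows))) abort("Reports must carry raw confusion counts.")
  tot <- summarise(rows, across(dplyr::all_of(c("n", need)), sum))
  tibble(
    id = "pooled",
    n = tot$n, tp = tot$tp, fn = tot$fn, tn = tot$tn, fp = tot$fp,
    accuracy = 100 * (tot$tp + tot$tn) / tot$n,
    sensitivity = if (tot$tp + tot$fn > 0) 100 * tot$tp / (tot$tp + tot$fn) else NA_real_,
    specificity = if (tot$tn + tot$fp > 0) 100 * tot$tn / (tot$tn + tot$fp) else NA_real_
  )
}
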