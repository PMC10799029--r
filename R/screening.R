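#' Screening configuration for MVS-CGS
#'
#' Tuning knobs of the candidate-gene screen: percentile tails over the
#' sorted absolute relative changes of per-class means, standard deviations
#' and Sharpe ratios (class mean divided by class SD), the class-separation
#' proportion threshold attached to each track, and whether to repeat the
#' screen on squared expression and intersect ("common ground seeking").
#'
#' `pct_mean` selects from the *bottom* of the sorted mean changes by
#' default — the procedure as printed — which favours genes whose mean
#' barely moves but whose spread or signal-to-noise does; set
#' `mean_tail = "top"` for the conventional reading.
#'
#' @param pct_mean,pct_sd,pct_sharpe Tail sizes in percent (defaults 1, 15, 5).
#' @param mean_tail `"bottom"` (default, literal procedure) or `"top"`.
#' @param sep_sharpe,sep_mean,sep_sd Separation-proportion thresholds for
#'   genes kept by the Sharpe, mean and SD tracks (defaults 0.5, 0.7, 0.8).
#' @param squared_transform Re-screen on squared expression and intersect
#'   candidate sets (default `FALSE`).
#' @param rc_base Which class anchors the relative change denominator:
#'   `"control"` (default) or `"tumor"`.
#' @return A list of class `cfmax_screen_config`.
#' @export
screening_config <- function(pct_mean = 1, pct_sd = 15, pct_sharpe = 5,
                             mean_tail = c("bottom", "top"),
                             sep_sharpe = 0.5, sep_mean = 0.7, sep_sd = 0.8,
                             squared_transform = FALSE,
                             rc_base = c("control", "tumor")) {
  mean_tail <- match.arg(mean_tail)
  rc_base <- match.arg(rc_base)
  for (p in c(pct_mean, pct_sd, pct_sharpe)) {
    if (!(p > 0 && p <= 100)) abort("Percentile tails must lie in (0, 100].")
  }
  for (t in c(sep_sharpe, sep_mean, sep_sd)) {
    if (!(t >= 0 && t <= 1)) abort("Separation thresholds must lie in [0, 1].")
  }
  structure(
    list(
      pct_mean = pct_mean, pct_sd = pct_sd, pct_sharpe = pct_sharpe,
      mean_tail = mean_tail,
      sep_sharpe = sep_sharpe, sep_mean = sep_mean, sep_sd = sep_sd,
      squared_transform = squared_transform, rc_base = rc_base
    ),
    class = "cfmax_screen_config"
  )
}

#' Per-gene class statistics and relative changes
#'
#' For each gene: mean, SD and Sharpe ratio (mean/SD) within tumors and
#' within controls, and the absolute relative change of each quantity,
#' `|q_T - q_N| / |q_base|` with the control class as base by default.
#' Sharpe ratios are scale-free, which is what lets the same screen run on
#' cohorts measured on different platforms without normalization. Genes
#' with a zero-SD class have an undefined Sharpe ratio and are flagged
#' (`sharpe_defined = FALSE`); a zero base value likewise flags that
#' relative change as `NA` and drops the gene from that ranking only.
#'
#' @param cohort A [cohort()] with at least two samples in each class.
#' @param rc_base `"control"` or `"tumor"` denominator class.
#' @return A tibble, one row per gene: `gene`, `mean_t`, `mean_n`, `sd_t`,
#'   `sd_n`, `sharpe_t`, `sharpe_n`, `rc_mean`, `rc_sd`, `rc_sharpe`,
#'   `sharpe_defined`.
#' @export
class_stats <- function(cohort, rc_base = "control") {
  stopifnot(is_cohort(cohort))
  tum <- cohort$labels == 1L
  if (sum(tum) < 2 || sum(!tum) < 2) {
    abort("Both classes need at least 2 samples to compute class statistics.")
  }
  xt <- cohort$expression[tum, , drop = FALSE]
  xn <- cohort$expression[!tum, , drop = FALSE]
  mean_t <- unname(colMeans(xt)); mean_n <- unname(colMeans(xn))
  sd_t <- unname(apply(xt, 2, stats::sd)); sd_n <- unname(apply(xn, 2, stats::sd))
  sharpe_t <- ifelse(sd_t > 0, mean_t / sd_t, NA_real_)
  sharpe_n <- ifelse(sd_n > 0, mean_n / sd_n, NA_real_)
  rc <- function(qt, qn) {
    base <- if (rc_base == "control") qn else qt
    ifelse(is.na(qt) | is.na(qn) | base == 0, NA_real_, abs(qt - qn) / abs(base))
  }
  tibble(
    gene = cohort$gene_ids,
    mean_t = mean_t, mean_n = mean_n,
    sd_t = sd_t, sd_n = sd_n,
    sharpe_t = sharpe_t, sharpe_n = sharpe_n,
    rc_mean = rc(mean_t, mean_n),
    rc_sd = rc(sd_t, sd_n),
    rc_sharpe = rc(sharpe_t, sharpe_n),
    sharpe_defined = !is.na(sharpe_t) & !is.na(sharpe_n)
  )
}

# select ceil(pct/100 * n_eligible) genes from one tail of a ranking;
# ties broken by gene identifier so the result is order-invariant
tail_select <- function(stats, col, pct, tail) {
  eligible <- stats[!is.na(stats[[col]]), c("gene", col)]
  n <- nrow(eligible)
  if (n == 0) return(character(0))
  k <- ceiling(pct / 100 * n)
  ord <- if (identical(tail, "top")) {
    order(-eligible[[col]], eligible$gene)
  } else {
    order(eligible[[col]], eligible$gene)
  }
  eligible$gene[ord][seq_len(k)]
}

#' Percentile screen over relative-change rankings
#'
#' Sorts the absolute relative changes of means, SDs and Sharpe ratios and
#' keeps a configured percentile tail of each ranking (sizes are
#' `ceiling(pct/100 * eligible)`, ties broken in gene-identifier order).
#'
#' @param stats Output of [class_stats()].
#' @param config A [screening_config()].
#' @return Named list of character vectors: `mean`, `sd`, `sharpe`.
#' @export
percentile_screen <- function(stats, config = screening_config()) {
  list(
    mean = tail_select(stats, "rc_mean", config$pct_mean, config$mean_tail),
    sd = tail_select(stats, "rc_sd", config$pct_sd, "top"),
    sharpe = tail_select(stats, "rc_sharpe", config$pct_sharpe, "top")
  )
}

#' Class-separation filter
#'
#' Keeps a gene when one class's values clear the other's entirely often
#' enough: if the tumor mean exceeds the control mean, the proportion of
#' tumor samples above the *maximum* control value must reach the
#' threshold (inclusively); with the opposite direction, the proportion of
#' tumor samples below the minimum control value is used.
#'
#' @param cohort A [cohort()].
#' @param genes Character vector of candidate genes (empty in, empty out).
#' @param threshold Required separation proportion in \[0, 1\].
#' @return Character vector of surviving genes.
#' @export
separation_filter <- function(cohort, genes, threshold) {
  stopifnot(is_cohort(cohort))
  if (length(genes) == 0) return(character(0))
  expr <- cohort_genes(cohort, genes)
  tum <- cohort$labels == 1L
  keep <- map_lgl(seq_along(genes), function(j) {
    v <- expr[, j]
    tm <- mean(v[tum]); nm <- mean(v[!tum])
    if (tm > nm) {
      mean(v[tum] > max(v[!tum])) >= threshold
    } else if (tm < nm) {
      mean(v[tum] < min(v[!tum])) >= threshold
    } else {
      FALSE
    }
  })
  genes[keep]
}

#' MVS-CGS candidate-gene screen
#'
#' The full screening procedure ("merging variable selections and common
#' ground seeking"): per-gene class statistics, percentile selection on
#' each relative-change ranking, a separation filter per track at its own
#' threshold, and the union of the three survivor sets. When
#' `squared_transform` is set the procedure is repeated on squared
#' expression values and the two candidate sets are intersected.
#'
#' @param cohort A [cohort()].
#' @param config A [screening_config()].
#' @return A tibble report (one row per gene, class `cfmax_screen`) with
#'   all statistics, per-track kept flags, and a `candidate` column; the
#'   candidate gene set is also attached as attribute `"candidates"`.
#' @seealso [candidate_genes()]
#' @export
mvs_cgs <- function(cohort, config = screening_config()) {
  run_once <- function(co) {
    stats <- class_stats(co, rc_base = config$rc_base)
    kept <- percentile_screen(stats, config)
    surv <- list(
      mean = separation_filter(co, kept$mean, config$sep_mean),
      sd = separation_filter(co, kept$sd, config$sep_sd),
      sharpe = separation_filter(co, kept$sharpe, config$sep_sharpe)
    )
    list(stats = stats, kept = kept, surv = surv,
         candidates = sort(unique(unlist(surv))))
  }
  first <- run_once(cohort)
  candidates <- first$candidates
  if (isTRUE(config$squared_transform)) {
    sq <- cohort(cohort$expression^2, cohort$labels,
                 cohort_id = paste0(cohort$cohort_id, "^2"),
                 strata = cohort$strata)
    second <- run_once(sq)
    candidates <- intersect(candidates, second$candidates)
  }
  report <- first$stats |>
    mutate(
      kept_mean = .data$gene %in% first$kept$mean,
      kept_sd = .data$gene %in% first$kept$sd,
      kept_sharpe = .data$gene %in% first$kept$sharpe,
      sep_mean = .data$gene %in% first$surv$mean,
      sep_sd = .data$gene %in% first$surv$sd,
      sep_sharpe = .data$gene %in% first$surv$sharpe,
      candidate = .data$gene %in% candidates
    )
  attr(report, "candidates") <- candidates
  attr(report, "config") <- config
  class(report) <- c("cfmax_screen", class(report))
  report
}

#' Extract the candidate gene set from a screening report
#'
#' @param report A `cfmax_screen` tibble from [mvs_cgs()].
#' @return Character vector of candidate genes.
#' @export
candidate_genes <- function(report) {
  attr(report, "candidates") %||% report$gene[report$candidate]
}

#' Screening diagnostics plot
#'
#' Relative-change rankings with candidates highlighted.
#'
#' @param object A `cfmax_screen` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cfmax_screen <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("gene", "rc_mean", "rc_sd", "rc_sharpe", "candidate")],
    cols = c("rc_mean", "rc_sd", "rc_sharpe"),
    names_to = "metric", values_to = "relative_change"
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$metric, y = .data$relative_change,
                 colour = .data$candidate)
  ) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "absolute relative change (log scale)")
}
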