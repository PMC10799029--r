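#' Competing factor: one linear predictor over a gene group
#'
#' A competing factor is an intercept plus a coefficient vector over a small,
#' ordered gene group. A sample's disease log-odds is the maximum of its
#' factor scores, so factors "compete" to determine the call. An *inactive*
#' factor carries an intercept of `-Inf`: it loses every comparison and the
#' model degenerates gracefully to fewer factors (with a single active
#' factor the model is ordinary logistic regression).
#'
#' @param intercept Numeric scalar, or `-Inf` for an inactive factor.
#' @param coefficients Named numeric vector; names are gene identifiers.
#' @return An object of class `cfmax_factor`.
#' @examples
#' competing_factor(-90.3645,
#'   c(APP = 2.8598, PSMC2 = 5.5149, SLC20A1 = -0.8795))
#' @export
competing_factor <- function(intercept, coefficients = numeric(0)) {
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  coefficients <- unlist(coefficients)
  if (length(coefficients) > 0 && is.null(names(coefficients))) {
    abort("`coefficients` must be named by gene identifier.")
  }
  if (any(!is.finite(coefficients))) {
    abort("Factor coefficients must be finite.")
  }
  if (!is.finite(intercept) && !identical(intercept, -Inf)) {
    abort("`intercept` must be finite or -Inf (inactive factor).")
  }
  names(coefficients) <- toupper(names(coefficients))
  structure(
    list(intercept = intercept, coefficients = coefficients),
    class = "cfmax_factor"
  )
}

#' @rdname competing_factor
#' @export
inactive_factor <- function() competing_factor(-Inf)

#' @rdname competing_factor
#' @param x Object to test.
#' @export
is_active <- function(x) {
  stopifnot(inherits(x, "cfmax_factor"))
  is.finite(x$intercept)
}

#' @export
print.cfmax_factor <- function(x, ...) {
  if (!is_active(x)) {
    cat("<competing factor: inactive>\n")
  } else {
    terms <- paste(
      sprintf("%+.4g*%s", x$coefficients, names(x$coefficients)),
      collapse = " "
    )
    cat(sprintf("<competing factor> %.4g %s\n", x$intercept, terms))
  }
  invisible(x)
}

#' Max-logistic classifier
#'
#' Bundles an ordered list of competing factors with a probability cutoff.
#' The decision rule calls a sample a tumor when the logistic transform of
#' its maximal factor score exceeds the threshold; a probability *exactly*
#' at the threshold is called control, matching the 0-1-loss convention
#' used by the fitting objective.
#'
#' @param factors List of [competing_factor()] objects (at least one active).
#' @param threshold Probability cutoff in (0, 1); default 0.5.
#' @param cohort_id Optional cohort the coefficients were fitted on.
#' @return An object of class `cfmax_classifier`.
#' @export
max_logistic <- function(factors, threshold = 0.5, cohort_id = NULL) {
  if (inherits(factors, "cfmax_factor")) factors <- list(factors)
  stopifnot(all(vapply(factors, inherits, logical(1), "cfmax_factor")))
  if (!any(vapply(factors, is_active, logical(1)))) {
    abort("A classifier needs at least one active competing factor.")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly inside (0, 1).")
  }
  if (is.null(names(factors)) || any(names(factors) == "")) {
    names(factors) <- paste0("CF", seq_along(factors))
  }
  structure(
    list(factors = factors, threshold = threshold, cohort_id = cohort_id),
    class = "cfmax_classifier"
  )
}

#' @export
print.cfmax_classifier <- function(x, ...) {
  cat(sprintf(
    "<max-logistic classifier>  %d factor(s), threshold %.3g%s\n",
    length(x$factors), x$threshold,
    if (is.null(x$cohort_id)) "" else paste0(", cohort ", x$cohort_id)
  ))
  for (nm in names(x$factors)) {
    cat(" ", nm, ": ", sep = "")
    print(x$factors[[nm]])
  }
  invisible(x)
}

#' Gene union of a classifier or partition
#'
#' @param x A `cfmax_classifier` or a list of gene-id character vectors.
#' @return Character vector of distinct genes used by any active factor.
#' @export
gene_union <- function(x) {
  groups <- if (inherits(x, "cfmax_classifier")) {
    map(x$factors, function(f) names(f$coefficients))
  } else {
    x
  }
  unique(unlist(groups))
}

#' Score one competing factor
#'
#' Computes `intercept + x %*% coefficients` for each sample row. Columns of
#' `expr` are matched to the factor's genes by name when names are present;
#' otherwise positional order is used and lengths must agree. An inactive
#' factor scores `-Inf` everywhere.
#'
#' @param expr Numeric vector (one sample) or matrix (samples x genes).
#' @param factor A [competing_factor()].
#' @return Numeric vector of scores, one per sample.
#' @export
factor_score <- function(expr, factor) {
  stopifnot(inherits(factor, "cfmax_factor"))
  if (is.vector(expr)) expr <- matrix(expr, nrow = 1, dimnames = list(NULL, names(expr)))
  if (!is_active(factor)) return(rep(-Inf, nrow(expr)))
  beta <- factor$coefficients
  if (length(beta) == 0) return(rep(factor$intercept, nrow(expr)))
  if (!is.null(colnames(expr))) {
    missing <- setdiff(names(beta), toupper(colnames(expr)))
    if (length(missing) > 0) {
      abort(paste0("Expression is missing genes: ", paste(missing, collapse = ", ")))
    }
    expr <- expr[, match(names(beta), toupper(colnames(expr))), drop = FALSE]
  } else if (ncol(expr) != length(beta)) {
    abort(sprintf(
      "Expression has %d columns but the factor has %d coefficients.",
      ncol(expr), length(beta)
    ))
  }
  if (anyNA(expr) || any(!is.finite(expr))) {
    abort("Expression values must be finite.")
  }
  drop(expr %*% beta) + factor$intercept
}

#' Per-factor score matrix
#'
#' @param expr Samples x genes numeric matrix (or single named row).
#' @param classifier A [max_logistic()] classifier.
#' @return Numeric matrix, samples x factors.
#' @export
factor_scores <- function(expr, classifier) {
  stopifnot(inherits(classifier, "cfmax_classifier"))
  if (is.vector(expr)) expr <- matrix(expr, nrow = 1, dimnames = list(NULL, names(expr)))
  out <- vapply(
    classifier$factors, function(f) factor_score(expr, f),
    numeric(nrow(expr))
  )
  if (nrow(expr) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(classifier$factors)))
  out
}

#' Maximal log-odds (CFmax) of each sample
#'
#' The sample's log-odds of disease is the maximum over factor scores. The
#' winning factor index (first one on ties) is attached as attribute
#' `"winner"`.
#'
#' @inheritParams factor_scores
#' @return Numeric vector of log-odds with a `winner` attribute.
#' @export
max_logodds <- function(expr, classifier) {
  s <- factor_scores(expr, classifier)
  out <- apply(s, 1L, max)
  attr(out, "winner") <- apply(s, 1L, which.max)
  out
}

#' Logistic risk probability
#'
#' Numerically stable logistic transform of a log-odds value;
#' `-Inf` (the inactive-factor sentinel) maps to 0 and large magnitudes do
#' not overflow.
#'
#' @param logodds Numeric vector of log-odds (CFmax values).
#' @return Probabilities in \[0, 1\].
#' @examples
#' risk_probability(-4.05384) # 0.01706 at 5 decimals
#' @export
risk_probability <- function(logodds) {
  bad <- is.nan(logodds) | (is.na(logodds) & !is.nan(logodds))
  if (any(bad)) abort("`logodds` must be numeric (got NA/NaN).")
  stats::plogis(logodds)
}

#' Threshold a risk probability into a class call
#'
#' Returns 1 (tumor) iff `prob > threshold`; a probability exactly at the
#' threshold is called 0, the convention under which the 0-1 loss counts a
#' tumor with p = 0.5 as an error.
#'
#' @param prob Probabilities in \[0, 1\].
#' @param threshold Cutoff in (0, 1).
#' @return Integer vector of 0/1 calls.
#' @export
classify_prob <- function(prob, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single value in (0, 1).")
  }
  as.integer(prob > threshold)
}

#' Score a cohort or expression table with a classifier
#'
#' The workhorse prediction verb: returns one row per sample with every
#' factor score, the winning score `cf_max`, the risk probability `p_max`,
#' the class call, and the subgroup label (which factors individually
#' exceed score 0, i.e. per-factor probability above 0.5).
#'
#' @param data A `cfmax_cohort`, or a data frame / matrix of expression with
#'   gene columns (a `label` column, if present, is carried through).
#' @param classifier A [max_logistic()] classifier.
#' @return A tibble with columns `sample_id`, (`label`,) one column per
#'   factor, `cf_max`, `p_max`, `pred`, `subgroup`.
#' @export
score_samples <- function(data, classifier) {
  stopifnot(inherits(classifier, "cfmax_classifier"))
  label <- NULL
  if (is_cohort(data)) {
    expr <- data$expression
    label <- data$labels
    ids <- rownames(expr)
  } else {
    df <- as.data.frame(data)
    if ("label" %in% names(df)) {
      label <- df$label
      df$label <- NULL
    }
    ids <- if ("sample_id" %in% names(df)) {
      v <- as.character(df$sample_id); df$sample_id <- NULL; v
    } else {
      sprintf("S%d", seq_len(nrow(df)))
    }
    expr <- as.matrix(df)
  }
  s <- factor_scores(expr, classifier)
  cf_max <- unname(apply(s, 1L, max))
  p_max <- risk_probability(cf_max)
  out <- bind_cols(
    tibble(sample_id = ids),
    if (!is.null(label)) tibble(label = as.integer(label)),
    as_tibble(s),
    tibble(
      cf_max = cf_max,
      p_max = p_max,
      pred = classify_prob(p_max, classifier$threshold),
      subgroup = subgroup_assignment(s)
    )
  )
  class(out) <- c("cfmax_scores", class(out))
  out
}

#' @export
predict.cfmax_classifier <- function(object, newdata, ...) {
  score_samples(newdata, object)
}

#' 0-1 loss of a classifier on a cohort
#'
#' Counts misclassified samples: tumors with risk probability at or below
#' the threshold plus controls above it.
#'
#' @param classifier A [max_logistic()] classifier.
#' @param cohort A [cohort()].
#' @return Non-negative integer count.
#' @export
misclassification_count <- function(classifier, cohort) {
  stopifnot(is_cohort(cohort))
  expr <- cohort_genes(cohort, gene_union(classifier))
  p <- risk_probability(max_logodds(expr, classifier))
  pred <- classify_prob(p, classifier$threshold)
  sum(pred != cohort$labels)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a max-logistic classifier into a coefficient table
#'
#' @param x A `cfmax_classifier`.
#' @param ... Unused.
#' @return A tibble with columns `factor`, `term`, `estimate`; intercepts
#'   use term `"(Intercept)"`.
#' @exportS3Method generics::tidy
tidy.cfmax_classifier <- function(x, ...) {
  purrr::imap(x$factors, function(f, nm) {
    tibble(
      factor = nm,
      term = c("(Intercept)", names(f$coefficients)),
      estimate = c(f$intercept, unname(f$coefficients))
    )
  }) |>
    bind_rows()
}

#' Risk-probability plot for scored samples
#'
#' One point per sample (in input order) at its maximal risk probability,
#' shaped by true label when available, with a horizontal line at the
#' decision threshold — the standard per-cohort risk display.
#'
#' @param object A tibble from [score_samples()].
#' @param threshold Cutoff line to draw (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cfmax_scores <- function(object, threshold = 0.5, ...) {
  df <- mutate(object, .idx = dplyr::row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$.idx, y = .data$p_max))
  if ("label" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(
      shape = factor(.data$label, levels = c(0, 1), labels = c("control", "tumor")),
      colour = factor(.data$label, levels = c(0, 1), labels = c("control", "tumor"))
    )) +
      ggplot2::labs(shape = NULL, colour = NULL)
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "sample", y = "risk probability (Pmax)") +
    ggplot2::ylim(0, 1)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
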