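#' Construct a cohort dataset
#'
#' A cohort bundles one study's expression matrix (samples in rows, genes in
#' columns, on the cohort's native measurement scale) with its binary
#' tumor/control labels and optional per-sample strata (e.g. stage or CMS
#' subtype). Gene identifiers are uppercased on ingest so that matching
#' across cohorts is case-insensitive but otherwise exact.
#'
#' @param expression Numeric matrix or data frame, samples x genes, with
#'   gene identifiers as column names. No missing values are allowed.
#' @param labels Binary vector (0 = control, 1 = tumor), one per sample.
#' @param cohort_id Character scalar naming the cohort.
#' @param strata Optional per-sample stratum labels (character or factor).
#' @param sample_ids Optional sample identifiers; defaults to row names or
#'   `S1..Sn`.
#' @return An object of class `cfmax_cohort`.
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
#' co <- cohort(x, labels = rep(c(0, 1), 5), cohort_id = "toy")
#' co
#' @export
cohort <- function(expression, labels, cohort_id = "cohort",
                   strata = NULL, sample_ids = NULL) {
  if (is.data.frame(expression)) expression <- as.matrix(expression)
  if (!is.matrix(expression) || !is.numeric(expression)) {
    abort("`expression` must be a numeric matrix (samples x genes).")
  }
  if (is.null(colnames(expression))) {
    abort("`expression` must carry gene identifiers as column names.")
  }
  if (anyNA(expression) || any(!is.finite(expression))) {
    abort("`expression` contains missing or non-finite values.")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(expression)) {
    abort(sprintf(
      "Length of `labels` (%d) must equal the number of samples (%d).",
      length(labels), nrow(expression)
    ))
  }
  if (!all(labels %in% c(0L, 1L))) {
    abort("`labels` must be binary: 0 (control) or 1 (tumor).")
  }
  colnames(expression) <- toupper(colnames(expression))
  if (anyDuplicated(colnames(expression))) {
    dup <- unique(colnames(expression)[duplicated(colnames(expression))])
    abort(paste0("Duplicate gene identifiers: ", paste(dup, collapse = ", ")))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(expression) %||% sprintf("S%d", seq_len(nrow(expression)))
  }
  rownames(expression) <- sample_ids
  if (!is.null(strata)) {
    strata <- as.character(strata)
    if (length(strata) != nrow(expression)) {
      abort("`strata` must have one entry per sample.")
    }
  }
  structure(
    list(
      cohort_id = as.character(cohort_id),
      expression = expression,
      labels = labels,
      gene_ids = colnames(expression),
      strata = strata
    ),
    class = "cfmax_cohort"
  )
}

#' Build a cohort from a tidy data frame
#'
#' Accepts the samples-in-rows layout most tidyverse workflows use: one row
#' per sample, one column per gene, plus a label column and optional
#' identifier / stratum columns.
#'
#' @param data A data frame with gene columns and a label column.
#' @param label Name of the binary label column (default `"label"`).
#' @param sample_id Optional name of a sample-identifier column.
#' @param stratum Optional name of a stratum column.
#' @inheritParams cohort
#' @return A `cfmax_cohort`.
#' @export
as_cohort <- function(data, label = "label", sample_id = NULL,
                      stratum = NULL, cohort_id = "cohort") {
  stopifnot(is.data.frame(data))
  if (!label %in% names(data)) {
    abort(sprintf("Label column '%s' not found.", label))
  }
  meta <- c(label, sample_id, stratum)
  gene_cols <- setdiff(names(data), meta)
  expr <- as.matrix(data[gene_cols])
  cohort(
    expr,
    labels = data[[label]],
    cohort_id = cohort_id,
    strata = if (!is.null(stratum)) data[[stratum]],
    sample_ids = if (!is.null(sample_id)) as.character(data[[sample_id]])
  )
}

#' @export
print.cfmax_cohort <- function(x, ...) {
  cat(sprintf(
    "<cfmax_cohort '%s'>  %d samples (%d tumor / %d control), %d genes%s\n",
    x$cohort_id, length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
    length(x$gene_ids),
    if (is.null(x$strata)) "" else sprintf(", %d strata", length(unique(x$strata)))
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.cfmax_cohort <- function(x, ...) {
  bind_cols(
    tibble(
      sample_id = rownames(x$expression),
      label = x$labels
    ),
    if (!is.null(x$strata)) tibble(stratum = x$strata),
    as_tibble(x$expression)
  )
}

# internal: expression sub-matrix for a gene set, with a pointed error
cohort_genes <- function(cohort, genes) {
  missing <- setdiff(genes, cohort$gene_ids)
  if (length(missing) > 0) {
    abort(sprintf(
      "Genes absent from cohort '%s': %s",
      cohort$cohort_id, paste(missing, collapse = ", ")
    ))
  }
  cohort$expression[, genes, drop = FALSE]
}

is_cohort <- function(x) inherits(x, "cfmax_cohort")

as_cohort_list <- function(cohorts) {
  if (is_cohort(cohorts)) cohorts <- list(cohorts)
  stopifnot(all(vapply(cohorts, is_cohort, logical(1))))
  names(cohorts) <- vapply(cohorts, function(co) co$cohort_id, character(1))
  cohorts
}
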