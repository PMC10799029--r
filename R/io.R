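#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression table in either orientation and returns a
#' samples-x-genes matrix, optionally transformed. Per-dataset transforms
#' mirror common preprocessing of public expression matrices: `"log2p1"`
#' applies `log2(x + 1)` (so a count of 0 maps to 0) and `"ln"` the
#' natural logarithm. The transform is applied before any downstream
#' statistic. Duplicate gene identifiers, ragged rows and non-numeric
#' cells are rejected with the offending name or line.
#'
#' @param path Path to a delimited text file with a header line.
#' @param orientation `"samples"` (samples in rows, default) or `"genes"`
#'   (genes in rows; the matrix is transposed on read). In genes-in-rows
#'   layout the first column holds gene identifiers.
#' @param transform `"none"`, `"log2p1"`, or `"ln"`.
#' @param delim Field delimiter; guessed from the file extension when
#'   `NULL` (`,` for `.csv`, tab otherwise).
#' @return A numeric matrix, samples x genes.
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples", "genes"),
                                  transform = c("none", "log2p1", "ln"),
                                  delim = NULL) {
  orientation <- match.arg(orientation)
  transform <- match.arg(transform)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal")
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("Parse problem at line %d: %s", probs$row[1] + 1L, probs$expected[1]))
  }
  id_col <- names(df)[1]
  ids <- as.character(df[[id_col]])
  value_cols <- names(df)[-1]
  bad <- value_cols[!map_lgl(df[value_cols], is.numeric)]
  if (length(bad) > 0) {
    abort(sprintf("Non-numeric expression column(s): %s", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(df[value_cols])
  rownames(m) <- ids
  if (orientation == "genes") m <- t(m)
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    abort(sprintf("Duplicate gene identifiers: %s", paste(dup, collapse = ", ")))
  }
  if (anyNA(m)) abort("Expression table contains missing values.")
  switch(transform,
    none = m,
    log2p1 = log2(m + 1),
    ln = log(m)
  )
}

#' Read a sample label table
#'
#' A two-column delimited table mapping sample identifiers to binary
#' labels (1 = tumor, 0 = control).
#'
#' @param path Path to the table.
#' @param delim Delimiter (guessed from extension when `NULL`).
#' @return A tibble with columns `sample_id`, `label`.
#' @export
read_labels <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) abort("Label table needs sample-id and label columns.")
  out <- tibble(sample_id = as.character(df[[1]]), label = as.integer(df[[2]]))
  if (!all(out$label %in% c(0L, 1L))) abort("Labels must be 0/1.")
  out
}

#' Write / read a cohort's expression and labels
#'
#' Emits the same delimited formats the readers ingest: an expression TSV
#' (samples in rows) and a two-column label TSV.
#'
#' @param cohort A [cohort()].
#' @param expr_path,label_path Output paths.
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, expr_path, label_path) {
  stopifnot(is_cohort(cohort))
  expr_df <- bind_cols(
    tibble(sample_id = rownames(cohort$expression)),
    as_tibble(cohort$expression)
  )
  readr::write_tsv(expr_df, expr_path)
  readr::write_tsv(
    tibble(sample_id = rownames(cohort$expression), label = cohort$labels),
    label_path
  )
  invisible(cohort)
}

#' Serialize a classifier to structured text
#'
#' One factor per record (factor name, intercept, gene-coefficient pairs)
#' written at full double precision, so write/read round-trips are
#' bit-exact.
#'
#' @param classifier A [max_logistic()] classifier.
#' @param path Output path.
#' @return `classifier`, invisibly.
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "cfmax_classifier"))
  lines <- c(
    "# cfmax classifier v1",
    sprintf("cohort\t%s", classifier$cohort_id %||% ""),
    sprintf("threshold\t%s", num_to_chr(classifier$threshold))
  )
  for (nm in names(classifier$factors)) {
    f <- classifier$factors[[nm]]
    lines <- c(lines, sprintf("factor\t%s", nm),
               sprintf("intercept\t%s",
                       if (is_active(f)) num_to_chr(f$intercept) else "-Inf"))
    for (g in names(f$coefficients)) {
      lines <- c(lines, sprintf("coef\t%s\t%s", g, num_to_chr(f$coefficients[[g]])))
    }
  }
  writeLines(lines, path)
  invisible(classifier)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  cohort_id <- NULL
  threshold <- 0.5
  factors <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      factors[[cur$name]] <<- competing_factor(cur$intercept, cur$coefs)
    }
  }
  for (f in fields) {
    key <- f[[1]]
    if (key == "cohort") {
      cohort_id <- if (length(f) > 1 && nzchar(f[[2]])) f[[2]]
    } else if (key == "threshold") {
      threshold <- as.numeric(f[[2]])
    } else if (key == "factor") {
      flush()
      cur <- list(name = f[[2]], intercept = NA_real_, coefs = numeric(0))
    } else if (key == "intercept") {
      cur$intercept <- if (f[[2]] == "-Inf") -Inf else as.numeric(f[[2]])
    } else if (key == "coef") {
      cur$coefs[f[[2]]] <- as.numeric(f[[3]])
    } else {
      abort(sprintf("Corrupt classifier record: '%s'", key))
    }
  }
  flush()
  if (length(factors) == 0) abort("Classifier file holds no factors.")
  max_logistic(factors, threshold = threshold, cohort_id = cohort_id)
}

#' Run the screen -> search -> evaluate pipeline
#'
#' Ties the stages together on a list of cohorts: per-cohort MVS-CGS
#' screening (candidates are unioned across cohorts), Monte-Carlo subset
#' search, and per-cohort plus pooled evaluation. All intermediate
#' artifacts are written to `out_dir` as delimited text, together with a
#' manifest recording the seed and configuration, so two runs from the
#' same inputs and seed produce identical result tables.
#'
#' @param cohorts A cohort or list of cohorts.
#' @param out_dir Output directory (created if needed).
#' @param screen A [screening_config()].
#' @param search A [search_config()].
#' @param seed Integer seed for every random stage.
#' @return A list (invisibly): `candidates`, `search` (the
#'   `cfmax_search`), `evaluations`, `pooled`.
#' @export
run_pipeline <- function(cohorts, out_dir,
                         screen = screening_config(),
                         search = search_config(),
                         seed = 1L) {
  cohorts <- as_cohort_list(cohorts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  reports <- map(cohorts, mvs_cgs, config = screen)
  candidates <- sort(unique(unlist(map(reports, candidate_genes))))
  for (nm in names(reports)) {
    readr::write_tsv(as_tibble(reports[[nm]]),
                     file.path(out_dir, sprintf("screen_%s.tsv", nm)))
  }
  if (length(candidates) < search$group_size) {
    abort("Screening produced too few candidate genes to search.")
  }

  result <- monte_carlo_search(cohorts, search, candidates = candidates)
  for (nm in names(result$classifiers)) {
    write_classifier(result$classifiers[[nm]],
                     file.path(out_dir, sprintf("classifier_%s.txt", nm)))
  }
  readr::write_tsv(result$metrics, file.path(out_dir, "metrics.tsv"))
  readr::write_tsv(tidy(result$criteria), file.path(out_dir, "criteria.tsv"))

  evaluations <- map(names(cohorts), function(nm) {
    evaluate_cohort(result$classifiers[[nm]], cohorts[[nm]])
  })
  names(evaluations) <- names(cohorts)
  pooled <- pooled_metrics(evaluations)
  readr::write_tsv(pooled, file.path(out_dir, "pooled_metrics.tsv"))

  manifest <- list(
    seed = seed,
    n_cohorts = length(cohorts),
    candidates = candidates,
    search = unclass(search[c("G", "group_size", "n_draws", "sen", "spe",
                              "shrink_target")]),
    package_version = as.character(utils::packageVersion("cfmax"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(candidates = candidates, search = result,
                 evaluations = evaluations, pooled = pooled))
}
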