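#' Published four-gene CRC classifiers
#'
#' Loads the packaged coefficient table of the published four-gene
#' (APP, CXCL8, PSMC2, SLC20A1) colorectal-cancer competing-factor
#' classifiers across ten cohorts: per-factor intercepts and gene
#' coefficients as printed, the reported accuracy/sensitivity/specificity,
#' and an `assignment` tag recording whether the gene-to-coefficient
#' mapping is explicit in the source (dataset 1 and the all-four-gene
#' factors) or inferred from coefficient-sign rules and stated gene
#' combinations (the source table's flattened layout does not uniquely
#' determine the columns of the remaining rows).
#'
#' @return A tibble, one row per factor, with gene coefficient columns
#'   `APP`, `CXCL8`, `PSMC2`, `SLC20A1` (`NA` where the gene is not in the
#'   factor) and metric columns in percent. The pooled `"total"` row is
#'   included.
#' @export
published_classifiers <- function() {
  path <- system.file("extdata", "published_classifiers.tsv", package = "cfmax")
  if (path == "") abort("Packaged classifier fixture is missing.")
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    dataset = readr::col_character(),
                    source = readr::col_character(),
                    factor = readr::col_character(),
                    assignment = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Published worked-example rows
#'
#' Loads the packaged per-sample worked examples: four samples from each
#' of four cohorts with their four gene expression values, per-factor
#' scores, winning score and risk probability. Score and probability
#' columns are kept as printed (character), preserving display precision;
#' numeric parses are added as `cf_max_num` and `p_max_num`.
#'
#' @param dataset Optional dataset filter (`"1"`, `"2"`, `"3"`, `"7"`).
#' @return A tibble of worked-example rows.
#' @export
worked_examples <- function(dataset = NULL) {
  path <- system.file("extdata", "worked_examples.tsv", package = "cfmax")
  if (path == "") abort("Packaged worked-example fixture is missing.")
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           dataset = readr::col_character(),
                           sample_id = readr::col_character(),
                           label = readr::col_integer(),
                           APP = readr::col_double(),
                           CXCL8 = readr::col_double(),
                           PSMC2 = readr::col_double(),
                           SLC20A1 = readr::col_double(),
                           .default = readr::col_character()
                         )) |>
    mutate(
      cf_max_num = as.numeric(.data$cf_max),
      p_max_num = as.numeric(.data$p_max)
    )
  if (!is.null(dataset)) out <- filter(out, .data$dataset == !!as.character(dataset))
  out
}

#' Published classifier table as scoring objects
#'
#' Converts the rows of [published_classifiers()] for one dataset into a
#' [max_logistic()] classifier (coefficient-carrying factors only; `Max`
#' metric rows and stage-restricted single-gene factors are skipped unless
#' requested).
#'
#' @param dataset Dataset identifier as in the fixture (e.g. `"1"`).
#' @param include_stage Include the stage-1 single-gene factor
#'   (default `FALSE`).
#' @return A `cfmax_classifier`.
#' @export
published_classifier_for <- function(dataset, include_stage = FALSE) {
  tbl <- published_classifiers() |>
    filter(.data$dataset == !!as.character(dataset), .data$factor != "Max")
  if (!include_stage) tbl <- filter(tbl, .data$factor != "CF_Stage1")
  if (nrow(tbl) == 0) abort(sprintf("No factors for dataset '%s'.", dataset))
  genes <- c("APP", "CXCL8", "PSMC2", "SLC20A1")
  factors <- map(seq_len(nrow(tbl)), function(i) {
    co <- unlist(tbl[i, genes])
    competing_factor(tbl$intercept[i], co[!is.na(co)])
  })
  names(factors) <- tbl$factor
  max_logistic(factors)
}

# half of the last displayed digit's value (the display rounding radius)
display_half_ulp <- function(printed) {
  if (grepl("[eE]", printed)) {
    mant <- sub("[eE].*$", "", printed)
    d <- if (grepl("\\.", mant)) nchar(sub("^[^.]*\\.", "", mant)) else 0L
    expo <- as.numeric(sub("^.*[eE]", "", printed))
    0.5 * 10^(expo - d)
  } else {
    d <- if (grepl("\\.", printed)) nchar(sub("^[^.]*\\.", "", printed)) else 0L
    0.5 * 10^(-d)
  }
}

# does logistic(printed log-odds) reproduce the printed probability at its
# displayed precision?  The printed log-odds is itself display-rounded, so
# its half-ulp uncertainty is propagated through the logistic slope.
prob_matches_display <- function(cf_printed, p_printed) {
  if (is.na(p_printed) || is.na(cf_printed)) return(NA)
  cf <- as.numeric(cf_printed)
  p <- risk_probability(cf)
  slack <- display_half_ulp(p_printed) +
    p * (1 - p) * display_half_ulp(cf_printed) + 1e-12
  isTRUE(abs(p - as.numeric(p_printed)) <= slack)
}

#' Verify the published worked examples
#'
#' Runs three internal-consistency checks on every worked-example row:
#' (a) the maximum of the printed factor scores equals the printed
#' winning score exactly; (b) the logistic transform of the printed
#' winning score reproduces the printed risk probability at its displayed
#' precision; (c) for rows whose coefficient-to-gene mapping is explicit
#' (dataset 1), factor scores recomputed from the printed coefficients and
#' the row's printed expression values fall within `tol` of the printed
#' scores (the slack absorbs display rounding of the inputs). Check (c)
#' is reported `NA` where the mapping is only inferred.
#'
#' @param rows Worked-example rows (default [worked_examples()]).
#' @param classifiers Published coefficient table (default
#'   [published_classifiers()]).
#' @param tol Tolerance of check (c); default 0.05.
#' @return A tibble with one row per worked example and logical columns
#'   `check_max`, `check_prob`, `check_coef` plus the recomputation error
#'   `coef_max_abs_err`.
#' @export
verify_worked_examples <- function(rows = worked_examples(),
                                   classifiers = published_classifiers(),
                                   tol = 0.05) {
  genes <- c("APP", "CXCL8", "PSMC2", "SLC20A1")
  out <- map(seq_len(nrow(rows)), function(i) {
    row <- rows[i, ]
    cfs <- suppressWarnings(as.numeric(unlist(row[c("cf_1", "cf_2", "cf_3")])))
    cfs <- cfs[!is.na(cfs)]
    check_max <- isTRUE(max(cfs) == row$cf_max_num)
    check_prob <- isTRUE(prob_matches_display(row$cf_max, row$p_max))
    ctab <- classifiers |>
      filter(.data$dataset == row$dataset,
             .data$factor %in% c("CF1", "CF2", "CF3"),
             .data$assignment == "explicit")
    check_coef <- NA
    err <- NA_real_
    if (nrow(ctab) > 0) {
      errs <- map_dbl(seq_len(nrow(ctab)), function(j) {
        co <- unlist(ctab[j, genes])
        co <- co[!is.na(co)]
        recomputed <- ctab$intercept[j] +
          sum(co * unlist(row[names(co)]))
        printed <- as.numeric(row[[paste0("cf_", sub("CF", "", ctab$factor[j]))]])
        abs(recomputed - printed)
      })
      err <- max(errs)
      check_coef <- err <= tol
    }
    tibble(
      dataset = row$dataset, sample_id = row$sample_id,
      check_max = check_max, check_prob = check_prob,
      check_coef = check_coef, coef_max_abs_err = err
    )
  })
  bind_rows(out)
}
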