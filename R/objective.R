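#' Sparsity penalty on the gene union and factor count
#'
#' The selection objective penalizes the size of the gene union `|S_u|`
#' through `|S_u| - f(|S_u|, G)` where
#' `f(s, G) = (s + G - 1) / ((s + 1) * G - 1)`. The fraction `f` is
#' monotone decreasing in both arguments, so the penalty grows with the
#' number of distinct genes and, for fixed union size, with the number of
#' factors.
#'
#' @param su_size Size of the gene union (positive integer).
#' @param G Number of factor groups (positive integer).
#' @return The penalty value `su_size - f(su_size, G)`.
#' @examples
#' sparsity_penalty(4, 2) # 4 - 5/9
#' @export
sparsity_penalty <- function(su_size, G) {
  stopifnot(su_size >= 1, G >= 1)
  su_size - penalty_fraction(su_size, G)
}

#' @rdname sparsity_penalty
#' @export
penalty_fraction <- function(su_size, G) {
  denom <- (su_size + 1) * G - 1
  if (any(denom == 0)) abort("Penalty fraction undefined: zero denominator.")
  (su_size + G - 1) / denom
}

#' Penalty configuration
#'
#' Non-negative tuning weights for the two penalty terms of the selection
#' objective: `lambda1` inflates the base of the error term, `lambda2`
#' scales the sparsity penalty. Defaults (0, 1) weight errors by gene-union
#' size alone and apply the sparsity term at unit strength.
#'
#' @param lambda1,lambda2 Non-negative reals.
#' @return A list of class `cfmax_penalty`.
#' @export
penalty_config <- function(lambda1 = 0, lambda2 = 1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "cfmax_penalty")
}

#' Penalized multi-cohort selection objective
#'
#' The objective combines the pooled 0-1 loss across cohorts with the
#' sparsity penalty:
#' `(1 + lambda1 + |S_u|)^E + lambda2 * sparsity_penalty(|S_u|, G)`,
#' where `E` is the total misclassification count over all cohorts. The
#' literal value overflows double precision for realistic error counts
#' (e.g. base 5 with 500 errors), so by default the objective is computed
#' and returned in the log domain as
#' `log( exp(E * log(1 + lambda1 + |S_u|)) + lambda2 * penalty )`,
#' which is exactly `log` of the literal objective, is overflow-free, and —
#' `log` being strictly increasing — induces the same ranking over
#' candidate classifiers wherever the literal value is representable.
#'
#' @param classifiers A single classifier (applied to every cohort) or a
#'   list of per-cohort classifiers sharing one gene partition.
#' @param cohorts A `cfmax_cohort` or list of them, matched by position.
#' @param penalty A [penalty_config()].
#' @param log_domain Return the log-domain value (default) or the literal
#'   objective (finite only on tiny instances).
#' @return Numeric scalar.
#' @export
penalized_objective <- function(classifiers, cohorts,
                                penalty = penalty_config(),
                                log_domain = TRUE) {
  cohorts <- as_cohort_list(cohorts)
  if (inherits(classifiers, "cfmax_classifier")) {
    classifiers <- rep(list(classifiers), length(cohorts))
  }
  stopifnot(length(classifiers) == length(cohorts))
  errors <- sum(map_int(
    seq_along(cohorts),
    function(k) misclassification_count(classifiers[[k]], cohorts[[k]])
  ))
  su <- length(gene_union(classifiers[[1]]))
  G <- length(classifiers[[1]]$factors)
  pen <- penalty$lambda2 * sparsity_penalty(su, G)
  log_first <- errors * log(1 + penalty$lambda1 + su)
  if (log_domain) {
    log_add_exp(log_first, if (pen > 0) log(pen) else -Inf)
  } else {
    exp(log_first) + pen
  }
}
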