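# Small fixture builders used across the suite. All randomness is seeded by
# the caller.

# linearly separable single-factor toy: gene A high in tumors
separable_cohort <- function(n = 20, id = "sep") {
  set.seed(11)
  lab <- rep(c(0L, 1L), each = n / 2)
  a <- ifelse(lab == 1L, 8, 2) + rnorm(n, sd = 0.4)
  b <- rnorm(n, 5)
  cohort(cbind(A = a, B = b), lab, cohort_id = id)
}

# two tumor clusters at opposite corners so that no single linear factor
# separates tumors from controls, but two factors do
xor_cohort <- function(n_per = 12, id = "xor") {
  set.seed(12)
  ctrl <- cbind(A = rnorm(2 * n_per, 0, 0.3), B = rnorm(2 * n_per, 0, 0.3))
  t1 <- cbind(A = rnorm(n_per, 4, 0.3), B = rnorm(n_per, -4, 0.3))
  t2 <- cbind(A = rnorm(n_per, -4, 0.3), B = rnorm(n_per, 4, 0.3))
  cohort(rbind(ctrl, t1, t2),
         c(rep(0L, 2 * n_per), rep(1L, 2 * n_per)), cohort_id = id)
}

# tiny labeled matrix with hand-computable class statistics (4 + 4 samples)
hand_stats_cohort <- function() {
  x <- cbind(
    G1 = c(1, 2, 3, 4, 5, 6, 7, 8),   # tumors 5-8
    G2 = c(2, 2, 2, 2, 3, 3, 3, 3)    # constant within class
  )
  cohort(x, c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), cohort_id = "hand")
}

# brute-force exhaustive minimizer of the penalized objective over all
# unordered selections (with repetition) of G groups of `size` genes —
# independent of the Monte-Carlo path
exhaustive_minimum <- function(cohorts, candidates, G, size,
                               penalty = penalty_config()) {
  groups <- utils::combn(candidates, size, simplify = FALSE)
  idx <- utils::combn(length(groups) + G - 1, G, simplify = FALSE) # multisets
  # map multiset combinations back to group indices
  best <- Inf
  pick <- function(sel) {
    # sel is an increasing index vector into a stars-and-bars encoding
    sel - seq_len(G) + 1L
  }
  for (sel in idx) {
    gidx <- pick(sel)
    part <- groups[gidx]
    fits <- fit_max_logistic(cohorts, part)
    obj <- penalized_objective(fits, cohorts, penalty)
    if (obj < best) best <- obj
  }
  best
}
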