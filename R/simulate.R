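#' Simulation configuration for planted multi-cohort data
#'
#' Describes a family of `K` tumor/control cohorts sharing a small causal
#' gene set whose labels follow a planted max-logistic rule, buried among
#' exchangeable null genes, with each cohort measured on its own platform
#' scale. The defaults emulate the structure the analysis assumes: three
#' cohorts of 500 samples on log-count-like, array-intensity-like and
#' RT-PCR-like scales, four causal genes arranged in two disjoint planted
#' factors (`{c1,c2}` and `{c3,c4}`), and cohort-specific factor
#' activation probabilities so different cohorts are dominated by
#' different disease subtypes — mirroring how real cohorts differ in
#' subgroup composition.
#'
#' Each tumor activates a non-empty subset of the planted factors (factor
#' `j` independently with probability `factor_weights[[k]][j]`), matching
#' the observation that patients are often detected by several competing
#' factors at once. The genes of every active factor are shifted by
#' `effect_size` latent standard deviations, giving the strong
#' tumor/control separation the screening procedure is designed to pick
#' up. Platform maps for causal genes are affine, so the planted factors
#' remain exactly linear on each cohort's native scale and are stored
#' per-cohort in the ground truth.
#'
#' @param K Number of cohorts (default 3).
#' @param n Samples per cohort (default 500).
#' @param n_genes Total genes (default 200).
#' @param n_causal Causal genes (default 4; 0 gives a pure-null cohort
#'   with Bernoulli labels).
#' @param prevalence Tumor fraction in (0, 1) (default 0.5).
#' @param effect_size Latent class shift per causal gene in SD units
#'   (default 4.5).
#' @param noise_sd Per-gene measurement noise SD on the latent scale,
#'   added after labels are determined (default 0.3).
#' @param platforms Character vector recycled over cohorts:
#'   `"logcount"`, `"intensity"`, `"pcr"`.
#' @param factor_weights Optional list of per-cohort factor activation
#'   probabilities; the default alternates (0.85, 0.65), (0.65, 0.85),
#'   (0.8, 0.8), ... so each factor dominates somewhere.
#' @param label_mode `"deterministic"` (label = 1 iff planted log-odds
#'   > 0) or `"bernoulli"` (label drawn from the planted probability).
#' @param flip_gene,flip_cohorts Optionally negate one causal gene's
#'   direction in the given cohorts (the planted coefficient sign flips
#'   while labels are unchanged), emulating a gene whose association
#'   reverses across populations.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A list of class `cfmax_sim_config`.
#' @export
sim_config <- function(K = 3, n = 500, n_genes = 200, n_causal = 4,
                       prevalence = 0.5, effect_size = 4.5, noise_sd = 0.3,
                       platforms = c("logcount", "intensity", "pcr"),
                       factor_weights = NULL,
                       label_mode = c("deterministic", "bernoulli"),
                       flip_gene = NULL, flip_cohorts = integer(0),
                       seed = 1L) {
  label_mode <- match.arg(label_mode)
  stopifnot(K >= 1, n >= 4, n_genes >= max(1, n_causal),
            prevalence > 0, prevalence < 1, noise_sd >= 0, effect_size >= 0)
  platforms <- match.arg(platforms, c("logcount", "intensity", "pcr"),
                         several.ok = TRUE)
  platforms <- rep_len(platforms, K)
  genes <- sprintf("G%03d", seq_len(n_genes))
  causal <- if (n_causal > 0) genes[seq_len(n_causal)] else character(0)
  partition <- if (n_causal >= 4) {
    list(causal[1:2], causal[3:4])
  } else if (n_causal > 0) {
    list(causal)
  } else {
    list()
  }
  G <- length(partition)
  if (is.null(factor_weights)) {
    base <- list(c(0.85, 0.65), c(0.65, 0.85), c(0.8, 0.8))
    factor_weights <- map(seq_len(K), function(k) {
      w <- base[[(k - 1) %% 3 + 1]]
      if (G == 1) 1 else w[seq_len(G)]
    })
  }
  structure(
    list(K = K, n = n, n_genes = n_genes, genes = genes, causal = causal,
         partition = partition, prevalence = prevalence,
         effect_size = effect_size, noise_sd = noise_sd,
         platforms = platforms, factor_weights = factor_weights,
         label_mode = label_mode, flip_gene = flip_gene,
         flip_cohorts = as.integer(flip_cohorts), seed = as.integer(seed)),
    class = "cfmax_sim_config"
  )
}

# platform descriptors: affine map for causal columns, monotone quantile
# map for null columns, both increasing in the latent value
# The affine causal maps use a low baseline relative to the dynamic range
# (offset/scale ~ 1.2-1.5), the regime of disease markers whose normal-tissue
# expression is low; null genes follow platform-typical baseline
# distributions.
platform_map <- function(tag) {
  switch(tag,
    logcount = list(offset = 2, scale = 1.5,
                    null = function(z) 8 + 1.5 * z),
    intensity = list(offset = 300, scale = 200,
                     null = function(z) stats::qgamma(stats::pnorm(z), shape = 4, scale = 100)),
    pcr = list(offset = 1.5, scale = 1.2,
               null = function(z) stats::qlnorm(stats::pnorm(z), meanlog = 0.5, sdlog = 1)),
    abort(sprintf("Unknown platform tag '%s'.", tag))
  )
}

#' Generate one synthetic cohort with its planted truth
#'
#' Draws latent standard-normal expression, shifts each intended tumor's
#' causal genes along one planted factor, determines labels from the
#' planted max-logistic score (or from its Bernoulli probability), adds
#' measurement noise, and maps every gene onto the cohort's platform
#' scale. The returned truth stores the planted per-cohort factors on the
#' *native* scale, so rescoring the emitted data with the planted
#' classifier reproduces the labels exactly when `noise_sd = 0` in
#' deterministic mode.
#'
#' @param config A [sim_config()].
#' @param k Cohort index in `1..K`.
#' @return A list with elements `cohort` (a [cohort()]) and `truth`
#'   (causal genes, partition, planted native-scale factors, per-sample
#'   planted log-odds and labels).
#' @export
generate_cohort <- function(config, k = 1L) {
  stopifnot(inherits(config, "cfmax_sim_config"), k >= 1, k <= config$K)
  set.seed(config$seed + 7919L * as.integer(k))
  n <- config$n
  G <- length(config$partition)
  pm <- platform_map(config$platforms[[k]])

  # intended classes and factor assignment (RNG order is fixed so that
  # configs differing only in platform yield identical labels)
  n_tum <- round(config$prevalence * n)
  intended <- sample(rep(c(1L, 0L), c(n_tum, n - n_tum)))
  # each tumor activates a non-empty subset of planted factors
  activation <- matrix(FALSE, n, max(G, 1L))
  if (G > 0) {
    w <- config$factor_weights[[k]]
    tum_rows <- which(intended == 1L)
    act <- matrix(stats::runif(length(tum_rows) * G) < rep(w, each = length(tum_rows)),
                  length(tum_rows), G)
    empty <- rowSums(act) == 0
    if (any(empty)) {
      act[cbind(which(empty), sample(seq_len(G), sum(empty), replace = TRUE))] <- TRUE
    }
    activation[tum_rows, ] <- act
  }
  z <- matrix(stats::rnorm(n * config$n_genes), n, config$n_genes,
              dimnames = list(sprintf("%s-S%03d", toupper(config$platforms[[k]]), 1:n),
                              config$genes))
  if (G > 0) {
    for (j in seq_len(G)) {
      rows <- which(activation[, j])
      z[rows, config$partition[[j]]] <-
        z[rows, config$partition[[j]]] + config$effect_size
    }
  }

  # planted latent-scale factors and score
  if (G > 0) {
    latent_factors <- map(config$partition, function(g) {
      competing_factor(-length(g) * config$effect_size / 2,
                       stats::setNames(rep(1, length(g)), g))
    })
    latent_cls <- max_logistic(latent_factors)
    logodds <- max_logodds(z[, config$causal, drop = FALSE], latent_cls)
    labels <- switch(config$label_mode,
      deterministic = as.integer(logodds > 0),
      bernoulli = stats::rbinom(n, 1L, risk_probability(logodds))
    )
    if (config$label_mode == "deterministic" &&
        abs(mean(labels) - config$prevalence) > 0.1) {
      abort(sprintf(
        "Configured prevalence %.2f is infeasible in deterministic mode (achieved %.2f); increase `effect_size`.",
        config$prevalence, mean(labels)
      ))
    }
  } else {
    logodds <- rep(NA_real_, n)
    labels <- stats::rbinom(n, 1L, config$prevalence)
  }

  # measurement noise, direction flips, platform scale
  x <- z + if (config$noise_sd > 0) {
    matrix(stats::rnorm(n * config$n_genes, sd = config$noise_sd),
           n, config$n_genes)
  } else 0
  flip <- stats::setNames(rep(1, length(config$causal)), config$causal)
  if (!is.null(config$flip_gene) && k %in% config$flip_cohorts) {
    flip[[toupper(config$flip_gene)]] <- -1
  }
  native <- x
  for (g in config$genes) {
    if (g %in% config$causal) {
      native[, g] <- pm$offset + pm$scale * flip[[g]] * x[, g]
    } else {
      native[, g] <- pm$null(x[, g])
    }
  }

  # planted factors on the cohort's native scale:
  # latent x_g = flip_g * (native_g - offset) / scale
  native_factors <- if (G > 0) {
    map(config$partition, function(grp) {
      co <- stats::setNames(flip[grp] / pm$scale, grp)
      b0 <- -length(grp) * config$effect_size / 2 - sum(co * pm$offset)
      competing_factor(b0, co)
    })
  } else {
    list()
  }

  co <- cohort(native, labels,
               cohort_id = sprintf("sim%d-%s", k, config$platforms[[k]]))
  truth <- structure(
    list(causal_genes = config$causal, partition = config$partition,
         factors = native_factors, logodds = logodds, labels = labels,
         activation = activation, platform = config$platforms[[k]]),
    class = "cfmax_truth"
  )
  list(cohort = co, truth = truth)
}

#' Generate all cohorts of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return A list with `cohorts` (named list of [cohort()] objects) and
#'   `truth` (per-cohort planted truths; causal genes and partition are
#'   shared).
#' @export
generate_multicohort <- function(config) {
  out <- map(seq_len(config$K), function(k) generate_cohort(config, k))
  cohorts <- as_cohort_list(map(out, "cohort"))
  truths <- map(out, "truth")
  names(truths) <- names(cohorts)
  list(cohorts = cohorts, truth = truths)
}

#' Planted classifier of a generated cohort
#'
#' Convenience accessor: the planted truth's native-scale factors as a
#' ready-to-score [max_logistic()] classifier.
#'
#' @param truth A `cfmax_truth` from [generate_cohort()].
#' @return A `cfmax_classifier`.
#' @export
planted_classifier <- function(truth) {
  stopifnot(inherits(truth, "cfmax_truth"))
  if (length(truth$factors) == 0) abort("Pure-null truth has no planted factors.")
  max_logistic(truth$factors)
}
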