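test_that("factor scoring matches an independent multiply-accumulate", {
  set.seed(101)
  for (i in 1:20) {
    g <- sample(2:5, 1)
    genes <- paste0("G", seq_len(g))
    beta <- rnorm(g)
    b0 <- rnorm(1)
    x <- rnorm(g)
    names(x) <- genes
    f <- competing_factor(b0, setNames(beta, genes))
    # brute-force dot product
    acc <- b0
    for (j in seq_len(g)) acc <- acc + x[[genes[j]]] * beta[j]
    expect_equal(factor_score(x, f), acc)
  }
})

test_that("zero coefficients return the intercept; inactive factors lose every max", {
  f <- competing_factor(3.5, c(A = 0, B = 0))
  expect_equal(factor_score(c(A = 100, B = -7), f), 3.5)
  cls <- max_logistic(list(competing_factor(-2, c(A = 1)), inactive_factor()))
  s <- max_logodds(matrix(c(5, -5), 2, 1, dimnames = list(NULL, "A")), cls)
  expect_equal(as.numeric(s), c(3, -7))
  expect_equal(attr(s, "winner"), c(1L, 1L))
})

test_that("scoring rejects mismatched or non-finite input", {
  f <- competing_factor(0, c(A = 1, B = 2))
  expect_error(factor_score(matrix(1, 1, 1), f), "columns")
  expect_error(factor_score(c(A = 1, B = NA), f), "finite")
  expect_error(factor_score(c(A = 1, C = 2), f), "missing genes")
})

test_that("max of factor scores matches a loop-based maximum", {
  set.seed(102)
  genes <- paste0("G", 1:3)
  factors <- lapply(1:5, function(j) {
    competing_factor(rnorm(1), setNames(rnorm(3), genes))
  })
  cls <- max_logistic(factors)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, genes))
  got <- max_logodds(x, cls)
  for (i in 1:10) {
    scores <- sapply(factors, function(f) factor_score(x[i, ], f))
    m <- scores[1]
    for (s in scores[-1]) if (s > m) m <- s
    expect_equal(got[[i]], m)
  }
})

test_that("with a single active factor the model is plain logistic regression", {
  co <- separable_cohort()
  fit <- suppressWarnings(
    glm(lab ~ A + B,
        data = data.frame(co$expression, lab = co$labels),
        family = binomial())
  )
  b <- unname(coef(fit))
  cls <- max_logistic(competing_factor(b[1], c(A = b[2], B = b[3])))
  expect_equal(
    as.numeric(max_logodds(co$expression, cls)),
    unname(predict(fit, type = "link")),
    tolerance = 1e-10
  )
})

test_that("risk probability is the stable logistic transform", {
  expect_equal(risk_probability(0), 0.5)
  expect_equal(round(risk_probability(-4.05384), 5), 0.01706)
  expect_equal(round(risk_probability(8.352782), 6), 0.999764)
  expect_equal(risk_probability(-Inf), 0)
  expect_equal(risk_probability(1000), 1)
  expect_equal(risk_probability(-1000), 0)
  expect_error(risk_probability(NaN), "numeric")
})

test_that("classification at the threshold boundary calls control", {
  expect_identical(classify_prob(0.5), 0L)
  expect_identical(classify_prob(0.696302), 1L)
  expect_identical(classify_prob(0.01706), 0L)
  expect_error(classify_prob(0.4, threshold = 1), "threshold")
})

test_that("an all-zero-score classifier misclassifies exactly the tumors", {
  co <- separable_cohort()
  cls <- max_logistic(competing_factor(0, c(A = 0, B = 0)))
  expect_equal(misclassification_count(cls, co), sum(co$labels == 1L))
})

test_that("misclassification count equals an exhaustive per-sample check", {
  set.seed(103)
  x <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("A", "B")))
  lab <- sample(0:1, 8, replace = TRUE)
  co <- cohort(x, lab, cohort_id = "toy8")
  cls <- max_logistic(list(
    competing_factor(0.3, c(A = 1.2, B = -0.5)),
    competing_factor(-0.1, c(A = -1, B = 1))
  ))
  manual <- 0L
  for (i in 1:8) {
    p <- risk_probability(max(
      0.3 + 1.2 * x[i, "A"] - 0.5 * x[i, "B"],
      -0.1 - x[i, "A"] + x[i, "B"]
    ))
    pred <- if (p > 0.5) 1L else 0L
    manual <- manual + (pred != lab[i])
  }
  expect_equal(misclassification_count(cls, co), manual)
})

test_that("predictions are invariant to factor order", {
  co <- xor_cohort()
  f1 <- competing_factor(-2, c(A = 1, B = -1))
  f2 <- competing_factor(-2, c(A = -1, B = 1))
  cls12 <- max_logistic(list(f1, f2))
  cls21 <- max_logistic(list(f2, f1))
  expect_equal(
    as.numeric(max_logodds(co$expression, cls12)),
    as.numeric(max_logodds(co$expression, cls21))
  )
  expect_equal(misclassification_count(cls12, co),
               misclassification_count(cls21, co))
})

test_that("duplicating a group never changes scores but grows the penalty with G", {
  co <- separable_cohort()
  f <- competing_factor(-5, c(A = 1))
  cls1 <- max_logistic(list(f))
  cls2 <- max_logistic(list(f, f))
  expect_equal(as.numeric(max_logodds(co$expression, cls1)),
               as.numeric(max_logodds(co$expression, cls2)))
  su <- 1
  expect_gt(sparsity_penalty(su, 2), sparsity_penalty(su, 1))
})

test_that("score_samples returns the tidy per-sample table", {
  co <- separable_cohort()
  fits <- fit_max_logistic(co, list(c("A")))
  sc <- score_samples(co, fits[[1]])
  expect_s3_class(sc, "tbl_df")
  expect_named(sc, c("sample_id", "label", "CF1", "cf_max", "p_max", "pred", "subgroup"))
  expect_equal(sc$pred, as.integer(sc$p_max > 0.5))
  expect_equal(sc$subgroup == "", sc$cf_max <= 0)
})
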