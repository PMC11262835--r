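twoProteinInstance <- function() {
  truth <- annotationDB(list(MF = list(P1 = c("a", "b"), P2 = "c")))
  pred <- predictionSet(list(MF = list(
    P1 = c(a = 0.9, b = 0.4))), method = "toy")
  list(truth = truth, pred = pred)
}

test_that("precision and recall follow the covered/total averaging rule", {
  x <- twoProteinInstance()
  pr <- precisionRecall(x$pred, x$truth, "MF", t = 0.4)
  expect_equal(pr$pr, 1)
  expect_equal(pr$re, 0.5)
  expect_equal(pr$M, 1L)
  expect_equal(pr$N, 2L)

  perfect <- predictionSet(list(MF = list(P1 = c(a = 1, b = 1),
                                          P2 = c(c = 1))))
  for (t in c(0.01, 0.5, 1)) {
    v <- precisionRecall(perfect, x$truth, "MF", t)
    expect_equal(v$pr, 1)
    expect_equal(v$re, 1)
  }

  none <- predictionSet()
  v <- precisionRecall(none, x$truth, "MF", 0.1)
  expect_equal(v$re, 0)
  expect_equal(v$M, 0L)
  expect_true(v$prUndefined)
})

test_that("fmax matches exhaustive enumeration on the two-protein example", {
  x <- twoProteinInstance()
  fc <- fmaxCurve(x$pred, x$truth, "MF")
  expect_equal(fmaxValue(fc), 2 / 3, tolerance = 1e-12)
  expect_lte(fmaxThreshold(fc), 0.4)

  perfect <- predictionSet(list(MF = list(P1 = c(a = 1, b = 1))))
  oneTruth <- annotationDB(list(MF = list(P1 = c("a", "b"))))
  expect_equal(fmaxValue(fmaxCurve(perfect, oneTruth, "MF")), 1)

  wrong <- predictionSet(list(MF = list(P1 = c(z = 0.9))))
  expect_equal(fmaxValue(fmaxCurve(wrong, oneTruth, "MF")), 0)
})

test_that("grid mode equals exact mode when scores sit on the grid", {
  for (seed in 1:40) {
    x <- randomEvalInstance(seed, gridAligned = TRUE)
    g <- fmaxCurve(x$pred, x$truth, "MF", mode = "grid")
    e <- fmaxCurve(x$pred, x$truth, "MF", mode = "exact")
    expect_equal(fmaxValue(g), fmaxValue(e), tolerance = 1e-12)
  }
})

test_that("refining the grid never decreases fmax, which stays in [0,1]", {
  for (seed in 1:20) {
    x <- randomEvalInstance(seed)
    coarse <- fmaxCurve(x$pred, x$truth, "MF", thresholds = seq(0.1, 1, 0.1))
    fine <- fmaxCurve(x$pred, x$truth, "MF",
                      thresholds = seq(0.01, 1, 0.01))
    exact <- fmaxCurve(x$pred, x$truth, "MF", mode = "exact")
    expect_gte(fmaxValue(fine) + 1e-12, fmaxValue(coarse))
    expect_gte(fmaxValue(exact) + 1e-12, fmaxValue(fine))
    expect_gte(fmaxValue(exact), 0)
    expect_lte(fmaxValue(exact), 1)
  }
})

test_that("constant information content makes wFmax equal Fmax", {
  for (seed in 1:30) {
    x <- randomEvalInstance(seed)
    ic <- stats::setNames(rep(2.5, length(x$terms)), x$terms)
    expect_equal(fmaxValue(wfmaxCurve(x$pred, x$truth, "MF", ic)),
                 fmaxValue(fmaxCurve(x$pred, x$truth, "MF")),
                 tolerance = 1e-12)
  }
})

test_that("IC weighting follows the weighted precision/recall definitions", {
  truth <- annotationDB(list(MF = list(P1 = c("a", "b"))))
  pred <- predictionSet(list(MF = list(P1 = c(a = 1))))
  ic <- c(a = 3, b = 1)
  wc <- wfmaxCurve(pred, truth, "MF", ic)
  expect_equal(fmaxValue(wc), 6 / 7, tolerance = 1e-12)  # wpr=1, wre=3/4

  expect_equal(fmaxValue(wfmaxCurve(predictionSet(), truth, "MF", ic)), 0)
  expect_error(wfmaxCurve(pred, truth, "MF", c(a = 3)), "information")
})

test_that("recall never drops when a correct prediction is added", {
  for (seed in 1:20) {
    x <- randomEvalInstance(seed)
    sets <- predictionScores(x$pred, "MF")
    p <- names(sets)[[1L]]
    truthTerms <- annotations(x$truth, "MF")[[p]]
    missing <- setdiff(truthTerms, names(sets[[p]]))
    if (length(missing) == 0L) next
    sets2 <- sets
    sets2[[p]] <- c(sets2[[p]], stats::setNames(0.99, missing[[1L]]))
    pred2 <- predictionSet(list(MF = sets2))
    for (t in c(0.2, 0.5, 0.9)) {
      before <- precisionRecall(x$pred, x$truth, "MF", t)
      after <- precisionRecall(pred2, x$truth, "MF", t)
      expect_gte(after$re + 1e-12, before$re)
    }
  }
})

test_that("per-protein F is the harmonic mean of own precision and recall", {
  truth <- annotationDB(list(MF = list(P1 = c("a", "b"), P2 = c("a"),
                                       P3 = c("b"))))
  pred <- predictionSet(list(MF = list(P1 = c(a = 0.9), P2 = c(a = 0.9),
                                       P3 = c(z = 0.9))))
  f <- perProteinF(pred, truth, "MF", t = 0.5)
  expect_equal(f[["P1"]], 2 * 1 * 0.5 / 1.5)
  expect_equal(f[["P2"]], 1)
  expect_equal(f[["P3"]], 0)
})

test_that("paired t-test matches the closed-form oracle", {
  fa <- c(0.9, 0.8, 0.7, 0.6)
  fb <- c(0.8, 0.6, 0.7, 0.5)
  cmp <- pairedTTest(fa, fb)
  ## independent closed form on the differences
  d <- fa - fb
  tOracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  pOracle <- 2 * stats::pt(-abs(tOracle), df = length(d) - 1)
  expect_equal(cmp@tStatistic, tOracle, tolerance = 1e-12)
  expect_equal(cmp@pValue, pOracle, tolerance = 1e-12)
  expect_equal(cmp@df, 3L)
  expect_equal(unname(cmp@sem), c(stats::sd(fa), stats::sd(fb)) / 2)

  same <- pairedTTest(fa, fa)
  expect_true(same@degenerate)
  expect_true(is.na(same@pValue))

  two <- pairedTTest(c(0.5, 0.9), c(0.4, 0.6))
  expect_equal(two@df, 1L)
})

test_that("annotated-hit fractions are percentages with input validation", {
  expect_equal(annotatedHitFraction(1, 3), 33.3)
  expect_equal(annotatedHitFraction(0, 10), 0)
  expect_equal(annotatedHitFraction(10, 10), 100)
  expect_error(annotatedHitFraction(5, 0), "positive")
  expect_error(annotatedHitFraction(11, 10), "nTotal")
})
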