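test_that("confusion counting follows the <= 0.80 boundary convention", {
  co <- data.frame(unit_id = c("a", "b", "c", "d"), level = "vessel",
                   reference_ffr = c(0.80, 0.79, 0.85, 0.90),
                   index_ffr = c(0.80, 0.90, 0.75, 0.95))
  cts <- confusionCounts(co, "vessel")
  # both exactly 0.80 count as a true positive
  expect_identical(unname(counts(cts)), c(1L, 1L, 1L, 1L))
  # perfect test: no false calls
  co$index_ffr <- co$reference_ffr
  cts2 <- confusionCounts(co, "vessel")
  expect_identical(unname(counts(cts2)[c("fp", "fn")]), c(0L, 0L))
  expect_error(confusionCounts(co, "patient"), "no rows")
})

test_that("packaged fixture reproduces the published per-vessel table", {
  fx <- vesselFixture()
  cts <- confusionCounts(fx, "vessel")
  expect_identical(unname(counts(cts)), c(20L, 50L, 6L, 2L))
  m <- diagnosticMetrics(cts)
  expect_lt(abs(m$estimate[m$metric == "accuracy"] - 89.7), 0.05)
  expect_lt(abs(m$estimate[m$metric == "npv"] - 96.2), 0.05)
})

test_that("metric point estimates and intervals match reference values", {
  cts <- new("ConfusionCounts", tp = 17L, tn = 32L, fp = 3L, fn = 2L,
             level = "patient", threshold = 0.8)
  m <- diagnosticMetrics(cts)
  est <- setNames(m$estimate, m$metric)
  expect_lt(abs(est["accuracy"] - 90.7), 0.05)
  expect_lt(abs(est["sensitivity"] - 89.5), 0.05)
  expect_lt(abs(est["specificity"] - 91.4), 0.05)
  expect_lt(abs(est["ppv"] - 85.0), 0.05)
  expect_lt(abs(est["npv"] - 94.1), 0.05)
  # exact Clopper-Pearson bounds for sensitivity 17/19
  sens <- m[m$metric == "sensitivity", ]
  expect_lt(abs(sens$lower - 66.9), 0.05)
  expect_lt(abs(sens$upper - 98.7), 0.05)
  expect_identical(sens$ci_method, "clopper-pearson")
  # all-correct classifier: every metric 100 with upper bound 100
  mAll <- diagnosticMetrics(new("ConfusionCounts", tp = 5L, tn = 5L,
                                fp = 0L, fn = 0L, level = "vessel",
                                threshold = 0.8))
  expect_true(all(mAll$estimate == 100))
  expect_true(all(mAll$upper == 100))
  # zero denominator flagged undefined, not NaN
  mU <- diagnosticMetrics(new("ConfusionCounts", tp = 0L, tn = 10L,
                              fp = 0L, fn = 0L, level = "vessel",
                              threshold = 0.8))
  expect_true(is.na(mU$estimate[mU$metric == "sensitivity"]))
  expect_identical(mU$ci_method[mU$metric == "sensitivity"], "undefined")
})

test_that("complement identities hold exactly", {
  set.seed(8)
  for (i in 1:10) {
    cts <- new("ConfusionCounts", tp = sample(1:30, 1), tn = sample(1:30, 1),
               fp = sample(1:30, 1), fn = sample(1:30, 1),
               level = "vessel", threshold = 0.8)
    m <- setNames(diagnosticMetrics(cts)$estimate, c("accuracy", "sensitivity",
                                                     "specificity", "ppv", "npv"))
    fnr <- 100 * cts@fn / (cts@tp + cts@fn)
    fpr <- 100 * cts@fp / (cts@tn + cts@fp)
    expect_equal(m[["sensitivity"]] + fnr, 100)
    expect_equal(m[["specificity"]] + fpr, 100)
  }
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(50:300, 1)
    sc <- round(runif(n), 2)              # heavy ties
    lb <- runif(n) < runif(1, 0.2, 0.8)
    if (all(lb) || all(!lb)) next
    r <- rocAuc(sc, lb)
    expect_lt(abs(auc(r) - mannWhitneyAUC(sc, lb)), 1e-12)
    expect_true(all(diff(r@points$fpr) >= -1e-12))
    expect_true(all(diff(r@points$tpr) >= -1e-12))
  }
})

test_that("AUC is invariant under monotone score transforms and separation", {
  set.seed(5)
  sc <- runif(300); lb <- runif(300) < 0.4
  a0 <- auc(rocAuc(sc, lb))
  expect_equal(auc(rocAuc(qlogis(sc / 1.001 + 1e-4), lb)), a0, tolerance = 1e-12)
  expect_equal(auc(rocAuc(sc^3, lb)), a0, tolerance = 1e-12)
  # perfect separation (low score = positive)
  expect_equal(auc(rocAuc(c(rep(0.5, 20), rep(0.9, 30)),
                          c(rep(TRUE, 20), rep(FALSE, 30)))), 1.0)
  # label-independent scores stay near 0.5
  set.seed(13)
  scN <- runif(2000); lbN <- runif(2000) < 0.4
  expect_gte(auc(rocAuc(scN, lbN)), 0.47)
  expect_lte(auc(rocAuc(scN, lbN)), 0.53)
})

test_that("agreement statistics recover identity, anticorrelation and noise", {
  x <- c(0.7, 0.8, 0.9, 0.6, 0.75)
  agI <- agreementStats(x, x)
  expect_equal(agI@r, 1)
  expect_equal(agI@meanDiff, 0)
  expect_equal(agI@sdDiff, 0)
  agA <- agreementStats(c(1, 2, 3), c(3, 2, 1))
  expect_equal(agA@r, -1)
  set.seed(21)
  xr <- runif(5000, 0.4, 1)
  yr <- xr + 0.06 + rnorm(5000, 0, 0.07)
  ag <- agreementStats(xr, yr)
  expect_gte(ag@meanDiff, 0.055); expect_lte(ag@meanDiff, 0.065)
  expect_gte(ag@sdDiff, 0.065); expect_lte(ag@sdDiff, 0.075)
  expect_equal(ag@loa, ag@meanDiff + c(-1.96, 1.96) * ag@sdDiff)
  expect_lt(ag@p, 1e-10)
  expect_error(agreementStats(rep(1, 5), runif(5)), "constant")
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  # 10,000 binomial replicates at p = 0.9, n = 20
  set.seed(99)
  x <- rbinom(10000, 20, 0.9)
  lo <- qbeta(0.025, x, 20 - x + 1); lo[x == 0] <- 0
  hi <- qbeta(0.975, x + 1, 20 - x); hi[x == 20] <- 1
  cover <- mean(lo <= 0.9 & 0.9 <= hi)
  se <- sqrt(0.95 * 0.05 / 10000)
  expect_gte(cover, 0.95 - 3 * se)
})

test_that("counts round-trip through CSV without changing the metrics", {
  fx <- vesselFixture()
  f <- tempfile(fileext = ".csv")
  writeCohort(fx, f)
  fx2 <- readCohort(f)
  m1 <- diagnosticMetrics(confusionCounts(fx, "vessel"))
  m2 <- diagnosticMetrics(confusionCounts(fx2, "vessel"))
  expect_equal(m1, m2)
})

test_that("exhaustive table search finds a unique per-patient table", {
  tb <- findTables(54, 90.7, 89.5, 91.4, 85.0, 94.1)
  expect_identical(nrow(tb), 1L)
  expect_identical(unname(unlist(tb[1, ])), c(17L, 2L, 32L, 3L))
})
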