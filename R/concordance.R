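#' 2x2 confusion counts for index vs reference FFR
#'
#' Reference-positive means reference FFR <= threshold (hemodynamically
#' significant), predicted-positive means index FFR <= threshold; the
#' boundary value 0.80 is positive on both sides.
#'
#' @param cohort data.frame with columns level, reference_ffr, index_ffr
#'   (see \code{\link{generateCohort}}).
#' @param level "vessel" or "patient".
#' @param threshold positivity threshold (default 0.80).
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(cohort, level = "vessel", threshold = 0.80) {
  rows <- cohort[cohort$level == level, , drop = FALSE]
  if (nrow(rows) == 0) stop(sprintf("no rows at the %s level", level))
  refPos <- rows$reference_ffr <= threshold
  idxPos <- rows$index_ffr <= threshold
  new("ConfusionCounts",
      tp = sum(refPos & idxPos), tn = sum(!refPos & !idxPos),
      fp = sum(!refPos & idxPos), fn = sum(refPos & !idxPos),
      level = level, threshold = threshold)
}

# Exact Clopper-Pearson 95% interval for x successes of n, in percent.
clopperPearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  100 * c(lo, hi)
}

# Standard-logit (Mercaldo) 95% interval for predictive values, in
# percent; falls back to Clopper-Pearson at the boundary counts.
logitInterval <- function(x, n, conf = 0.95) {
  if (x == 0 || x == n) return(clopperPearson(x, n, conf))
  p <- x / n
  se <- sqrt(1 / x + 1 / (n - x))
  z <- qnorm(1 - (1 - conf) / 2)
  lg <- log(p / (1 - p)) + c(-z, z) * se
  100 * exp(lg) / (1 + exp(lg))
}

#' Diagnostic metrics with 95% confidence intervals
#'
#' Point estimates: accuracy (TP+TN)/total, sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN), in percent.
#' Intervals: exact Clopper-Pearson for accuracy/sensitivity/specificity,
#' standard-logit for PPV/NPV; the method used is tagged per row.
#' Metrics with a zero denominator are returned as NA and flagged
#' "undefined" rather than propagating NaN.
#'
#' @param x a \linkS4class{ConfusionCounts}.
#' @return data.frame with columns metric, estimate, lower, upper,
#'   ci_method (percent scale, full precision; round for reporting).
#' @export
diagnosticMetrics <- function(x) {
  tp <- x@tp; tn <- x@tn; fp <- x@fp; fn <- x@fn
  tot <- tp + tn + fp + fn
  one <- function(metric, num, den, method) {
    if (den == 0)
      return(data.frame(metric = metric, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        ci_method = "undefined"))
    ci <- if (method == "clopper-pearson") clopperPearson(num, den)
          else logitInterval(num, den)
    data.frame(metric = metric, estimate = 100 * num / den,
               lower = ci[1], upper = ci[2], ci_method = method)
  }
  rbind(one("accuracy", tp + tn, tot, "clopper-pearson"),
        one("sensitivity", tp, tp + fn, "clopper-pearson"),
        one("specificity", tn, tn + fp, "clopper-pearson"),
        one("ppv", tp, tp + fp, "logit"),
        one("npv", tn, tn + fn, "logit"))
}

#' ROC curve and AUC for an FFR-like score
#'
#' Ischemia is low-score (FFR <= 0.80), so the sweep predicts positive
#' when score <= t over all unique score thresholds.  The trapezoidal
#' AUC over this step curve equals the Mann-Whitney statistic
#' U / (n+ n-) with half credit for ties.
#'
#' @param scores numeric index scores (e.g. computed FFR).
#' @param labels logical (or 0/1) reference positivity.
#' @return a \linkS4class{ROCCurve}.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (all(labels) || all(!labels))
    stop("ROC requires both classes present")
  stopifnot(length(scores) == length(labels))
  th <- sort(unique(scores))
  nPos <- sum(labels); nNeg <- sum(!labels)
  tpr <- vapply(th, function(t) sum(scores <= t & labels) / nPos, 0)
  fpr <- vapply(th, function(t) sum(scores <= t & !labels) / nNeg, 0)
  pts <- data.frame(threshold = c(-Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  a <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  new("ROCCurve", points = pts, auc = a,
      orientation = "lower_score_positive")
}

#' Paired agreement: Pearson correlation and Bland-Altman
#'
#' Pearson r with the two-sided p-value from the t transform
#' (t = r sqrt((n-2)/(1-r^2)), n-2 df); Bland-Altman mean and SD of the
#' differences (index - reference) with 95% limits of agreement
#' mean +/- 1.96 SD.
#'
#' @param reference,index paired measurements (n >= 3, both with
#'   non-zero variance).
#' @return an \linkS4class{AgreementSummary}.
#' @export
agreementStats <- function(reference, index) {
  stopifnot(length(reference) == length(index))
  n <- length(reference)
  if (n < 3) stop("at least 3 pairs are required")
  if (sd(reference) == 0) stop("reference values are constant (zero variance)")
  if (sd(index) == 0) stop("index values are constant (zero variance)")
  r <- cor(reference, index)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  d <- index - reference
  md <- mean(d); sdd <- sd(d)
  new("AgreementSummary", r = r, p = p, meanDiff = md, sdDiff = sdd,
      loa = md + c(-1.96, 1.96) * sdd, n = as.integer(n))
}

#' Packaged per-vessel concordance fixture
#'
#' A synthetic 78-vessel paired cohort constructed so the 0.80-threshold
#' 2x2 table is TP 20, TN 50, FP 6, FN 2 - the published per-vessel
#' confusion counts of the validation study this pipeline emulates.  The
#' FFR values themselves are synthetic; only the counts (and the metrics
#' derived from them) are meaningful.
#'
#' @return cohort data.frame (vessel level only).
#' @export
vesselFixture <- function() {
  path <- system.file("extdata", "vessel_cohort_synthetic.csv",
                      package = "ctFFR")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Search all 2x2 tables of a given total for printed percentages
#'
#' Exhaustively enumerates every (TP, FN, TN, FP) with the given total
#' and returns those whose accuracy, sensitivity, specificity, PPV and
#' NPV round (half-up, one decimal) to the targets.
#'
#' @param total table total (e.g. 54 patients).
#' @param accuracy,sensitivity,specificity,ppv,npv targets in percent,
#'   one decimal.
#' @return data.frame of matching tables (columns tp, fn, tn, fp).
#' @export
findTables <- function(total, accuracy, sensitivity, specificity, ppv, npv) {
  total <- as.integer(total)
  rnd1 <- function(x) floor(x * 10 + 0.5) / 10
  hits <- list()
  for (tp in 0:total) for (fn in 0:(total - tp)) for (tn in 0:(total - tp - fn)) {
    fp <- total - tp - fn - tn
    fp <- as.integer(fp); tp <- as.integer(tp); fn <- as.integer(fn); tn <- as.integer(tn)
    if ((tp + fn) == 0 || (tn + fp) == 0 || (tp + fp) == 0 || (tn + fn) == 0) next
    ok <- rnd1(100 * (tp + tn) / total) == accuracy &&
      rnd1(100 * tp / (tp + fn)) == sensitivity &&
      rnd1(100 * tn / (tn + fp)) == specificity &&
      rnd1(100 * tp / (tp + fp)) == ppv &&
      rnd1(100 * tn / (tn + fn)) == npv
    if (ok) hits[[length(hits) + 1]] <- data.frame(tp = tp, fn = fn, tn = tn, fp = fp)
  }
  if (length(hits) == 0)
    data.frame(tp = integer(), fn = integer(), tn = integer(), fp = integer())
  else do.call(rbind, hits)
}
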