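#' ROC analysis with Youden-index cutoff selection
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' scores, plus -Inf and +Inf endpoints; a subject is called positive when
#' its score is strictly greater than the cutoff. The reported cutoff
#' maximizes the Youden index `J = sensitivity + specificity - 1`; ties are
#' broken toward the smallest cutoff. Calibration is in-sample.
#'
#' @param scores numeric vector of DCVV scores (ml).
#' @param labels positives as `TRUE`/`1` (or `"yes"`), negatives as
#'   `FALSE`/`0` (or `"no"`). Both classes must be present.
#' @return A `cutoff_calibration` list: `roc_points` (data.frame of cutoff,
#'   sensitivity, specificity, sorted by cutoff), `best_cutoff`,
#'   `youden_j`, `sensitivity`, `specificity`, `accuracy`.
#' @export
roc_youden <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  if (length(scores) != length(lab)) stop("scores and labels differ in length")
  if (!any(lab) || all(lab))
    stop("ROC undefined: both classes must be present in 'labels'")
  us <- sort(unique(scores))
  cands <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  npos <- sum(lab); nneg <- sum(!lab)
  sens <- vapply(cands, function(ct) sum(scores[lab] > ct) / npos, 0)
  spec <- vapply(cands, function(ct) sum(scores[!lab] <= ct) / nneg, 0)
  j <- sens + spec - 1
  best <- which.max(j) # first maximum = smallest cutoff
  acc <- (sens[best] * npos + spec[best] * nneg) / (npos + nneg)
  structure(list(
    roc_points = data.frame(cutoff = cands, sensitivity = sens,
                            specificity = spec),
    best_cutoff = cands[best], youden_j = j[best],
    sensitivity = sens[best], specificity = spec[best], accuracy = acc),
    class = "cutoff_calibration")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  l <- tolower(as.character(labels))
  if (!all(l %in% c("yes", "no", "vva", "no vva", "true", "false")))
    stop("labels must be logical, 0/1, or yes/no")
  l %in% c("yes", "vva", "true")
}

#' @export
print.cutoff_calibration <- function(x, ...) {
  cat(sprintf(
    "Youden-optimal cutoff %.3f ml (J = %.3f): sens %.3f, spec %.3f, acc %.3f\n",
    x$best_cutoff, x$youden_j, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Accuracy from sensitivity, specificity and prevalence
#'
#' `accuracy = sens * prevalence + spec * (1 - prevalence)`.
#'
#' @param sens,spec,prevalence fractions in `[0, 1]`.
#' @return Accuracy as a fraction.
#' @examples
#' confusion_metrics(0.95, 0.90, 20 / 50) # 0.92
#' @export
confusion_metrics <- function(sens, spec, prevalence) {
  vals <- c(sens, spec, prevalence)
  if (any(vals < 0 | vals > 1)) stop("inputs must be in [0, 1]")
  sens * prevalence + spec * (1 - prevalence)
}

#' @rdname confusion_metrics
#' @param tp,fp,tn,fn confusion counts.
#' @return For the count variant, a list with `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (tp + fn == 0 || tn + fp == 0) stop("both classes must be present")
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / sum(counts))
}

#' Two-sample t-test from group summaries
#'
#' Independent-samples t-test computed from the printed group means,
#' standard deviations and sizes. The default is the pooled-variance
#' Student's test with `df = n1 + n2 - 2`; `welch = TRUE` uses the
#' Welch-Satterthwaite approximation.
#'
#' @param mean1,sd1,n1 summary of group 1 (`sd1 > 0`, `n1 >= 2`).
#' @param mean2,sd2,n2 summary of group 2.
#' @param welch use Welch's unequal-variance form.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson's chi-squared statistic without continuity correction, with
#' `df = (r - 1)(c - 1)`. A warning is issued when any expected count is
#' below 5 (the asymptotic approximation is then questionable), but the
#' uncorrected statistic is still returned.
#'
#' @param table r x c matrix of non-negative counts with positive margins,
#'   at least 2 x 2.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be >= 0")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin: chi-squared undefined")
  expected <- outer(rs, cs) / sum(tab)
  if (any(expected < 5))
    warning("some expected counts are < 5; chi-squared approximation may be poor")
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors, `n >= 3`, both non-constant.
#' @return List with `r`, `p` (two-tailed), `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pooled mean of group means
#'
#' Sample-size-weighted mean, `sum(n_i * m_i) / sum(n_i)`.
#'
#' @param means group means.
#' @param ns group sizes (`>= 1`).
#' @return The pooled mean.
#' @examples
#' pooled_mean(c(36.90, 38.70), c(30, 20)) # 37.62
#' @export
pooled_mean <- function(means, ns) {
  if (length(means) != length(ns)) stop("means and ns differ in length")
  if (any(ns < 1)) stop("group sizes must be >= 1")
  sum(ns * means) / sum(ns)
}

#' Classify visual venous asymmetry from a DCVV score
#'
#' A subject is called `"VVA"` when its DCVV is strictly greater than the
#' cutoff; ties map to `"no VVA"`, consistent with the positivity rule of
#' [roc_youden()].
#'
#' @param dcvv DCVV score(s) in ml, `>= 0`.
#' @param cutoff cutoff in ml (e.g. a Youden-optimal value).
#' @return Character vector of `"VVA"` / `"no VVA"`.
#' @export
classify_vva <- function(dcvv, cutoff) {
  if (any(dcvv < 0)) stop("dcvv must be >= 0")
  ifelse(dcvv > cutoff, "VVA", "no VVA")
}
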