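#' Outcome indicator for a cohort
#'
#' Binary outcome per case under a named definition. `tumor_related_death`
#' is death attributed to the tumor at any time during follow-up (the
#' primary outcome). `all_cause_12mo` is death from any cause within the
#' first 12 months; it requires every case to have either died or been
#' followed for at least 12 months, which the cohort inclusion rule
#' guarantees.
#'
#' @param cohort An `amf_cohort`.
#' @param outcome `"tumor_related_death"` or `"all_cause_12mo"`.
#' @return Logical vector, one element per case.
#' @export
outcome_indicator <- function(cohort,
                              outcome = c("tumor_related_death",
                                          "all_cause_12mo")) {
  outcome <- match.arg(outcome)
  cs <- cohort$cases
  need <- c("died", "death_tumor_related", "followup_months")
  if (!all(need %in% names(cs)) || anyNA(cs$died)) {
    stop("cohort lacks outcome fields required for '", outcome, "'",
         call. = FALSE)
  }
  if (outcome == "tumor_related_death") {
    cs$died & cs$death_tumor_related
  } else {
    short <- !cs$died & cs$followup_months < 12
    if (any(short)) {
      stop("all_cause_12mo requires 12 months of follow-up for ",
           "survivors; violated by case(s): ",
           paste(cs$case_id[short], collapse = ", "), call. = FALSE)
    }
    cs$died & cs$followup_months <= 12
  }
}

#' Cross-classify a threshold rule against an outcome
#'
#' Builds the 2x2 confusion table of classifier positivity (poor
#' prognosis predicted) against the binary outcome.
#'
#' @param cohort An `amf_cohort`.
#' @param rule A [threshold_rule()].
#' @param outcome Outcome definition, see [outcome_indicator()].
#' @return Object of class `confusion_table`: list with integer cells
#'   `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(cohort, rule,
                      outcome = c("tumor_related_death", "all_cause_12mo")) {
  prof <- marker_profiles(cohort, rules = list())
  pos <- classify(prof, rule)
  y <- outcome_indicator(cohort, outcome)
  confusion_table(tp = sum(pos & y), fn = sum(!pos & y),
                  fp = sum(pos & !y), tn = sum(!pos & !y))
}

#' @rdname confusion
#' @param tp,fn,fp,tn Non-negative integer cells.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              outcome = c("event", "no event")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion via the
#' beta-quantile closed form: lower = qbeta(alpha/2, x, n-x+1), upper =
#' qbeta(1-alpha/2, x+1, n-x), with the degenerate ends 0 (x=0) and 1
#' (x=n). For x = n the lower bound reduces to (alpha/2)^(1/n). The
#' interval is conservative: its coverage is at least the nominal level
#' for every n and p.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(83, 83)  # lower bound 0.025^(1/83)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, n >= 1, x >= 0, x <= n,
            level > 0, level < 1)
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp) and positive
#' predictive value tp/(tp+fp), each with a two-sided Clopper-Pearson
#' interval. A metric whose denominator is zero is undefined and is
#' reported as `NA`, never as 0.
#'
#' @param table A [confusion_table()].
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `accuracy_metrics`: data frame with columns
#'   `metric`, `numerator`, `denominator`, `estimate`, `lower`, `upper`.
#' @export
accuracy_metrics <- function(table, ci_level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  defs <- list(sensitivity = c(table$tp, table$tp + table$fn),
               specificity = c(table$tn, table$tn + table$fp),
               ppv = c(table$tp, table$tp + table$fp))
  rows <- lapply(names(defs), function(nm) {
    x <- defs[[nm]][1]; n <- defs[[nm]][2]
    if (n == 0) {
      data.frame(metric = nm, numerator = x, denominator = n,
                 estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      ci <- clopper_pearson(x, n, ci_level)
      data.frame(metric = nm, numerator = x, denominator = n,
                 estimate = x / n, lower = ci[["lower"]],
                 upper = ci[["upper"]])
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "ci_level") <- ci_level
  class(out) <- c("accuracy_metrics", "data.frame")
  out
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  cat("accuracy metrics (", 100 * attr(x, "ci_level"), "% exact CI)\n",
      sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %s (%s-%s)  [%d/%d]\n", x$metric[i],
                format_percent(x$estimate[i]), format_percent(x$lower[i]),
                format_percent(x$upper[i]), x$numerator[i],
                x$denominator[i]))
  }
  invisible(x)
}

#' ROC curve and AUC by pairwise concordance
#'
#' Builds the ROC curve of a numeric prognostic score against a binary
#' outcome, with thresholds enumerated at midpoints between distinct
#' observed scores (plus sentinels), and computes the AUC as the
#' pairwise concordance probability: over all (event, non-event) pairs,
#' a concordant pair counts 1, a tie 0.5 (Mann-Whitney convention). The
#' trapezoidal integral of the curve equals this concordance exactly.
#' The attached confidence interval uses the DeLong variance of the
#' concordance statistic, truncated to \[0, 1\].
#'
#' @param scores Numeric vector, one score per case; higher score is
#'   interpreted as worse prognosis.
#' @param labels Logical vector: `TRUE` = outcome-positive (event).
#' @param ci_level Confidence level for the AUC interval.
#' @return Object of class `roc_curve`: list with `curve` (data frame
#'   `threshold`, `sensitivity`, `fpr`), `auc`, `auc_ci`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels, ci_level = 0.95) {
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires at least one event and one non-event", call. = FALSE)
  }
  auc <- auc_concordance(scores, labels)

  s <- sort(unique(scores))
  thr <- c(Inf, rev(if (length(s) > 1) (s[-1] + s[-length(s)]) / 2), -Inf)
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)

  ci <- auc_delong_ci(scores, labels, ci_level)
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    fpr = fpr),
                 auc = auc, auc_ci = ci, n_pos = n_pos, n_neg = n_neg,
                 ci_level = ci_level),
            class = "roc_curve")
}

#' @rdname roc_curve
#' @details `auc_concordance()` computes the AUC directly from average
#'   ranks (exactly the tie-corrected Mann-Whitney statistic);
#'   `auc_trapezoid()` integrates a curve data frame and is used as the
#'   cross-checking route.
#' @export
auc_concordance <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @rdname roc_curve
#' @param curve Data frame with `sensitivity` and `fpr` columns ordered
#'   along the curve.
#' @export
auc_trapezoid <- function(curve) {
  o <- order(curve$fpr, curve$sensitivity)
  x <- curve$fpr[o]; y <- curve$sensitivity[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# DeLong-type CI from placement-value variances of the concordance AUC.
auc_delong_ci <- function(scores, labels, level = 0.95) {
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v_pos <- vapply(pos, function(a) mean(psi(a, neg)), 0)
  v_neg <- vapply(neg, function(b) mean(psi(pos, b)), 0)
  auc <- mean(v_pos)
  var_auc <- (if (m > 1) stats::var(v_pos) / m else 0) +
             (if (n > 1) stats::var(v_neg) / n else 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * sqrt(var_auc)),
    upper = min(1, auc + z * sqrt(var_auc)))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC %.3f (%d%% CI %.3f-%.3f), %d events / %d non-events\n",
              x$auc, round(100 * x$ci_level), x$auc_ci[["lower"]],
              x$auc_ci[["upper"]], x$n_pos, x$n_neg))
  invisible(x)
}
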