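#' Adjusted AMF-to-MF ratio
#'
#' Proportion of atypical mitotic figures among all mitotic figures, with
#' two adjustments that blunt the leverage of a single atypical figure in
#' a near-amitotic tumor: when the AMF count is positive it is reduced by
#' one before division, and a case without a single mitotic figure is
#' assigned a ratio of zero. So `ratio = max(amf - 1, 0) / mc` for
#' `mc > 0`, and 0 for `mc == 0`. A single AMF therefore never yields a
#' positive ratio regardless of the mitotic count.
#'
#' @param amf_count Integer vector, number of atypical mitotic figures.
#' @param mc Integer vector, mitotic count (normal + atypical figures) in
#'   the same region.
#' @return Numeric vector of proportions in \[0, 1\].
#' @examples
#' amf_mf_ratio(4, 8)   # 0.375
#' amf_mf_ratio(1, 1)   # 0: the subtract-one rule
#' amf_mf_ratio(0, 0)   # 0 by convention
#' @export
amf_mf_ratio <- function(amf_count, mc) {
  stopifnot(length(amf_count) == length(mc) || length(amf_count) == 1L ||
              length(mc) == 1L)
  if (any(amf_count < 0 | mc < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(amf_count > mc, na.rm = TRUE)) {
    stop("amf_count cannot exceed mc", call. = FALSE)
  }
  ifelse(mc == 0, 0, pmax(amf_count - 1, 0) / mc)
}

#' Two-tier histologic grade
#'
#' The 2011 two-tier grading rule for canine cutaneous mast cell tumors:
#' a tumor is high grade if any of four criteria is met — mitotic count
#' >= 7 per 2.37 mm2, >= 3 multinucleated (3+ nuclei) cells per 10 HPF,
#' >= 3 bizarre nuclei per 10 HPF, or karyomegaly present. The mitotic
#' count is evaluated first; `basis` records every satisfied criterion.
#' The rule is monotone: increasing any covariate never lowers the grade.
#'
#' @param mc Mitotic count per 2.37 mm2 region.
#' @param multinucleated Multinucleated cells per 10 HPF.
#' @param bizarre Bizarre nuclei per 10 HPF.
#' @param karyomegaly Logical, karyomegaly present.
#' @return For scalar input, a list with `grade` (`"low"`/`"high"`) and
#'   `basis` (character vector, possibly empty, in evaluation order
#'   mc, multinucleation, bizarre_nuclei, karyomegaly). For vector input
#'   the grades as a character vector with a `basis` attribute (list).
#' @examples
#' two_tier_grade(7, 0, 0, FALSE)
#' two_tier_grade(6, 0, 0, TRUE)
#' @export
two_tier_grade <- function(mc, multinucleated = 0L, bizarre = 0L,
                           karyomegaly = FALSE) {
  n <- max(length(mc), length(multinucleated), length(bizarre),
           length(karyomegaly))
  mc <- rep_len(mc, n); multinucleated <- rep_len(multinucleated, n)
  bizarre <- rep_len(bizarre, n); karyomegaly <- rep_len(karyomegaly, n)
  if (any(c(mc, multinucleated, bizarre) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  crit <- cbind(mc = mc >= 7,
                multinucleation = multinucleated >= 3,
                bizarre_nuclei = bizarre >= 3,
                karyomegaly = as.logical(karyomegaly))
  grade <- ifelse(rowSums(crit) > 0, "high", "low")
  basis <- lapply(seq_len(n), function(i) colnames(crit)[which(crit[i, ])])
  if (n == 1L) return(list(grade = grade[[1L]], basis = basis[[1L]]))
  attr(grade, "basis") <- basis
  grade
}

#' Threshold classification rules
#'
#' A `threshold_rule` dichotomizes one per-case statistic into good vs.
#' poor prognosis. `default_rules()` returns the evaluated rule set:
#' AMF count >= 3, adjusted AMF:MF ratio > 7.5%, mitotic count >= 6
#' (the established cut for this tumor type), presence of any multipolar
#' AMF, and high two-tier grade. Counts use inclusive cuts (`ge`); the
#' ratio uses a strict cut (`gt`), so a ratio of exactly 7.5% is
#' negative. Cutpoints are parameters, not constants: alternative cuts
#' can be screened by constructing rules directly.
#'
#' @param statistic One of `"amf_count"`, `"amf_mf_ratio"`, `"mc"`,
#'   `"multipolar_presence"`, `"grade"`.
#' @param cutpoint Numeric cut (ignored for `grade`).
#' @param direction `"ge"` (>=) or `"gt"` (>).
#' @param label Optional display label.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(statistic = c("amf_count", "amf_mf_ratio", "mc",
                                         "multipolar_presence", "grade"),
                           cutpoint = NA_real_,
                           direction = c("ge", "gt"),
                           label = NULL) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  if (statistic != "grade" && !is.finite(cutpoint)) {
    stop("a numeric cutpoint is required for statistic '", statistic, "'",
         call. = FALSE)
  }
  structure(list(statistic = statistic, cutpoint = cutpoint,
                 direction = direction,
                 label = label %||% statistic),
            class = "threshold_rule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname threshold_rule
#' @export
default_rules <- function() {
  list(
    amf_count = threshold_rule("amf_count", 3, "ge", "AMF count >= 3"),
    amf_mf_ratio = threshold_rule("amf_mf_ratio", 0.075, "gt",
                                  "AMF:MF ratio > 7.5%"),
    mc = threshold_rule("mc", 6, "ge", "Mitotic count >= 6"),
    multipolar = threshold_rule("multipolar_presence", 1, "ge",
                                "Multipolar AMF present"),
    grade = threshold_rule("grade", NA_real_, "ge", "High two-tier grade")
  )
}

#' @export
print.threshold_rule <- function(x, ...) {
  cmp <- if (x$statistic == "grade") "== high"
         else paste(if (x$direction == "ge") ">=" else ">", x$cutpoint)
  cat("threshold_rule:", x$label, "(", x$statistic, cmp, ")\n")
  invisible(x)
}

#' Per-case marker profiles
#'
#' Derives the full marker profile for every case of a cohort: mitotic
#' count, AMF count, adjusted AMF:MF ratio, multipolar AMF count, the
#' two-tier grade with its basis, plus one logical column per default
#' classifier and the MC-and-ratio combination.
#'
#' @param cohort An `amf_cohort`.
#' @param rules Named list of [threshold_rule()]s (default
#'   [default_rules()]).
#' @return Data frame with one row per case; classifier columns are named
#'   `positive_<rule name>`, with `positive_mc_and_ratio` for the
#'   combination rule.
#' @export
marker_profiles <- function(cohort, rules = default_rules()) {
  validate_cohort(cohort)
  cs <- cohort$cases
  prof <- data.frame(
    case_id = cs$case_id,
    mc = cs$mc,
    amf_count = cs$amf_count,
    amf_mf_ratio = amf_mf_ratio(cs$amf_count, cs$mc),
    multipolar_count = cs$multipolar_count,
    stringsAsFactors = FALSE
  )
  gr <- two_tier_grade(cs$mc, cs$multinucleated_count,
                       cs$bizarre_nuclei_count, cs$karyomegaly)
  if (nrow(cs) == 1L) {
    prof$grade <- gr$grade
    prof$grade_basis <- paste(gr$basis, collapse = "+")
  } else {
    prof$grade <- as.character(gr)
    prof$grade_basis <- vapply(attr(gr, "basis"), paste, "", collapse = "+")
  }
  for (nm in names(rules)) {
    prof[[paste0("positive_", nm)]] <- classify(prof, rules[[nm]])
  }
  prof$positive_mc_and_ratio <- combined_mc_ratio(prof)
  prof
}

#' Apply a threshold rule to marker profiles
#'
#' @param profile Data frame of marker profiles ([marker_profiles()]) or
#'   any data frame holding the rule's statistic (for
#'   `multipolar_presence`, a `multipolar_count` column; for `grade`, a
#'   `grade` column).
#' @param rule A [threshold_rule()].
#' @return Logical vector; `TRUE` means poor prognosis (test positive).
#' @export
classify <- function(profile, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (rule$statistic == "grade") {
    if (!"grade" %in% names(profile)) stop("profile lacks grade",
                                           call. = FALSE)
    return(profile$grade == "high")
  }
  col <- if (rule$statistic == "multipolar_presence") "multipolar_count"
         else rule$statistic
  if (!col %in% names(profile)) {
    stop("profile lacks column '", col, "'", call. = FALSE)
  }
  x <- profile[[col]]
  if (rule$direction == "ge") x >= rule$cutpoint else x > rule$cutpoint
}

#' Combined mitotic count and ratio classifier
#'
#' Positive only when both the mitotic-count rule and the AMF:MF-ratio
#' rule are positive. The ratio term removes mitotically active tumors
#' whose figures are overwhelmingly normal, so the combination's
#' positives are always a subset of the mitotic-count positives.
#'
#' @param profile Marker profile data frame with `mc`, `amf_count`,
#'   `amf_mf_ratio` columns.
#' @param mc_rule,ratio_rule The two component rules; defaults as in
#'   [default_rules()].
#' @return Logical vector.
#' @export
combined_mc_ratio <- function(profile,
                              mc_rule = default_rules()$mc,
                              ratio_rule = default_rules()$amf_mf_ratio) {
  classify(profile, mc_rule) & classify(profile, ratio_rule)
}

#' Percent formatting with round-half-up
#'
#' Renders proportions as percentages with a fixed number of decimals,
#' rounding halves away from zero (so 92.75 prints as "92.8"), matching
#' the conventional presentation of diagnostic accuracy tables.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @param digits Decimals (default 1).
#' @return Character vector like `"76.9%"`; `NA` renders as
#'   `"undefined"`.
#' @export
format_percent <- function(p, digits = 1L) {
  out <- ifelse(is.na(p), "undefined",
                paste0(formatC(round_half_up(100 * p, digits),
                               format = "f", digits = digits), "%"))
  out
}

#' @rdname format_percent
#' @param x Numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}
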