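#' Mitotic figure morphology vocabulary
#'
#' The closed set of morphology labels used to annotate individual mitotic
#' figures (MFs). Normal labels cover the phases of an orderly M phase;
#' atypical labels cover polar asymmetries (bipolar size asymmetry, spindle
#' multipolarity), segregation abnormalities (chromosome/fragment lagging,
#' chromosome bridging), dispersed chromatin and a catch-all for other
#' complex atypias. The vocabulary is closed: free-text labels are rejected.
#'
#' @param which One of `"all"`, `"normal"`, `"atypical"`.
#' @return Character vector of labels.
#' @examples
#' mf_labels("atypical")
#' @export
mf_labels <- function(which = c("all", "normal", "atypical")) {
  which <- match.arg(which)
  normal <- c("prometaphase", "metaphase", "ring_metaphase", "anaphase",
              "telophase")
  atypical <- c("bipolar_asymmetry", "multipolar", "chromosome_lagging",
                "fragment_lagging", "chromosome_bridging", "dispersed",
                "other_atypical")
  switch(which,
         all = c(normal, atypical),
         normal = normal,
         atypical = atypical)
}

#' Classify a morphology label as atypical or multipolar
#'
#' `is_atypical_label()` is total over the closed vocabulary: every label is
#' either normal or atypical. `is_multipolar_label()` is true only for the
#' spindle-multipolarity label.
#'
#' @param label Character vector of morphology labels.
#' @return Logical vector.
#' @examples
#' is_atypical_label(c("metaphase", "multipolar"))
#' @export
is_atypical_label <- function(label) {
  bad <- setdiff(unique(label), mf_labels("all"))
  if (length(bad) > 0L) {
    stop("unknown morphology label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  label %in% mf_labels("atypical")
}

#' @rdname is_atypical_label
#' @export
is_multipolar_label <- function(label) {
  bad <- setdiff(unique(label), mf_labels("all"))
  if (length(bad) > 0L) {
    stop("unknown morphology label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  label == "multipolar"
}

#' Aggregate per-annotation rows to per-case counts
#'
#' Collapses one-row-per-mitotic-figure annotation tables to the per-case
#' counts used throughout: mitotic count (all MFs), AMF count (atypical
#' only) and multipolar AMF count. Aggregation is a multiset count and is
#' therefore order-independent.
#'
#' @param annotations Data frame with columns `case_id`, `region_id`,
#'   `label`.
#' @param case_ids Optional character vector of case ids to report (cases
#'   with no annotations get zero counts).
#' @return Data frame with columns `case_id`, `mc`, `amf_count`,
#'   `multipolar_count`.
#' @export
aggregate_annotations <- function(annotations, case_ids = NULL) {
  stopifnot(is.data.frame(annotations))
  need <- c("case_id", "label")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0L) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  atyp <- is_atypical_label(annotations$label)   # validates labels
  mult <- is_multipolar_label(annotations$label)
  ids <- as.character(if (is.null(case_ids)) unique(annotations$case_id)
                      else case_ids)
  f <- factor(as.character(annotations$case_id), levels = ids)
  if (anyNA(f)) {
    stop("annotation rows reference case ids absent from the case table: ",
         paste(unique(annotations$case_id[is.na(f)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    case_id = ids,
    mc = as.integer(tabulate(f, nbins = length(ids))),
    amf_count = as.integer(tapply_sum(atyp, f, length(ids))),
    multipolar_count = as.integer(tapply_sum(mult, f, length(ids))),
    stringsAsFactors = FALSE
  )
}

# sum of x by factor f with explicit zero for empty levels
tapply_sum <- function(x, f, nlev) {
  out <- rep(0, nlev)
  s <- rowsum(as.numeric(x), f)
  out[match(rownames(s), levels(f))] <- s[, 1L]
  out
}
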