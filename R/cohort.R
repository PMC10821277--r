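#' Region specification for mitotic-figure enumeration
#'
#' The tumor area within which mitotic figures are enumerated. The
#' conventional hotspot region is 2.37 mm2, equivalent to 10 high-power
#' fields at a standard field diameter. Thresholds bundled with this
#' package are defined for that area and are not rescaled: a different
#' area triggers a validation warning rather than a silent adjustment.
#'
#' @param area_mm2 Region area in mm2 (default 2.37).
#' @param hpf_equivalent Number of high-power fields the area corresponds
#'   to (default 10).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(area_mm2 = 2.37, hpf_equivalent = 10L) {
  stopifnot(is.numeric(area_mm2), length(area_mm2) == 1L, area_mm2 > 0)
  structure(list(area_mm2 = as.numeric(area_mm2),
                 hpf_equivalent = as.integer(hpf_equivalent)),
            class = "region_spec")
}

#' Assemble a tumor cohort
#'
#' Builds a validated cohort from a per-case table and (optionally) a
#' per-annotation table. Each case is one dog/tumor with counts enumerated
#' in a single hotspot region, two-tier grading covariates, and outcome
#' fields (follow-up in months, death flag, tumor-related-death flag).
#'
#' If `annotations` is supplied, per-case counts are derived by
#' aggregating labels; count columns present in `cases` must then agree
#' with the aggregation.
#'
#' @param cases Data frame with columns `case_id`, `mc`, `amf_count`,
#'   `multipolar_count`, `multinucleated_count`, `bizarre_nuclei_count`,
#'   `karyomegaly`, `followup_months`, `died`, `death_tumor_related`.
#'   Count columns may be omitted when `annotations` supplies them.
#' @param annotations Optional data frame with columns `case_id`,
#'   `region_id`, `label` (one row per mitotic figure).
#' @param region A [region_spec()].
#' @param provenance Free-text metadata (file origin or generator
#'   parameters).
#' @return An object of class `amf_cohort`: a list with elements `cases`
#'   (data frame), `annotations` (data frame or `NULL`), `region`,
#'   `provenance`.
#' @export
as_cohort <- function(cases, annotations = NULL, region = region_spec(),
                      provenance = "constructed in R") {
  stopifnot(is.data.frame(cases), inherits(region, "region_spec"))
  cases <- as.data.frame(cases, stringsAsFactors = FALSE)
  if (!"case_id" %in% names(cases)) stop("cases needs a case_id column",
                                         call. = FALSE)
  cases$case_id <- as.character(cases$case_id)

  if (!is.null(annotations)) {
    agg <- aggregate_annotations(annotations, case_ids = cases$case_id)
    for (col in c("mc", "amf_count", "multipolar_count")) {
      if (col %in% names(cases)) {
        bad <- which(cases[[col]] != agg[[col]])
        if (length(bad) > 0L) {
          stop("count column '", col, "' disagrees with annotation ",
               "aggregation for case(s): ",
               paste(cases$case_id[bad], collapse = ", "), call. = FALSE)
        }
      } else {
        cases[[col]] <- agg[[col]]
      }
    }
  }

  defaults <- list(multinucleated_count = 0L, bizarre_nuclei_count = 0L,
                   karyomegaly = FALSE)
  for (col in names(defaults)) {
    if (!col %in% names(cases)) cases[[col]] <- defaults[[col]]
  }
  for (col in c("mc", "amf_count", "multipolar_count",
                "multinucleated_count", "bizarre_nuclei_count")) {
    if (!col %in% names(cases)) {
      stop("cases lacks column '", col, "' and no annotations were given",
           call. = FALSE)
    }
    cases[[col]] <- as.integer(cases[[col]])
  }
  for (col in c("karyomegaly", "died", "death_tumor_related")) {
    if (col %in% names(cases)) cases[[col]] <- as.logical(cases[[col]])
  }
  if ("followup_months" %in% names(cases)) {
    cases$followup_months <- as.numeric(cases$followup_months)
  }

  obj <- structure(list(cases = cases, annotations = annotations,
                        region = region, provenance = provenance),
                   class = "amf_cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort against its structural invariants
#'
#' Checks id uniqueness, count ordering (AMF count cannot exceed the
#' mitotic count since the mitotic count includes normal and atypical
#' figures; multipolar AMFs are a subset of AMFs), non-negativity, and
#' outcome consistency (a tumor-related death implies a death). Violations
#' are reported with the offending `case_id`. A region area different from
#' 2.37 mm2 raises a warning because the bundled thresholds are defined
#' for that area only.
#'
#' @param cohort An `amf_cohort`.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "amf_cohort"))
  cs <- cohort$cases
  if (nrow(cs) == 0L) stop("cohort is empty", call. = FALSE)
  if (anyDuplicated(cs$case_id)) {
    stop("duplicate case_id(s): ",
         paste(unique(cs$case_id[duplicated(cs$case_id)]), collapse = ", "),
         call. = FALSE)
  }
  fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad) > 0L) {
      stop(what, " for case(s): ", paste(cs$case_id[bad], collapse = ", "),
           call. = FALSE)
    }
  }
  for (col in c("mc", "amf_count", "multipolar_count",
                "multinucleated_count", "bizarre_nuclei_count")) {
    fail(is.na(cs[[col]]) | cs[[col]] < 0L, paste0("negative or missing ", col))
  }
  fail(cs$amf_count > cs$mc, "amf_count exceeds mc")
  fail(cs$multipolar_count > cs$amf_count, "multipolar_count exceeds amf_count")
  if (all(c("died", "death_tumor_related") %in% names(cs))) {
    fail(!is.na(cs$death_tumor_related) & cs$death_tumor_related &
           !(!is.na(cs$died) & cs$died),
         "death_tumor_related without died")
  }
  if ("followup_months" %in% names(cs)) {
    fail(!is.na(cs$followup_months) & cs$followup_months < 0,
         "negative followup_months")
  }
  if (abs(cohort$region$area_mm2 - 2.37) > 1e-9) {
    warning("region area differs from 2.37 mm2; bundled thresholds are ",
            "defined for 2.37 mm2 and are not rescaled", call. = FALSE)
  }
  invisible(cohort)
}

#' @export
print.amf_cohort <- function(x, ...) {
  cs <- x$cases
  cat("amf_cohort:", nrow(cs), "cases,", x$region$area_mm2,
      "mm2 region per case\n")
  if (all(c("died", "death_tumor_related") %in% names(cs)) &&
      !anyNA(cs$death_tumor_related)) {
    cat("  tumor-related deaths:", sum(cs$death_tumor_related),
        "| all deaths:", sum(cs$died), "\n")
  }
  cat("  total MFs:", sum(cs$mc), "| atypical:", sum(cs$amf_count), "\n")
  cat("  provenance:", format(x$provenance)[1], "\n")
  invisible(x)
}

cohort_columns <- c("case_id", "mc", "amf_count", "multipolar_count",
                    "multinucleated_count", "bizarre_nuclei_count",
                    "karyomegaly", "followup_months", "died",
                    "death_tumor_related")

#' Read and write cohort interchange files
#'
#' The per-case interchange format is a UTF-8, comma-separated table with
#' header columns `case_id, mc, amf_count, multipolar_count,
#' multinucleated_count, bizarre_nuclei_count, karyomegaly,
#' followup_months, died, death_tumor_related`. A second, per-annotation
#' dialect stores one mitotic figure per row with columns `case_id,
#' region_id, label`; because annotation rows carry no outcome fields the
#' annotation file accompanies a per-case file rather than replacing it.
#'
#' `read_cohort(path, annotations=)` reads a per-case table, optionally
#' merges an annotation file (deriving or cross-checking the counts), and
#' validates. Writing then re-reading restores the cohort exactly (up to
#' column order).
#'
#' @param path Per-case CSV path.
#' @param annotations Optional per-annotation CSV path.
#' @param region A [region_spec()].
#' @return `read_cohort`: an `amf_cohort`. `read_annotations`: a data
#'   frame. Writers return the path invisibly.
#' @export
read_cohort <- function(path, annotations = NULL, region = region_spec()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cs <- utils::read.csv(path, stringsAsFactors = FALSE)
  ann <- if (!is.null(annotations)) read_annotations(annotations) else NULL
  as_cohort(cs, annotations = ann, region = region,
            provenance = paste("read from", path))
}

#' @rdname read_cohort
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "region_id", "label")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann$case_id <- as.character(ann$case_id)
  is_atypical_label(ann$label)  # rejects unknown labels by name
  ann
}

#' @param cohort An `amf_cohort`.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  cs <- cohort$cases
  cols <- c(intersect(cohort_columns, names(cs)),
            setdiff(names(cs), cohort_columns))
  utils::write.csv(cs[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
write_annotations <- function(cohort, path) {
  validate_cohort(cohort)
  if (is.null(cohort$annotations)) {
    stop("cohort carries no per-annotation records", call. = FALSE)
  }
  utils::write.csv(
    cohort$annotations[, c("case_id", "region_id", "label")], path,
    row.names = FALSE, quote = FALSE)
  invisible(path)
}
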