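test_that("morphology vocabulary is closed and totally classified", {
  all_labels <- mf_labels("all")
  expect_length(all_labels, 12L)
  atyp <- is_atypical_label(all_labels)
  # every label is exactly one of normal/atypical
  expect_identical(sum(atyp), length(mf_labels("atypical")))
  expect_setequal(all_labels[!atyp], mf_labels("normal"))
  expect_true(all(is_multipolar_label(all_labels) ==
                    (all_labels == "multipolar")))
  expect_error(is_atypical_label("weird_shape"), "weird_shape")
})

test_that("annotation aggregation counts multisets, order-independently", {
  ann <- data.frame(
    case_id = "a",
    region_id = "r1",
    label = c("metaphase", "metaphase", "metaphase", "multipolar",
              "chromosome_bridging"),
    stringsAsFactors = FALSE
  )
  agg <- aggregate_annotations(ann)
  expect_identical(agg$mc, 5L)
  expect_identical(agg$amf_count, 2L)
  expect_identical(agg$multipolar_count, 1L)

  set.seed(11)
  for (i in 1:5) {
    labs <- sample(mf_labels("all"), 40, replace = TRUE)
    ids <- sample(c("a", "b", "c"), 40, replace = TRUE)
    ann <- data.frame(case_id = ids, region_id = "r", label = labs)
    perm <- sample(40)
    a1 <- aggregate_annotations(ann, case_ids = c("a", "b", "c"))
    a2 <- aggregate_annotations(ann[perm, ], case_ids = c("a", "b", "c"))
    expect_identical(a1, a2)
  }

  # a case listed but never annotated has zero counts
  agg0 <- aggregate_annotations(ann, case_ids = c("a", "b", "c", "empty"))
  expect_identical(agg0$mc[agg0$case_id == "empty"], 0L)
  expect_identical(agg0$amf_count[agg0$case_id == "empty"], 0L)
})

test_that("cohort validation reports offending cases", {
  cs <- random_cases(5, seed = 2)
  bad <- cs
  bad$amf_count[3] <- bad$mc[3] + 1L
  expect_error(as_cohort(bad), "amf_count exceeds mc.*c003")
  bad <- cs
  bad$multipolar_count[2] <- bad$amf_count[2] + 1L
  expect_error(as_cohort(bad), "multipolar_count exceeds amf_count")
  bad <- cs
  bad$died[4] <- FALSE; bad$death_tumor_related[4] <- TRUE
  expect_error(as_cohort(bad), "death_tumor_related without died")
  bad <- rbind(cs, cs[1, ])
  expect_error(as_cohort(bad), "duplicate case_id")
  expect_error(as_cohort(cs[0, ]), "empty")
  expect_warning(as_cohort(cs, region = region_spec(area_mm2 = 5)),
                 "not rescaled")
})

test_that("counts derived from annotations must match declared counts", {
  ann <- data.frame(case_id = "a", region_id = "r",
                    label = c("metaphase", "multipolar"))
  cs <- data.frame(case_id = "a", mc = 2L, amf_count = 2L,
                   multipolar_count = 1L, followup_months = 20,
                   died = FALSE, death_tumor_related = FALSE)
  expect_error(as_cohort(cs, annotations = ann), "disagrees")
  cs$amf_count <- 1L
  co <- as_cohort(cs, annotations = ann)
  expect_identical(co$cases$multipolar_count, 1L)
})

test_that("write/read round-trip preserves any valid cohort", {
  for (seed in 1:5) {
    co <- random_cohort(n = 20, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(co, path)
    back <- read_cohort(path)
    expect_equal(back$cases[cohort_columns], co$cases[cohort_columns])
  }
})

test_that("annotation files round-trip the label multiset", {
  set.seed(3)
  labs <- sample(mf_labels("all"), 25, replace = TRUE)
  ann <- data.frame(case_id = sample(c("a", "b"), 25, replace = TRUE),
                    region_id = "r1", label = labs,
                    stringsAsFactors = FALSE)
  agg <- aggregate_annotations(ann, case_ids = c("a", "b"))
  cs <- cbind(agg, followup_months = c(20, 30), died = FALSE,
              death_tumor_related = FALSE)
  co <- as_cohort(cs, annotations = ann)
  cpath <- withr::local_tempfile(fileext = ".csv")
  apath <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, cpath)
  write_annotations(co, apath)
  back <- read_cohort(cpath, annotations = apath)
  expect_identical(sort(back$annotations$label), sort(labs))
  expect_equal(back$cases$mc, co$cases$mc)
})

test_that("readers reject unknown labels and missing files by name", {
  apath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,region_id,label", "a,r,metaphase", "a,r,blob"),
             apath)
  expect_error(read_annotations(apath), "blob")
  expect_error(read_cohort("does/not/exist.csv"), "no such file")
})
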