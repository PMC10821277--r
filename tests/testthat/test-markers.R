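test_that("adjusted ratio follows the subtract-one and zero-MC rules", {
  expect_identical(amf_mf_ratio(0, 5), 0)
  expect_identical(amf_mf_ratio(1, 1), 0)   # single AMF never scores
  expect_identical(amf_mf_ratio(0, 0), 0)   # no MFs: ratio 0 by convention
  expect_equal(amf_mf_ratio(4, 8), 0.375)
  expect_error(amf_mf_ratio(4, 3), "exceed")
  expect_error(amf_mf_ratio(-1, 3), "non-negative")
})

test_that("ratio is monotone in each count argument", {
  for (mc in c(1, 5, 17, 40)) {
    r <- amf_mf_ratio(0:mc, mc)
    expect_true(all(diff(r) >= 0))  # non-decreasing in amf at fixed mc
  }
  for (amf in c(1, 2, 6)) {
    mcs <- amf:50
    r <- amf_mf_ratio(rep(amf, length(mcs)), mcs)
    expect_true(all(diff(r) <= 0))  # non-increasing in mc at fixed amf
  }
})

test_that("two-tier grade applies any-of-four criteria with basis", {
  g <- two_tier_grade(7, 0, 0, FALSE)
  expect_identical(g$grade, "high")
  expect_identical(g$basis, "mc")
  g <- two_tier_grade(6, 0, 0, TRUE)
  expect_identical(g$grade, "high")
  expect_identical(g$basis, "karyomegaly")
  g <- two_tier_grade(6, 2, 2, FALSE)
  expect_identical(g$grade, "low")
  expect_identical(g$basis, character(0))
  g <- two_tier_grade(9, 3, 5, TRUE)
  expect_setequal(g$basis, c("mc", "multinucleation", "bizarre_nuclei",
                             "karyomegaly"))
})

test_that("grade is monotone: raising a covariate never lowers it", {
  set.seed(5)
  for (i in 1:50) {
    mc <- sample(0:10, 1); mn <- sample(0:4, 1); bz <- sample(0:4, 1)
    km <- runif(1) < 0.2
    base <- two_tier_grade(mc, mn, bz, km)$grade
    expect_false(base == "high" &&
                   two_tier_grade(mc + 3, mn + 3, bz + 3, TRUE)$grade ==
                     "low")
    up <- two_tier_grade(mc + sample(0:5, 1), mn + sample(0:5, 1),
                         bz + sample(0:5, 1), km || runif(1) < 0.5)$grade
    if (base == "high") expect_identical(up, "high")
  }
})

test_that("default classifiers use the documented boundary semantics", {
  rules <- default_rules()
  prof <- data.frame(mc = c(5, 6), amf_count = c(2, 3),
                     amf_mf_ratio = c(0.075, 0.076),
                     multipolar_count = c(0, 1),
                     grade = c("low", "high"))
  expect_identical(classify(prof, rules$amf_count), c(FALSE, TRUE))
  # ratio boundary excluded: exactly 7.5% is negative
  expect_identical(classify(prof, rules$amf_mf_ratio), c(FALSE, TRUE))
  expect_identical(classify(prof, rules$mc), c(FALSE, TRUE))
  expect_identical(classify(prof, rules$multipolar), c(FALSE, TRUE))
  expect_identical(classify(prof, rules$grade), c(FALSE, TRUE))
})

test_that("ratio positivity implies at least two AMFs", {
  rule <- default_rules()$amf_mf_ratio
  for (mc in 0:50) for (amf in 0:mc) {
    if (classify(data.frame(amf_mf_ratio = amf_mf_ratio(amf, mc)), rule)) {
      expect_gte(amf, 2)
    }
  }
})

test_that("combined MC+ratio rule only removes MC positives", {
  prof <- data.frame(mc = c(30, 8, 4), amf_count = c(3, 4, 2))
  prof$amf_mf_ratio <- amf_mf_ratio(prof$amf_count, prof$mc)
  comb <- combined_mc_ratio(prof)
  # high MC but dilute atypia is eliminated; both-positive stays; low MC stays out
  expect_identical(comb, c(FALSE, TRUE, FALSE))
  for (seed in 1:5) {
    co <- random_cohort(40, seed)
    prof <- marker_profiles(co)
    expect_true(all(prof$positive_mc_and_ratio <= prof$positive_mc))
  }
})

test_that("marker profiles expose statistics, grade and classifier columns", {
  co <- random_cohort(25, seed = 9)
  prof <- marker_profiles(co)
  expect_identical(nrow(prof), 25L)
  expect_true(all(prof$amf_mf_ratio >= 0 & prof$amf_mf_ratio <= 1))
  expect_true(all(prof$amf_mf_ratio[prof$mc == 0] == 0))
  expect_identical(prof$amf_mf_ratio,
                   amf_mf_ratio(prof$amf_count, prof$mc))
  expect_true(all(c("positive_amf_count", "positive_amf_mf_ratio",
                    "positive_mc", "positive_multipolar",
                    "positive_grade", "positive_mc_and_ratio")
                  %in% names(prof)))
})

test_that("percent rendering rounds half up to one decimal", {
  expect_identical(format_percent(10 / 13), "76.9%")
  expect_identical(format_percent(0.92775), "92.8%")
  expect_identical(format_percent(NA_real_), "undefined")
  expect_identical(round_half_up(0.125, 2), 0.13)
})
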