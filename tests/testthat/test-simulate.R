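test_that("generation is deterministic in the seed and leaves the RNG alone", {
  p <- generator_params(n_cases = 60, seed = 99)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$cases, b$cases)
  c <- generate_cohort(generator_params(n_cases = 60, seed = 100))
  expect_false(identical(a$cases, c$cases))

  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generate_cohort(p)); after <- rnorm(3)
  expect_identical(before, after)  # private RNG stream
})

test_that("a cohort without an aggressive class has almost no tumor deaths", {
  p <- generator_params(n_cases = 200, p_aggressive = 0, seed = 31)
  co <- generate_cohort(p)
  # benign tumor hazard is tiny but nonzero; expect at most a stray death
  expect_lte(sum(co$cases$death_tumor_related), 2)
  expect_true(all(co$cases$mc >= co$cases$amf_count))
})

test_that("generated cohorts honor the minimum-follow-up inclusion rule", {
  co <- generate_cohort(generator_params(seed = 32))
  cs <- co$cases
  expect_true(all(cs$died | cs$followup_months >= 12))
  expect_true(all(cs$followup_months > 0))
  expect_true(all(cs$death_tumor_related <= cs$died))
})

test_that("tumor-death counts track the closed-form probability", {
  p <- generator_params(seed = 0)
  expected <- expected_tumor_death_prob(p)$marginal * p$n_cases
  deaths <- vapply(1:60, function(s) {
    sum(generate_cohort(generator_params(seed = s))$cases$death_tumor_related)
  }, 0)
  se <- sd(deaths) / sqrt(length(deaths))
  expect_lt(abs(mean(deaths) - expected), 3 * se + 1e-9)
  # and each draw sits in a broad binomial band around ~13/96
  expect_true(all(deaths >= 2 & deaths <= 30))
})

test_that("marker distributions converge to the specified laws", {
  # isolate each class and compare moments at large n
  for (cls in c(0, 1)) {
    p <- generator_params(n_cases = 10000, p_aggressive = cls,
                          seed = 41 + cls)
    co <- generate_cohort(p)
    k <- cls + 1L
    mu <- unname(p$mc_mean[k]); size <- unname(p$mc_dispersion[k])
    mc <- co$cases$mc
    expect_equal(mean(mc), mu, tolerance = 0.05)
    expect_equal(var(mc), mu + mu^2 / size, tolerance = 0.1)
    # conditional atypia: E[amf] = E[mc] * a/(a+b)
    pr <- unname(p$atypia_shape1[k] /
                   (p$atypia_shape1[k] + p$atypia_shape2[k]))
    expect_equal(mean(co$cases$amf_count), mu * pr, tolerance = 0.08)
  }
})

test_that("closed-form operating point is exact on degenerate laws", {
  # all mass at mc = 0: every count rule is negative, specificity 1
  p0 <- generator_params(mc_mean = c(benign = 0, aggressive = 0), seed = 5)
  op <- closed_form_operating_point(p0, default_rules()$mc)
  expect_equal(op$specificity, 1)
  expect_equal(op$sensitivity, 0)
  op <- closed_form_operating_point(p0, default_rules()$amf_count)
  expect_equal(op$specificity, 1)

  # two-point hand check: benign mass concentrated near mc=2, rule mc>=1;
  # with a huge dispersion parameter the NB is nearly Poisson(2)
  p1 <- generator_params(mc_mean = c(benign = 2, aggressive = 2),
                         mc_dispersion = c(benign = 1e8, aggressive = 1e8),
                         seed = 5)
  op <- closed_form_operating_point(p1, threshold_rule("mc", 1, "ge"))
  expect_equal(op$positive_prob_by_class[["benign"]],
               1 - dpois(0, 2), tolerance = 1e-6)
})

test_that("empirical operating points approach the closed form", {
  p <- generator_params(seed = 0)
  rules <- default_rules()[c("mc", "amf_count")]
  tallies <- list(mc = c(0, 0, 0, 0), amf_count = c(0, 0, 0, 0))
  for (s in 1:40) {
    co <- generate_cohort(generator_params(seed = 1000 + s))
    y <- outcome_indicator(co, "tumor_related_death")
    prof <- marker_profiles(co, rules = list())
    for (nm in names(rules)) {
      pos <- classify(prof, rules[[nm]])
      tallies[[nm]] <- tallies[[nm]] +
        c(sum(pos & y), sum(y), sum(!pos & !y), sum(!y))
    }
  }
  for (nm in names(rules)) {
    op <- closed_form_operating_point(p, rules[[nm]])
    t <- tallies[[nm]]
    sens <- t[1] / t[2]; spec <- t[3] / t[4]
    se_sens <- sqrt(op$sensitivity * (1 - op$sensitivity) / t[2])
    se_spec <- sqrt(op$specificity * (1 - op$specificity) / t[4])
    expect_lt(abs(sens - op$sensitivity), 3 * se_sens)
    expect_lt(abs(spec - op$specificity), 3 * se_spec)
  }
})

test_that("impossible inclusion parameters fail with a clear error", {
  # no deaths possible and the censoring horizon sits below the minimum
  # follow-up: every draw is excluded
  p <- generator_params(tumor_hazard = c(benign = 0, aggressive = 0),
                        other_cause_hazard = 0,
                        followup_admin_months = 6,
                        min_followup_months = 12, seed = 8)
  expect_error(generate_cohort(p), "inclusion rule")
})
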