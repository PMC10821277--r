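test_that("survival records encode outcome definitions and censoring", {
  cs <- data.frame(
    case_id = c("tumor8", "other20", "lost14"),
    mc = 0L, amf_count = 0L, multipolar_count = 0L,
    followup_months = c(8, 20, 14),
    died = c(TRUE, TRUE, FALSE),
    death_tumor_related = c(TRUE, FALSE, FALSE)
  )
  co <- as_cohort(cs)
  ts <- build_survival(co, "tumor_specific")
  ov <- build_survival(co, "overall")
  expect_equal(ts$time, c(8, 20, 14))
  expect_identical(ts$event, c(TRUE, FALSE, FALSE))  # other-cause censored
  expect_identical(ov$event, c(TRUE, TRUE, FALSE))

  cs$death_tumor_related <- c(TRUE, NA, NA)  # dead but unclassified cause
  expect_error(build_survival(as_cohort(cs), "tumor_specific"),
               "death-cause")
  cs$death_tumor_related <- c(TRUE, FALSE, FALSE)
  cs$followup_months[3] <- 0
  expect_error(build_survival(as_cohort(cs)), "positive")
})

test_that("product-limit estimator matches hand values on toy sets", {
  km <- kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$table$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)  # first time S drops to <= 0.5

  km <- kaplan_meier(c(4, 9, 30), c(FALSE, FALSE, FALSE))
  expect_true(all(km$table$survival == 1))
  expect_false(km$median_reached)
  expect_true(is.na(km$median))

  # mixed set {(1,event),(2,censored),(3,event)}: S = 2/3 after t=1,
  # then the last subject at risk dies at t=3 (oracle-confirmed value)
  km <- kaplan_meier(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km_survival_at(km, c(1, 2, 2.9, 3)), c(2 / 3, 2 / 3, 2 / 3, 0))
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(21)
  for (i in 1:10) {
    tm <- sample(1:12, 40, replace = TRUE)  # heavy ties
    km <- kaplan_meier(tm, rep(TRUE, 40))
    emp <- vapply(km$table$time, function(t) mean(tm > t), 0)
    expect_equal(km$table$survival, emp, tolerance = 1e-12)
  }
})

test_that("KM is invariant to record permutation and non-increasing", {
  set.seed(22)
  tm <- round(rexp(50, 0.1), 2) + 0.01
  ev <- runif(50) < 0.6
  a <- kaplan_meier(tm, ev)
  p <- sample(50)
  b <- kaplan_meier(tm[p], ev[p])
  expect_equal(a$table, b$table)
  expect_true(all(diff(a$table$survival) <= 1e-12))
  expect_lte(a$table$survival[1], 1)
})

test_that("Cox fit agrees with the survival-package oracle, with ties", {
  skip_if_not_installed("survival")
  set.seed(23)
  worst <- 0
  for (i in 1:40) {
    n <- 35
    tm <- sample(1:7, n, replace = TRUE)
    ev <- runif(n) < 0.65
    x <- if (i %% 2 == 0) rbinom(n, 1, 0.5) else rnorm(n)
    if (sum(ev) < 2) next
    if (length(unique(x)) == 2 && any(tapply(ev, x, sum) == 0)) next
    fit <- cox_univariate(tm, ev, x)
    oracle <- survival::coxph(
      survival::Surv(tm, ev) ~ x, ties = "efron",
      control = survival::coxph.control(eps = 1e-12, toler.chol = 1e-13,
                                        iter.max = 100))
    expect_true(fit$converged)
    worst <- max(worst, abs(fit$coef - unname(coef(oracle))))
    expect_equal(fit$se, sqrt(unname(vcov(oracle)[1, 1])),
                 tolerance = 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("null covariates recover HR near 1 and label swap inverts the HR", {
  set.seed(24)
  tm <- rexp(600, 0.05)
  ev <- rep(TRUE, 600)
  grp <- rep(c(0, 1), 300)   # independent of the times
  fit <- cox_univariate(tm, ev, grp)
  expect_true(fit$converged)
  expect_lt(abs(fit$coef), 3 * fit$se)  # HR ~ 1 within sampling error

  swap <- cox_univariate(tm, ev, 1 - grp)
  expect_equal(swap$hazard_ratio, 1 / fit$hazard_ratio, tolerance = 1e-8)
  expect_equal(unname(swap$ci), unname(rev(1 / fit$ci)), tolerance = 1e-8)
})

test_that("degenerate Cox configurations are flagged, not estimated", {
  fit <- cox_univariate(c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, FALSE),
                        c(1, 1, 0, 0))
  expect_false(fit$converged)
  expect_match(fit$message, "zero events")
  expect_true(is.na(fit$hazard_ratio))
  fit <- cox_univariate(1:4, rep(FALSE, 4), c(1, 0, 1, 0))
  expect_false(fit$converged)
  fit <- cox_univariate(1:4, rep(TRUE, 4), rep(1, 4))
  expect_false(fit$converged)
  expect_match(fit$message, "constant")
})

test_that("Wald interval uses the fixed normal quantile and exponentiates", {
  set.seed(25)
  tm <- rexp(80, 0.1); ev <- runif(80) < 0.7; x <- rbinom(80, 1, 0.5)
  fit <- cox_univariate(tm, ev, x)
  expect_equal(fit$hazard_ratio, exp(fit$coef))
  expect_equal(fit$ci[["lower"]], exp(fit$coef - 1.959964 * fit$se))
  expect_equal(fit$ci[["upper"]], exp(fit$coef + 1.959964 * fit$se))
  expect_true(all(fit$ci > 0))
})
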