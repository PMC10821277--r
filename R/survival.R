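#' Build survival records from a cohort
#'
#' Converts outcome fields to (time, event) pairs under a named
#' definition. `tumor_specific`: the event is tumor-related death; deaths
#' from other causes and losses to follow-up are censored at their
#' respective times. `overall`: the event is death from any cause;
#' losses to follow-up are censored.
#'
#' @param cohort An `amf_cohort`.
#' @param definition `"tumor_specific"` or `"overall"`.
#' @return Data frame with columns `case_id`, `time` (months), `event`
#'   (logical), plus a `definition` attribute.
#' @export
build_survival <- function(cohort,
                           definition = c("tumor_specific", "overall")) {
  definition <- match.arg(definition)
  cs <- cohort$cases
  need <- c("followup_months", "died", "death_tumor_related")
  if (!all(need %in% names(cs)) || anyNA(cs$died) ||
      anyNA(cs$followup_months)) {
    stop("cohort lacks the outcome fields needed for survival records",
         call. = FALSE)
  }
  if (any(cs$followup_months <= 0)) {
    stop("followup_months must be positive for survival analysis; ",
         "violated by case(s): ",
         paste(cs$case_id[cs$followup_months <= 0], collapse = ", "),
         call. = FALSE)
  }
  bad <- cs$died & is.na(cs$death_tumor_related)
  if (any(bad)) {
    stop("died without a death-cause classification for case(s): ",
         paste(cs$case_id[bad], collapse = ", "), call. = FALSE)
  }
  event <- if (definition == "tumor_specific") {
    cs$died & cs$death_tumor_related
  } else {
    cs$died
  }
  out <- data.frame(case_id = cs$case_id, time = cs$followup_months,
                    event = event, stringsAsFactors = FALSE)
  attr(out, "definition") <- definition
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival curve from right-censored records: at each
#' distinct event time t with d events among n at risk, the survival
#' estimate is multiplied by (1 - d/n). Censoring times remove cases
#' from the risk set after t (ties between events and censorings at the
#' same time follow the usual convention: events first). With no
#' censoring the estimate equals the empirical survivor function. The
#' median is the smallest event time at which the curve reaches 0.5 or
#' below; if the curve never does, the median is explicitly "not
#' reached" (`median = NA`, `median_reached = FALSE`).
#'
#' @param time Positive times in months (or a data frame from
#'   [build_survival()]).
#' @param event Logical event indicators (ignored when `time` is a data
#'   frame).
#' @return Object of class `km_fit`: list with `table` (data frame
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`), `median`,
#'   `median_reached`, `n`.
#' @export
kaplan_meier <- function(time, event = NULL) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  stopifnot(length(time) == length(event), length(time) > 0,
            all(time > 0), !anyNA(time), !anyNA(event))
  event <- as.logical(event)
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- sort(unique(time))
  n <- length(time)
  n_event <- vapply(ut, function(t) sum(time == t & event), 0L)
  n_censor <- vapply(ut, function(t) sum(time == t & !event), 0L)
  n_risk <- n - c(0L, cumsum(n_event + n_censor))[seq_along(ut)]
  surv <- cumprod(1 - n_event / n_risk)
  tab <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  drop_idx <- which(tab$n_event > 0 & tab$survival <= 0.5 + 1e-12)
  reached <- length(drop_idx) > 0
  structure(list(table = tab,
                 median = if (reached) tab$time[drop_idx[1L]] else NA_real_,
                 median_reached = reached,
                 n = n),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function evaluation: S(t) is the estimate after the last event
#' time <= t, with S(t) = 1 before the first observed time.
#'
#' @param fit A `km_fit`.
#' @param times Numeric vector.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(fit, times) {
  stopifnot(inherits(fit, "km_fit"))
  tab <- fit$table
  vapply(times, function(t) {
    i <- which(tab$time <= t)
    if (length(i) == 0L) 1 else tab$survival[max(i)]
  }, 0)
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit:", x$n, "records,",
      sum(x$table$n_event), "events\n")
  cat("  median survival:",
      if (x$median_reached) paste(x$median, "months") else "not reached",
      "\n")
  invisible(x)
}

#' Univariate Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood for a single covariate (typically
#' a binary poor-prognosis indicator) by Newton-Raphson, with Efron's
#' correction for tied event times. Iteration starts at 0 and stops when
#' the absolute score falls below 1e-9 or the coefficient changes by less
#' than 1e-10, with at most 50 iterations. The Wald interval is
#' exp(coef +/- 1.959964 * se). Monotone-likelihood configurations (all
#' events in one group of a binary covariate, or a diverging coefficient)
#' are flagged non-convergent; no estimate is reported silently.
#'
#' @param time Positive times (or a data frame from [build_survival()]).
#' @param event Logical event indicators.
#' @param group Numeric or logical covariate (e.g. classifier
#'   positivity).
#' @return Object of class `cox_fit`: list with `coef`, `se`,
#'   `hazard_ratio`, `ci` (lower/upper), `converged`, `iterations`,
#'   `message`, `n`, `n_event`.
#' @export
cox_univariate <- function(time, event = NULL, group = NULL) {
  if (is.data.frame(time)) {
    if (is.null(group)) group <- event
    event <- time$event
    time <- time$time
  }
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(time > 0))
  event <- as.logical(event)
  x <- as.numeric(group)
  n <- length(time)
  n_event <- sum(event)

  fail <- function(msg) {
    structure(list(coef = NA_real_, se = NA_real_,
                   hazard_ratio = NA_real_,
                   ci = c(lower = NA_real_, upper = NA_real_),
                   converged = FALSE, iterations = 0L, message = msg,
                   n = n, n_event = n_event),
              class = "cox_fit")
  }
  if (n_event == 0L) return(fail("no events"))
  ux <- unique(x)
  if (length(ux) < 2L) return(fail("covariate is constant"))
  if (length(ux) == 2L) {
    ev_by <- tapply(event, x, sum)
    if (any(ev_by == 0)) {
      return(fail("monotone likelihood: a group has zero events"))
    }
  }

  # Risk sets: for each distinct event time, indices at risk and dying.
  et <- sort(unique(time[event]))
  risk_idx <- lapply(et, function(t) which(time >= t))
  death_idx <- lapply(et, function(t) which(time == t & event))

  score_info <- function(beta) {
    eta <- exp(x * beta)
    U <- 0; I <- 0
    for (j in seq_along(et)) {
      R <- risk_idx[[j]]; D <- death_idx[[j]]
      d <- length(D)
      s0r <- sum(eta[R]);           s0d <- sum(eta[D])
      s1r <- sum(eta[R] * x[R]);    s1d <- sum(eta[D] * x[D])
      s2r <- sum(eta[R] * x[R]^2);  s2d <- sum(eta[D] * x[D]^2)
      l <- seq_len(d) - 1L
      phi <- s0r - (l / d) * s0d
      mu <- (s1r - (l / d) * s1d) / phi
      nu <- (s2r - (l / d) * s2d) / phi
      U <- U + sum(x[D]) - sum(mu)
      I <- I + sum(nu - mu^2)
    }
    list(U = U, I = I)
  }

  beta <- 0
  msg <- "converged"
  converged <- FALSE
  iter <- 0L
  while (iter < 50L) {
    iter <- iter + 1L
    si <- score_info(beta)
    if (!is.finite(si$U) || !is.finite(si$I) || si$I <= 1e-12) {
      return(fail("singular information matrix"))
    }
    step <- si$U / si$I
    beta_new <- beta + step
    if (abs(beta_new) > 20) {
      return(fail("coefficient diverging (monotone likelihood)"))
    }
    done <- abs(si$U) < 1e-9 || abs(step) < 1e-10
    beta <- beta_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    # accept if the score is small even though neither tolerance tripped
    si <- score_info(beta)
    if (abs(si$U) < 1e-6) converged <- TRUE else msg <- "max iterations"
  }
  si <- score_info(beta)
  se <- 1 / sqrt(si$I)
  z <- 1.959964
  structure(list(coef = beta, se = se, hazard_ratio = exp(beta),
                 ci = c(lower = exp(beta - z * se),
                        upper = exp(beta + z * se)),
                 converged = converged, iterations = iter, message = msg,
                 n = n, n_event = n_event),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  if (!x$converged) {
    cat("cox_fit: NOT CONVERGED (", x$message, ")\n", sep = "")
  } else {
    cat(sprintf("cox_fit: HR %.3g (95%% CI %.3g-%.3g), coef %.4f (se %.4f), %d events/%d records\n",
                x$hazard_ratio, x$ci[["lower"]], x$ci[["upper"]], x$coef,
                x$se, x$n_event, x$n))
  }
  invisible(x)
}
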