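#' Parameters for the synthetic cohort generator
#'
#' The generator emulates a single-institution survival cohort of canine
#' cutaneous mast cell tumors. Each case belongs to a latent benign or
#' aggressive class; the mitotic count follows a class-specific negative
#' binomial (counts in hotspot regions are overdispersed), each case
#' draws an atypia probability from a class-specific beta law (so the
#' AMF count given the mitotic count is beta-binomial), multipolar AMFs
#' are binomial within the AMFs, and tumor-related and other-cause death
#' times are exponential with monthly rates, subject to uniform
#' administrative censoring. Cases lost to follow-up before the minimum
#' follow-up without having died are redrawn, mirroring the study
#' inclusion rule.
#'
#' Defaults are calibrated to the published cohort composition: 96
#' cases, an aggressive-class share of 18/96, expected totals of roughly
#' 640 mitotic figures of which ~100 atypical, about 13 tumor-related
#' deaths with ~61% mortality in the aggressive class, and a 12-month
#' minimum follow-up.
#'
#' @param n_cases Number of cases.
#' @param p_aggressive Probability a case is in the aggressive class.
#' @param mc_mean,mc_dispersion Length-2 numeric vectors
#'   (benign, aggressive): negative-binomial mean and size for the
#'   mitotic count.
#' @param atypia_shape1,atypia_shape2 Length-2 vectors: beta parameters
#'   of the per-case atypia probability.
#' @param p_multipolar Length-2 vector: probability an AMF is multipolar.
#' @param tumor_hazard Length-2 vector: monthly exponential rate of
#'   tumor-related death.
#' @param other_cause_hazard Monthly rate of death from other causes.
#' @param followup_admin_months Horizon H of the administrative
#'   censoring time, drawn uniformly on (0, H).
#' @param min_followup_months Minimum follow-up for survivors (months);
#'   cases censored earlier are redrawn.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return Object of class `generator_params` (a named list).
#' @export
generator_params <- function(n_cases = 96L,
                             p_aggressive = 18 / 96,
                             mc_mean = c(benign = 2.4, aggressive = 25),
                             mc_dispersion = c(benign = 1.2,
                                               aggressive = 1.5),
                             atypia_shape1 = c(benign = 0.6,
                                               aggressive = 3),
                             atypia_shape2 = c(benign = 9,
                                               aggressive = 12),
                             p_multipolar = c(benign = 0.02,
                                              aggressive = 0.15),
                             tumor_hazard = c(benign = 0.0007,
                                              aggressive = 0.03),
                             other_cause_hazard = 0.003,
                             followup_admin_months = 60,
                             min_followup_months = 12,
                             seed = 1L) {
  p <- list(n_cases = as.integer(n_cases), p_aggressive = p_aggressive,
            mc_mean = mc_mean, mc_dispersion = mc_dispersion,
            atypia_shape1 = atypia_shape1, atypia_shape2 = atypia_shape2,
            p_multipolar = p_multipolar, tumor_hazard = tumor_hazard,
            other_cause_hazard = other_cause_hazard,
            followup_admin_months = followup_admin_months,
            min_followup_months = min_followup_months,
            seed = as.integer(seed))
  stopifnot(p$n_cases >= 2L,
            p$p_aggressive >= 0, p$p_aggressive <= 1,
            all(p$mc_mean >= 0), all(p$mc_dispersion > 0),
            all(p$atypia_shape1 > 0), all(p$atypia_shape2 > 0),
            all(p$p_multipolar >= 0), all(p$p_multipolar <= 1),
            all(p$tumor_hazard >= 0), p$other_cause_hazard >= 0,
            p$followup_admin_months > 0, p$min_followup_months >= 0)
  structure(p, class = "generator_params")
}

# run expr with a private RNG stream seeded from `seed`; the caller's
# RNG state is untouched
with_private_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under [generator_params()]: latent class, overdispersed
#' mitotic count, beta-binomial AMF count, binomial multipolar count,
#' competing exponential death times with uniform administrative
#' censoring, and the minimum-follow-up inclusion rule (survivors
#' censored before `min_followup_months` are redrawn, up to 1000
#' attempts per case). Equal seeds give identical cohorts; the global
#' RNG state is left untouched.
#'
#' @param params A [generator_params()].
#' @return An `amf_cohort` whose cases carry an extra `aggressive`
#'   column (the latent class, available for parameter-recovery
#'   studies).
#' @export
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  with_private_rng(p$seed, {
    n <- p$n_cases
    cls <- stats::rbinom(n, 1L, p$p_aggressive) + 1L  # 1 benign, 2 aggressive
    mc <- stats::rnbinom(n, size = p$mc_dispersion[cls],
                         mu = p$mc_mean[cls])
    atypia <- stats::rbeta(n, p$atypia_shape1[cls], p$atypia_shape2[cls])
    amf <- stats::rbinom(n, mc, atypia)
    multipolar <- stats::rbinom(n, amf, p$p_multipolar[cls])

    followup <- died <- tumor_death <- numeric(n)
    for (i in seq_len(n)) {
      lt <- p$tumor_hazard[cls[i]]
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        t_tumor <- if (lt > 0) stats::rexp(1, lt) else Inf
        t_other <- if (p$other_cause_hazard > 0) {
          stats::rexp(1, p$other_cause_hazard)
        } else Inf
        t_admin <- stats::runif(1, 0, p$followup_admin_months)
        t_death <- min(t_tumor, t_other)
        if (t_death <= t_admin) {            # death observed
          followup[i] <- t_death
          died[i] <- 1
          tumor_death[i] <- as.numeric(t_tumor <= t_other)
          ok <- TRUE
        } else if (t_admin >= p$min_followup_months) {  # adequate follow-up
          followup[i] <- t_admin
          died[i] <- 0
          tumor_death[i] <- 0
          ok <- TRUE
        }
        if (ok) break
      }
      if (!ok) {
        stop("inclusion rule rejected 1000 consecutive draws; ",
             "check hazard/censoring parameters", call. = FALSE)
      }
    }

    cases <- data.frame(
      case_id = sprintf("sim_%03d", seq_len(n)),
      mc = as.integer(mc),
      amf_count = as.integer(amf),
      multipolar_count = as.integer(multipolar),
      multinucleated_count = 0L,
      bizarre_nuclei_count = 0L,
      karyomegaly = FALSE,
      followup_months = round(followup, 3),
      died = died == 1,
      death_tumor_related = tumor_death == 1,
      aggressive = cls == 2L,
      stringsAsFactors = FALSE
    )
    # guard against a zero-duration follow-up after rounding
    cases$followup_months <- pmax(cases$followup_months, 0.001)
    as_cohort(cases,
              provenance = sprintf("generate_cohort(seed=%d, n=%d)",
                                   p$seed, n))
  })
}

#' Closed-form cohort-level probabilities under the generator
#'
#' `expected_tumor_death_prob()` returns the exact probability that an
#' included case dies a tumor-related death, marginally and per class.
#' With total death rate L = tumor + other hazard and administrative
#' censoring uniform on (0, H): P(death observed) = 1 - (1 - e^(-LH)) /
#' (LH); a death is tumor-related with probability tumor/(L); inclusion
#' additionally admits survivors censored at or after the minimum
#' follow-up m, with probability (e^(-Lm) - e^(-LH)) / (LH). The
#' generator's redraw rule conditions every case on inclusion.
#'
#' @param params A [generator_params()].
#' @return List with `per_class` (benign, aggressive), `marginal`, and
#'   `class_weight_given_inclusion`.
#' @export
expected_tumor_death_prob <- function(params = generator_params()) {
  p <- params
  H <- p$followup_admin_months
  m <- min(p$min_followup_months, H)
  per_class <- vapply(1:2, function(k) {
    lt <- p$tumor_hazard[k]
    L <- lt + p$other_cause_hazard
    if (L == 0) return(c(death = 0, incl = (H - m) / H))
    death <- lt / L * (1 - (1 - exp(-L * H)) / (L * H))
    died_any <- 1 - (1 - exp(-L * H)) / (L * H)
    surv_ok <- (exp(-L * m) - exp(-L * H)) / (L * H)
    c(death = death, incl = died_any + surv_ok)
  }, c(death = 0, incl = 0))
  w <- c(benign = 1 - p$p_aggressive, aggressive = p$p_aggressive) *
    per_class["incl", ]
  w <- w / sum(w)
  cond <- per_class["death", ] / per_class["incl", ]
  names(cond) <- c("benign", "aggressive")
  list(per_class = cond,
       marginal = sum(w * cond),
       class_weight_given_inclusion = w)
}

# beta-binomial pmf: k successes in n trials, p ~ Beta(a, b)
dbetabinom <- function(k, n, a, b) {
  exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

# P(classifier positive | class), marginalizing mc over its NB law and
# amf | mc over the beta-binomial; mc truncated where the NB tail < tol
class_positive_prob <- function(params, rule, class_k, tol = 1e-12) {
  p <- params
  mu <- p$mc_mean[class_k]; size <- p$mc_dispersion[class_k]
  a <- p$atypia_shape1[class_k]; b <- p$atypia_shape2[class_k]
  q <- p$p_multipolar[class_k]
  mc_max <- stats::qnbinom(1 - tol, size = size, mu = mu)
  mc_vals <- 0:mc_max
  pmc <- stats::dnbinom(mc_vals, size = size, mu = mu)
  pmc[length(pmc)] <- pmc[length(pmc)] +
    stats::pnbinom(mc_max, size = size, mu = mu, lower.tail = FALSE)

  pos_given_mc <- vapply(mc_vals, function(mcv) {
    if (rule$statistic == "mc") {
      return(as.numeric(if (rule$direction == "ge") mcv >= rule$cutpoint
                        else mcv > rule$cutpoint))
    }
    if (mcv == 0) {
      val <- switch(rule$statistic, amf_count = 0, amf_mf_ratio = 0,
                    multipolar_presence = 0)
      return(as.numeric(if (rule$direction == "ge") val >= rule$cutpoint
                        else val > rule$cutpoint))
    }
    ks <- 0:mcv
    pk <- dbetabinom(ks, mcv, a, b)
    pos_k <- switch(
      rule$statistic,
      amf_count = {
        ind <- if (rule$direction == "ge") ks >= rule$cutpoint
               else ks > rule$cutpoint
        as.numeric(ind)
      },
      amf_mf_ratio = {
        ratio <- pmax(ks - 1, 0) / mcv
        ind <- if (rule$direction == "ge") ratio >= rule$cutpoint
               else ratio > rule$cutpoint
        as.numeric(ind)
      },
      multipolar_presence = {
        # P(multipolar count satisfies the cut | amf = k), binomial tail
        cut <- ceiling(rule$cutpoint)
        vapply(ks, function(k) {
          stats::pbinom(cut - 1, k, q, lower.tail = FALSE)
        }, 0)
      },
      stop("closed form not defined for statistic '", rule$statistic, "'",
           call. = FALSE)
    )
    sum(pk * pos_k)
  }, 0)
  sum(pmc * pos_given_mc)
}

#' Closed-form operating point of a classifier under the generator
#'
#' Exact expected sensitivity and specificity of a threshold rule under
#' a [generator_params()] law, obtained by summing the count mass
#' functions over the rule's acceptance region in each latent class and
#' mixing classes with their conditional weights: counts and survival
#' are independent given the class, so P(test+ | tumor death) mixes the
#' per-class positivity with weights proportional to class probability
#' times class tumor-death probability (and analogously for
#' specificity, using inclusion minus death). Serves as the oracle for
#' Monte-Carlo convergence of empirical operating points.
#'
#' @param params A [generator_params()].
#' @param rule A [threshold_rule()] over `mc`, `amf_count`,
#'   `amf_mf_ratio` or `multipolar_presence`.
#' @return List with `sensitivity`, `specificity`, and
#'   `positive_prob_by_class`.
#' @export
closed_form_operating_point <- function(params, rule) {
  stopifnot(inherits(params, "generator_params"),
            inherits(rule, "threshold_rule"))
  p <- params
  pos <- vapply(1:2, function(k) class_positive_prob(p, rule, k), 0)
  dp <- expected_tumor_death_prob(p)
  prior <- c(1 - p$p_aggressive, p$p_aggressive)
  # joint-with-inclusion masses per class
  incl <- vapply(1:2, function(k) {
    lt <- p$tumor_hazard[k]; L <- lt + p$other_cause_hazard
    H <- p$followup_admin_months; m <- min(p$min_followup_months, H)
    if (L == 0) return((H - m) / H)
    (1 - (1 - exp(-L * H)) / (L * H)) +
      (exp(-L * m) - exp(-L * H)) / (L * H)
  }, 0)
  death <- dp$per_class * incl   # P(tumor death & inclusion | class)
  w_pos <- prior * death
  w_neg <- prior * (incl - death)
  list(sensitivity = sum(w_pos * pos) / sum(w_pos),
       specificity = sum(w_neg * (1 - pos)) / sum(w_neg),
       positive_prob_by_class = stats::setNames(pos,
                                                c("benign", "aggressive")))
}
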