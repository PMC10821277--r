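# Shared helpers: small random-but-valid cohorts for property tests.

random_cases <- function(n, seed) {
  set.seed(seed)
  mc <- rnbinom(n, size = 1.5, mu = 5)
  amf <- rbinom(n, mc, runif(n, 0, 0.5))
  died <- runif(n) < 0.3
  tumor <- died & runif(n) < 0.6
  fu <- ifelse(died, round(runif(n, 1, 40), 1), round(runif(n, 12, 60), 1))
  data.frame(
    case_id = sprintf("c%03d", seq_len(n)),
    mc = as.integer(mc),
    amf_count = as.integer(amf),
    multipolar_count = as.integer(rbinom(n, amf, 0.3)),
    multinucleated_count = as.integer(rpois(n, 0.3)),
    bizarre_nuclei_count = as.integer(rpois(n, 0.3)),
    karyomegaly = runif(n) < 0.05,
    followup_months = fu,
    died = died,
    death_tumor_related = tumor,
    stringsAsFactors = FALSE
  )
}

random_cohort <- function(n = 30, seed = 1) {
  as_cohort(random_cases(n, seed), provenance = paste("helper seed", seed))
}

# brute-force pairwise-concordance AUC, the independent oracle route
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
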