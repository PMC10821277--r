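Package: amfmct
Title: Prognostic Evaluation of Atypical Mitotic Figures in Canine
    Cutaneous Mast Cell Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating atypical mitotic figures (AMFs) as
    prognostic markers in canine cutaneous mast cell tumors. Computes
    per-case marker statistics (mitotic count, AMF count, adjusted
    AMF-to-MF ratio with the subtract-one rule, multipolar AMF count,
    two-tier histologic grade), applies threshold classifiers and their
    combination, and quantifies prognostic accuracy with exact
    Clopper-Pearson confidence intervals, ROC curves with concordance
    AUC and DeLong variance, Kaplan-Meier estimation, and univariate Cox
    proportional-hazards regression with Efron tie handling, all
    implemented from first principles. Includes a seeded synthetic
    cohort generator with overdispersed mitotic counts, beta-binomial
    atypia and right-censored exponential survival, plus a deterministic
    96-case reference fixture reconstructed from published aggregate
    counts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
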