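#!/usr/bin/env Rscript
# Reference-cohort accuracy analysis.
#
# Runs the full marker battery on the frozen 96-case reference cohort:
# per-case profiles, threshold classifiers, the accuracy table with
# exact intervals, and the mitotic-count/ratio combination. Writes the
# cohort, the profiles and the rendered report under results/.

suppressPackageStartupMessages(library(amfmct))

dir.create("results/fixture", showWarnings = FALSE, recursive = TRUE)

fx <- paper_fixture()
print(fx)
write_cohort(fx, "results/fixture/cohort.csv")

prof <- marker_profiles(fx)
utils::write.csv(prof, "results/fixture/marker_profiles.csv",
                 row.names = FALSE)

death <- outcome_indicator(fx, "tumor_related_death")
message(sprintf("AMFs among all MFs: %d/%d (%s)", sum(fx$cases$amf_count),
                sum(fx$cases$mc),
                format_percent(sum(fx$cases$amf_count) / sum(fx$cases$mc))))
message(sprintf("high grade: %d/%d; tumor-related deaths: %d (%d high-, %d low-grade)",
                sum(prof$grade == "high"), nrow(prof), sum(death),
                sum(death & prof$grade == "high"),
                sum(death & prof$grade == "low")))

for (nm in c("amf_count", "amf_mf_ratio", "mc", "multipolar")) {
  ct <- confusion(fx, default_rules()[[nm]], "tumor_related_death")
  message("\n-- ", default_rules()[[nm]]$label, " --")
  print(accuracy_metrics(ct))
}

comb <- sum(prof$positive_mc_and_ratio & !death)
message(sprintf("\nMC false positives: %d of %d MC positives (%s); after combining with the ratio rule: %d",
                sum(prof$positive_mc & !death), sum(prof$positive_mc),
                format_percent(mean(!death[prof$positive_mc])), comb))

bundle <- run_analysis(fx)
render_report(bundle, "results/fixture/report")
message("\nreport written to results/fixture/report/")
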