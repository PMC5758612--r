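#!/usr/bin/env Rscript

# Baseline experiment: threshold elevation in macular-degeneration observers
# vs controls from the packaged individual threshold table. Deterministic.

suppressPackageStartupMessages(library(latmask))
dir.create("results", showWarnings = FALSE)

bundle <- reproduce_experiment1()
print(bundle)

gs <- bundle$group_summary
cat("\nReading of the group summaries: MD observers show collinear inhibition\n")
cat(sprintf("at 3 lambda (TE %.3f +/- %.3f) but less than controls (%.3f +/- %.3f),\n",
            gs$mean_te[gs$group == "MD" & gs$separation == 3],
            gs$sd_te[gs$group == "MD" & gs$separation == 3],
            gs$mean_te[gs$group == "control" & gs$separation == 3],
            gs$sd_te[gs$group == "control" & gs$separation == 3]))
cat(sprintf("and facilitation at 8 lambda (TE %.4f vs %.4f in controls):\n",
            gs$mean_te[gs$group == "MD" & gs$separation == 8],
            gs$mean_te[gs$group == "control" & gs$separation == 8]))
cat("reduced inhibition inside the perceptual field with preserved border.\n")

write_report_json(bundle, "results/baseline_report.json")
write.csv(gs, "results/baseline_group_te.csv", row.names = FALSE)
write.csv(bundle$one_sample, "results/baseline_one_sample_t.csv", row.names = FALSE)
cat("wrote results/baseline_report.json, baseline_group_te.csv, baseline_one_sample_t.csv\n")
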