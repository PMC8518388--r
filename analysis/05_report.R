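#!/usr/bin/env Rscript
# Step 5: render the plain-text analysis report.
#
# Collates the model, its diagnostics, the separation-fix audit trail and
# the descriptive pony summary (ponies are excluded from modelling) into
# results/report.txt.

suppressPackageStartupMessages(library(bitlesion))

cohort <- csv_to_cohort("results/exams_scored.csv", "results/lesions.csv")
res <- run_pipeline(cohort)
lines <- render_report(res, print = TRUE)
writeLines(lines, "results/report.txt")
cat("\nwrote results/report.txt\n")
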