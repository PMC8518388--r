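#!/usr/bin/env Rscript
# Step 2: score every horse's acute lesions and classify severity.
#
# Re-reads the CSVs from step 1, recomputes per-horse point totals and the
# A-D / merged AB-CD classification from the lesion records, and reports
# the severity spectrum by breed group. Rescoring a scored file is
# idempotent, so this step can be run on its own output.

suppressPackageStartupMessages({library(bitlesion); library(dplyr)})

cohort <- csv_to_cohort("results/exams.csv", "results/lesions.csv")
scored <- score_cohort(cohort$exams, cohort$lesions)
readr::write_csv(scored, "results/exams_scored.csv")

cat("Severity categories by breed group:\n")
scored |>
  mutate(group = ifelse(grepl("pony", breed), "pony", breed)) |>
  count(group, category) |>
  tidyr::pivot_wider(names_from = category, values_from = n, values_fill = 0L) |>
  as.data.frame() |>
  print()
cat(sprintf("\nMerged outcome: %d AB, %d CD; worst horse scored %d points\n",
            sum(scored$merged == "AB"), sum(scored$merged == "CD"),
            max(scored$total_points)))
cat("wrote results/exams_scored.csv\n")
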