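#!/usr/bin/env Rscript
# Step 3: univariable screening and the two contingency contrasts.
#
# Chi-square screen of every candidate factor against the merged AB/CD
# outcome (Standardbreds and Finnhorses only), the uncorrected Pearson
# chi-square for blood-in-mouth by breed, and the two-sided Fisher exact
# test for bar lesions by bit jointedness. The same two tests are also run
# on the counts printed in the source study, where they give p = .027
# (rounds to .03) and p < .001 respectively.

suppressPackageStartupMessages({library(bitlesion); library(dplyr)})

cohort <- csv_to_cohort("results/exams_scored.csv", "results/lesions.csv")
exams <- bin_covariates(cohort$exams)
modelled <- exams |> filter(breed %in% c("standardbred", "finnhorse"))

screen <- univariable_screen(
  modelled,
  c("breed", "sex", "age_group", "bit_type", "thickness_class",
    "tongue_tie", "overcheck", "check_bit", "jaw_strap", "galloped",
    "top_three", "money_won", "raced_within_2wk", "distance_m", "start_type"))
readr::write_csv(select(screen, -table), "results/univariable_screen.csv")
cat("Univariable chi-square screen (synthetic cohort):\n")
print(as.data.frame(select(screen, -table)), digits = 3)

blood_synth <- pearson_chi_square(blood_by_breed_table(modelled))
blood_paper <- pearson_chi_square(rbind(finnhorse = c(16, 62),
                                        standardbred = c(15, 136)))
cat(sprintf("\nBlood by breed: synthetic p = %.3f; printed counts p = %.3f\n",
            blood_synth$p_value, blood_paper$p_value))

bar_synth <- fisher_exact(bar_lesion_table(
  list(exams = cohort$exams, lesions = cohort$lesions)))
bar_paper <- fisher_exact(rbind(unjointed = c(34, 17), jointed = c(24, 122)))
cat(sprintf("Bar lesions by jointedness (Fisher): synthetic p = %.2g; printed counts p = %.2g\n",
            bar_synth, bar_paper))
cat("wrote results/univariable_screen.csv\n")
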