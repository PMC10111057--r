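#!/usr/bin/env Rscript
# Simulate the study cohort (71 completers across six groups) and summarize
# its questionnaires: per-group THI / HADS-A / HADS-S effect percentages.

suppressPackageStartupMessages(library(tinnaerp))
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(seed = 20260926)
tab <- cohort_table(cohort)
write.csv(tab, "results/cohort.csv", row.names = FALSE)

cat(sprintf("Simulated %d completers (%d recruits, %d non-completers)\n",
            length(cohort), sum(attr(cohort, "recruited")),
            sum(attr(cohort, "recruited")) - length(cohort)))
print(table(tab$group))
cat("\nHearing-level bands:\n")
print(table(tab$hearing_band))

es <- effect_summary(cohort)
write.csv(es, "results/effect_summary.csv", row.names = FALSE)
cat("\nQuestionnaire effects (percent of group):\n")
print(es, row.names = FALSE)
cat("\nMost participants show no category change between sessions,\n",
    "matching the questionnaire picture the pipeline is built to complement.\n")
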