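#!/usr/bin/env Rscript
# Statistical evaluation of the simulated therapy effects: per-group
# normality + paired Wilcoxon on the 16 per-channel session AUCs, the
# questionnaire effect summary, and the correlation screen between
# participant variables and the AUC attributes.

suppressPackageStartupMessages(library(tinnaerp))

sa <- read.csv("results/session_auc.csv")
groups <- unique(sa$group)

tests <- lapply(groups, function(g) {
  s0 <- sa$auc[sa$group == g & sa$session == "S0"]
  sf <- sa$auc[sa$group == g & sa$session == "Sf"]
  evaluate_therapy(s0, sf, group = g)
})

cohort <- simulate_cohort(seed = 20260926)
es <- effect_summary(cohort)

# correlation screen: demographic/audiological variables of the reduced
# EEG cohort vs the per-participant AUC attributes
pa <- read.csv("results/participant_auc.csv")
tab <- cohort_table(cohort)
tin <- do.call(rbind, lapply(seq_len(nrow(pa)), function(i) {
  rows <- tab[tab$group == pa$group[i], ]
  rows[pa$participant[i], c("age", "sex", "heart_rate", "hl_left",
                            "hl_right", "pitch", "intensity", "laterality")]
}))
tin$therapy <- as.integer(factor(pa$group))
tin$auc_max <- pa$auc_max
tin$auc_ch <- match(pa$auc_ch, default_montage())  # montage index coding
screen <- correlation_screen(tin)

report <- build_report(tests, effects = es, correlations = screen,
                       path = "results/report.json")
cat("\nSignificant correlations (alpha = 0.05):\n")
print(screen$significant, row.names = FALSE)
cat("\nNote: the paired Wilcoxon compares all 16 channels jointly, so a",
    "\nstrictly single-channel amplification registers in AUCch (see the",
    "\npipeline output) but not necessarily in the group-level p-value;",
    "\nregionally consistent changes are what moves the test.\n")
cat("\nwrote results/report.json\n")
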