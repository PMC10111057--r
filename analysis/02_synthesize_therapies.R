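#!/usr/bin/env Rscript
# Synthesize one personalized therapy program per group from the simulated
# cohort and verify each program's spectral contract.

suppressPackageStartupMessages(library(tinnaerp))
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(seed = 20260926)
tab <- cohort_table(cohort)
pick <- function(g) cohort[[which(tab$group == g)[1]]]
fs <- 16000

rows <- list()
note <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)

p <- pick("TRT")
trt <- synthesize_trt(p, duration = 5, fs = fs, seed = 1)
note(therapy = "TRT", participant = p$id, pitch = p$tinnitus$pitch,
     detail = sprintf("octave band %.0f-%.0f Hz, rms %.2e FS",
                      trt$meta$band[1], trt$meta$band[2], trt$meta$rms))

p <- pick("ADT")
adt <- synthesize_adt(p, n_pulses = 50, p_deviant = 0.2, fs = fs, seed = 2)
note(therapy = "ADT", participant = p$id, pitch = p$tinnitus$pitch,
     detail = sprintf("standard %.0f Hz, deviant %.0f Hz, %d deviants of %d",
                      adt$meta$f_standard, adt$meta$f_deviant,
                      sum(adt$meta$schedule$type == "deviant"),
                      nrow(adt$meta$schedule)))

p <- pick("TEAE")
teae <- synthesize_teae(p, duration = 5, fs = fs, seed = 3)
note(therapy = "TEAE", participant = p$id, pitch = p$tinnitus$pitch,
     detail = sprintf("%d pips, notch %.0f-%.0f Hz",
                      nrow(teae$meta$schedule), teae$meta$notch[1],
                      teae$meta$notch[2]))

p <- pick("BBT")
bbt <- synthesize_bbt(p, beat_hz = 10, duration = 5, fs = fs)
note(therapy = "BBT", participant = p$id, pitch = p$tinnitus$pitch,
     detail = sprintf("carrier %.0f Hz left, %.0f Hz right",
                      bbt$meta$carrier, bbt$meta$carrier + bbt$meta$beat_hz))

plc <- synthesize_placebo(duration = 5, fs = fs, tempo_bpm = 70, seed = 4)
note(therapy = "placebo/control", participant = "-", pitch = NA,
     detail = sprintf("untuned music at %d bpm", plc$meta$tempo_bpm))

summary <- do.call(rbind, rows)
write.csv(summary, "results/therapy_programs.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat("\nEvery waveform peak-normalized to |amplitude| <= 1;",
    "EEG-session stimuli reuse these syntheses truncated to 1-s tokens.\n")
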