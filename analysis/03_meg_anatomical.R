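#!/usr/bin/env Rscript
# Anatomical-ROI MEG analyses on simulated source time courses: the
# peak-anchored M170 window, the fixed early M100 control window, and the
# fixed late (300-500 ms) window with the pseudo-irregularity interaction.
# Trial counts are reduced relative to the behavioral simulation so the
# 10,000-permutation millisecond-wise tests stay tractable on one CPU.

suppressMessages(library(megpriming))

seed <- 20260101L
dir.create("results", showWarnings = FALSE)
config <- analysis_config(n_perm = 10000, seed = seed)

spec <- simulation_spec(n_subjects = 16, trials_per_condition = 10,
                        seed = seed)
design <- generate_design(spec)
epochs <- simulate_roi_timecourses(design, spec)
epochs <- baseline_correct(epochs, config$baseline_ms)

m170 <- run_meg_analysis(epochs, design, "anatomical_m170", config)
write_report(m170, "results/meg_m170_report.json",
             "results/meg_m170_report.txt")
print(m170)

m100 <- run_meg_analysis(epochs, design, "m100", config,
                         conditions = c("identity", "regular"))
write_report(m100, "results/meg_m100_report.json",
             "results/meg_m100_report.txt")
print(m100)

late <- run_meg_analysis(epochs, design, "late", config)
write_report(late, "results/meg_late_report.json",
             "results/meg_late_report.txt")
print(late)
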