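#!/usr/bin/env Rscript
# Functional-ROI analysis: localize the priming-sensitive source patch with
# the identity + regular localizer inside the fusiform/inferior-temporal
# masks, then test the held-out irregular and pseudo-irregular conditions on
# the fROI-averaged time courses.

suppressMessages(library(megpriming))

seed <- 20260101L
dir.create("results", showWarnings = FALSE)
config <- analysis_config(n_perm = 10000, seed = seed)

spec <- simulation_spec(n_subjects = 8, trials_per_condition = 6,
                        seed = seed)
design <- generate_design(spec)
src <- simulate_source_grid(design, spec, patch = 3:7, n_sources = 20)

report <- run_meg_analysis(src, design, "froi", config)
write_report(report, "results/froi_report.json", "results/froi_report.txt")
write_froi_json(report$froi_definition, "results/froi_definition.json")
write_froi_label(report$froi_definition, "results/froi_sources.label")
print(report)
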