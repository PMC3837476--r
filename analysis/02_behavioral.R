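#!/usr/bin/env Rscript
# Behavioral reaction-time priming analysis: per-condition mixed-model
# priming estimates with Monte-Carlo permutation p-values, plus the
# PrimeType x Pseudo-irregularity likelihood-ratio interaction test.
# Requires results/trials_preprocessed.tsv from 01_simulate.R.

suppressMessages(library(megpriming))

trials <- read_trial_table("results/trials_preprocessed.tsv")
config <- analysis_config(n_perm = 10000, seed = 20260101L)

report <- run_behavioral(trials, config)
write_report(report, "results/behavioral_report.json",
             "results/behavioral_report.txt")
print(report)
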