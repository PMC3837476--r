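# megpriming

Millisecond-wise mixed-model and cluster-mass permutation analysis of
masked-priming MEG experiments, with a seeded synthetic-data generator for
the full study design.

## What it analyzes

In masked-priming lexical decision, a briefly presented, pattern-masked
prime precedes a visible target (`taught–TEACH`). Facilitation from related
primes — faster responses, reduced evoked activity around the M170
(~150–190 ms, left fusiform) — indexes early, form-based morphological
decomposition. The design crosses a two-level `PrimeType` factor
(related/unrelated) with four word conditions (identity, regular past
tense, irregular past tense, pseudo-irregular controls such as
`bell–BALL`), with subjects and items as crossed random factors, and asks
whether irregular-verb priming tracks a gradient morphophonological support
score (`AlbrightScore` ∈ [0, 1]).

## Core statistic

At each timepoint *t* of the source time course, a linear mixed model with
crossed random intercepts:

> *y*ₛᵢ(*t*) = β₀(*t*) + β₁(*t*)·**1**[unrelated] + *u*ₛ + *w*ᵢ + ε,  *u*ₛ ~ N(0, σ²ᵤ), *w*ᵢ ~ N(0, σ²ᵥ)

Maximal runs of consecutive timepoints with |t-value| > 1.96 of one sign
form clusters with mass Σt (the sum of the pointwise t-values). Family-wise
correction is by the permutation distribution of the maximum |Σt| under
within-subject relabelings of `PrimeType`, with add-one Monte-Carlo
p-values, p = (1 + #{M\* ≥ M})/(1 + n_perm). Interactions (score × prime,
pseudo-irregularity × prime) use √χ² from likelihood-ratio tests of nested
ML fits in place of t. Because refitting an LMM for every
timepoint × permutation is infeasible, permuted-label statistics are
computed by generalized least squares at the per-timepoint REML variance
components (frozen from the observed fit); at the observed labeling this
equals the `lme4` t exactly, and an exact refit mode is available for
auditing.

The package also provides: preprocessing (baseline correction, zero-phase
low-pass filtering, amplitude-threshold trial rejection, RT trimming and
subject exclusion), evoked-peak window selection, functional-ROI
localization on a source grid (independent identity + regular localizer,
polarity-signed facilitation, ≥ 50%-of-peak connected extent), covariate
orthogonalization, and score-bin analyses.

## Worked example

```r
library(megpriming)

spec   <- simulation_spec(n_subjects = 16, trials_per_condition = 10, seed = 1)
design <- generate_design(spec)
epochs <- baseline_correct(simulate_roi_timecourses(design, spec), c(-150, -50))

config <- analysis_config(n_perm = 2000, seed = 1)
report <- run_meg_analysis(epochs, design, "anatomical_m170", config)
print(report)
#> == anatomical_m170 analysis ==
#> detected peak: 176 ms
#> pooled: window [151, 201] ms, 2000 perms
#>   cluster 160-200 ms, mass -219.90, MC p = 0.0004998
write_report(report, "m170.json", "m170.txt")
```

The generator injects a related-trial effect at 158–208 ms; the pipeline
detects the evoked peak at 176 ms, centers its 50 ms window there, and the
cluster test recovers the effect (negative mass: the indicator codes
unrelated, and related trials are more positive).

## Analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing JSON
and text reports to `results/`:

```sh
Rscript analysis/01_simulate.R        # design, RTs, trimming, rejection log
Rscript analysis/02_behavioral.R      # per-condition LMM priming + MC p, interaction LRT
Rscript analysis/03_meg_anatomical.R  # M170 peak window, M100 control, late window
Rscript analysis/04_meg_froi.R        # fROI localization + held-out condition tests
Rscript analysis/05_albright.R        # score orthogonalization, interaction, score bins
```

All computation lives in the package; the scripts are thin narrative
drivers. See the vignette
(`vignettes/millisecond-cluster-permutation.Rmd`) for the statistical
design, generator anchoring, and decisions on under-specified points.

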