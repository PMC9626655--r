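# gicadfc

Static and dynamic functional connectivity analysis between large-scale
brain networks for a paired two-session (before/after) fMRI cohort, built
around **group independent component analysis with an intrinsic reference**
(GICA-IR) and **affinity-propagation connectivity states**.

It is aimed at researchers who have a within-subject, two-condition
resting-state design (e.g. the same participants scanned before and after a
prolonged exposure) and want to ask: *which network-pair couplings changed,
did the repertoire of dynamic connectivity states change, and how do states
transition?* Because raw data for such cohorts are rarely shareable, the
package ships a synthetic-cohort generator with planted spatial sources,
state-switching covariance dynamics and known Markov chains, so the entire
pipeline is verifiable end-to-end by parameter recovery.

## The model

Each session is a spatial ICA, `X_i = M_i S_i` (T x V). For every network,
matched subject components are stacked into `R` (K x V) and the first
principal component `r = e1'R` is the *intrinsic reference*. One group map
per network is extracted from the temporally concatenated group data by the
constrained program

    maximize  J(s) = (E[G(s)] − E[G(v)])²          (negentropy, G = log cosh)
    subject to  ε(s, r) − ξ ≤ 0,  E[s²] − 1 = 0    (ε = 1 − cor(s, r))

solved by an augmented Lagrangian on the whitened unit sphere. Dual
regression yields subject time courses; Pearson correlation over the whole
series (static FC) and over a sliding window of W = 20 TRs, step 1
(dynamic FC; 141 windows for T = 160) yields per-window 6x6 matrices whose
15 upper-triangle edges form the DFC vector set (141 x 15). Affinity
propagation over these vectors extracts recurring DFC states; per-window
state labels give a row-stochastic Markov transition matrix; paired t tests
with Benjamini-Hochberg FDR control across the 15 edges compare the two
sessions at the group level (paired by window) and the individual level
(paired by subject).

## Worked example

```r
library(gicadfc)

cfg <- pipeline_config(
  cohort = cohort_config(n_subjects = 4, V = 400, seed = 1),
  seed = 1)
b <- run_pipeline(cfg)

# group maps vs planted sources
cc <- abs(cor(t(b$decomposition$group$S), t(b$ground_truth$source_maps)))
round(apply(cc, 2, max), 3)
#> 0.986 0.985 0.988 0.991 0.965 0.989

# group-level dynamic FC, paired by window across 141 windows:
head(b$stats$dfc_group[order(b$stats$dfc_group$p), ], 3)
#>    edge     t  df        p        q significant
#> 14  4-6 -11.9 140 4.08e-23 6.12e-22        TRUE
#> 9   2-6  11.7 140 1.66e-22 1.24e-21        TRUE
#> 4   1-5   9.6 140 4.52e-17 2.26e-16        TRUE

# individual-level static FC, paired by subject (only 4 subjects here):
head(b$stats$sfc_individual[order(b$stats$sfc_individual$p), ], 2)
#>   edge    t df     p     q significant
#> 3  1-4 1.98  3 0.142 0.505       FALSE
#> 5  1-6 1.67  3 0.193 0.505       FALSE

# window-label transition matrix of the "before" group states:
round(b$states_group$pre$transitions$pre$P[1:4, 1:4], 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.889 0.056 0.056 0.000
#> [2,] 0.059 0.941 0.000 0.000
#> [3,] 0.000 0.000 0.950 0.050
#> [4,] 0.000 0.000 0.000 0.941
```

Reading the output: every planted spatial source is recovered at the group
level (|spatial correlation| > 0.96); the session-2 perturbation planted by
the generator (an altered connectivity state plus re-weighted transitions)
surfaces as strongly significant group-level *dynamic* FC differences,
while *static* FC across only 4 subjects shows none — the same qualitative
group/individual dissociation the method is designed to probe. Strong
diagonal dominance in the transition matrix reflects the planted state
dwell times.

The generator itself is a first-class module:

```r
ch <- generate_cohort(cohort_config(n_subjects = 33, seed = 7))
length(ch$sessions)        # 66 session datasets (33 subjects x 2)
ch$ground_truth$source_maps   # what the pipeline must recover
```

## Command line

```sh
Rscript inst/cli/gicadfc.R run-all  --config cfg.json --out results/ --seed 1
Rscript inst/cli/gicadfc.R simulate --config cfg.json --out sessions/ --seed 1
```

`cfg.json` may override any `pipeline_config()` / `cohort_config()` field,
e.g. `{"cohort": {"n_subjects": 8, "V": 500}, "scenarios": ["pre", "post"]}`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and its
assumptions, the solver and its numerical choices, what the synthetic
cohort does and does not emulate, the affinity-propagation preference
conventions, and known limitations.
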