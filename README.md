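# netreconfig

Dynamic brain-network reconfiguration analysis for multichannel EEG, in R.

Resting-state EEG organizes into communities of phase-locked channels that
rearrange on the scale of seconds. `netreconfig` reconstructs those
dynamics and quantifies them: band-limited signals (Butterworth
decomposition after 50 Hz notch and 1 Hz high-pass) are cut into
non-overlapping 2-s windows; phase-locking value (PLV) connectivity per
window yields a multilayer network per subject and frequency band
(delta/theta/alpha/beta/gamma); communities are detected by seeded Louvain
modularity optimization, validated against degree-preserving
weight-shuffled surrogate nulls (p < 0.05, Bonferroni over layers), and
regularized over time by multilayer modularity with inter-layer coupling
ω. From the resulting node-by-layer partition sequence the package
computes, per node and per subject × band:

- **flexibility** `f_i` — fraction of layer transitions at which node *i*
  changes community;
- **disjointedness** `d_i` — fraction of transitions where it changes
  community alone;
- **cohesive fraction** `c_i` — partnered changes, with `f_i = c_i + d_i`
  exactly;
- **cohesion matrix / cohesion strength** `s_i` — pairwise co-transition
  counts and their normalized row sums;
- **community cohesion / disjointedness / change** — site-averaged
  summaries, with change = cohesion + disjointedness exactly.

Group analysis provides Kruskal–Wallis omnibus tests with Dunn post-hoc
comparisons under Benjamini–Hochberg FDR (site × band significance
matrices per group pair), and a six-classifier benchmark (SVM-RBF, random
forest, gradient boosting, MLP, KNN, naive Bayes) with repeated matched
subsampling on cohesion-strength features.

A synthetic cohort generator plants ground truth at both levels — block
models on a community switching schedule, and 19-channel oscillatory
recordings whose communities share band-limited carriers and switch at
scheduled window boundaries, with a per-group coupling deficit that lowers
downstream cohesion strength — so every stage of the pipeline is testable
against known truth.

## Worked example

```r
library(netreconfig)

# a cohort with a planted patient deficit: coupling 0.5 vs control 1.0
spec <- cohort_spec(seed = 11)            # 2 x 20 subjects, 60 s @ 500 Hz
sched <- random_schedule(19, 30, n_epochs = 5, seed = 11)
cohort <- generate_cohort(spec, sched)

tab <- run_cohort_pipeline(cohort, seed = 12)  # ~6 min on one CPU
fm <- feature_matrix(tab)                 # cohesion strength, 95 features
cs <- rowMeans(fm$x)
mean(cs[fm$labels == "control"])          # 0.0399
mean(cs[fm$labels == "patient"])          # 0.0278
wilcox.test(cs[fm$labels == "patient"], cs[fm$labels == "control"],
            alternative = "less", exact = FALSE)$p.value   # 5.7e-08

benchmark_classifiers(fm$x, fm$labels, "patient",
                      n_repetitions = 100, seed = 13)
#> <classification_report> target=patient, 100 repetitions
#>   svm  accuracy 0.998 +/- 0.018
#>   rf   accuracy 1.000 +/- 0.000
#>   gb   accuracy 0.943 +/- 0.095
#>   mlp  accuracy 0.994 +/- 0.027
#>   knn  accuracy 0.757 +/- 0.122
#>   nb   accuracy 0.939 +/- 0.076
```

The planted coupling deficit shows up exactly as designed: patients have
significantly lower mean cohesion strength, and the best of the six
classifiers separates the groups with accuracy well above 0.8 from
cohesion-strength features alone.

Real recordings enter through `read_recording()` (EDF or delimited matrix
with JSON sidecar), then `preprocess()`, `band_window()`,
`build_multilayer()`, `detect_communities()` and `reconfig_metrics()` —
or in one step via `subject_reconfig()`. A command-line front end lives at
`inst/cli/netreconfig` (`simulate`, `run`, `metrics`, `classify`
subcommands).

## Documentation

The methods vignette (`vignettes/network-reconfiguration.Rmd`) documents
the models, the parameter defaults and why they are what they are, what
the synthetic generator does and does not emulate, numerical choices, and
known limitations.
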