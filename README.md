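# dragkinetics

Drag-and-drop touchscreen gestures as digital biomarkers for developmental
screening in young children.

When a child drags an on-screen object to a target, the app logs every
touch sample: a timestamp, pixel coordinates, and a phase (`down`, `move`,
`up`). Children with developmental disabilities move differently — shorter
playtimes, more off-target wandering, and fewer reversals in the sign of
per-axis finger velocity and acceleration ("sign-change volatility", the
key biomarker). `dragkinetics` implements the complete analysis chain for
this kind of data, for researchers in digital phenotyping who need a
reproducible, file-driven pipeline that runs without access to clinical
logs:

* **Event-log model** — JSON Lines reader/writer for per-event touch logs
  with down/move/up stroke bracketing and round-trip identity
  (`read_sessions()`, `write_sessions()`).
* **Synthetic cohorts** — a seeded two-group session generator whose
  trajectory model (straight drift + sinusoidal micro-oscillation + noise)
  realizes the published group contrasts by construction
  (`generate_cohorts()`, `cohort_config_for_cles()`).
* **Kinetic features** — playtime, stroke counts and lengths, touch-region
  ratios, and per-axis velocity/acceleration sign-change counts
  (`extract_features()`, `features_table()`).
* **Comparison protocol** — Kolmogorov–Smirnov normality screening, F-test
  variance routing, t vs Mann–Whitney tests, and three effect sizes:
  Cohen's *d*, η², and the common language effect size
  CLES(A,B) = (#{a>b} + ½#{a=b}) / (n_A·n_B) by full pairwise enumeration
  (`route_and_test()`, `compare_all_features()`).
* **Joint-fusion 1D CNN** — a native-R convolutional network over the
  per-event channel stack, fused with the time-fixed feature vector, with
  stratified child-grouped 10-fold cross-validation reporting
  AUROC/AUPRC/accuracy/F/precision/recall/specificity as mean (SD)
  (`build_model()`, `run_cv()`, `grid_search()`).
* **Grad-CAM attribution** — gradient-weighted class activation maps over
  the sequence branch, joined back onto pixel coordinates for
  which-part-of-the-drag inspection (`grad_cam()`, `overlay_export()`).

See `vignettes/dragkinetics-methods.Rmd` for the models, parameter
conventions, and design decisions.

## Worked example

```r
library(dragkinetics)

cfg <- cohort_config(n_typical = 40, n_disability = 40, seed = 1)
sessions <- generate_cohorts(cfg)

feats <- features_table(sessions)
report <- compare_all_features(feats[feats$label == "typical", ],
                               feats[feats$label == "disability", ])
subset(report, feature %in% c("playtime_s", "acc_sign_changes_x",
                              "height_max_ratio"))
#>             feature median_a  iqr_a median_b  iqr_b routed_test p_value
#>          playtime_s    8.876 11.253    4.623  8.758      t_test  0.0374
#>    height_max_ratio    0.433  0.218    0.452  0.307      t_test  0.7039
#>  acc_sign_changes_x   44.500 51.750   26.500 53.500      t_test  0.1805
#>  effect_size_kind effect_size significant
#>           cohen_d      0.4744        TRUE
#>           cohen_d     -0.0853       FALSE
#>           cohen_d      0.3022       FALSE

data <- build_fused_dataset(sessions, max_len = 64)
cv <- run_cv(data, model_config(epochs = 15), k = 5, seed = 2)
cv
#> <cv_report> 5-fold cross-validation, 80 samples
#>   auroc        1.000 (0.000)
#>   auprc        1.000 (0.000)
#>   accuracy     0.988 (0.028)
#>   f_score      0.988 (0.026)
#>   precision    0.978 (0.050)
#>   recall       1.000 (0.000)
#>   specificity  0.975 (0.056)
```

Reading the output: medians and IQRs are per group (A = typical,
B = disability); each feature is routed to a t test or Mann–Whitney by the
normality screen, with the matching effect size. At 40 children per group
only the playtime contrast reaches significance on this seed, while the
classifier — which fuses all features with the event-level sequence —
separates the cohorts essentially perfectly: the built-in group contrasts
(oscillation rate 3 vs 1.5 cycles/s, wander probability 0.05 vs 0.35) are
deliberately strong.

The full pipeline (generate → extract → compare → cross-validate →
attribute) runs from a single YAML config:

```r
run_pipeline("pipeline.yaml", "run1")   # or: inst/cli/dragkinetics.R run ...
```

producing `sessions.jsonl`, `features.csv`, `comparison.csv`,
`cv_report.json`, ROC/PR curve points, and Grad-CAM overlay CSVs.

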