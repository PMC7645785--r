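# propriomap

Analysis toolkit for **proprioceptive hand-localization error maps**: the
spatial field of errors people make when they place their unseen hand under
visual targets. Given multi-session visual-matching trials on a 5 × 20
target grid (and, optionally, trajectory-copying movement traces recorded in
the same workspace), propriomap

- builds per-subject, per-session **error maps** (2 × 5 × 20 arrays of
  hand − target vectors, in cm) with regional summaries, session-wise error
  reduction `100% · (error₁ − errorᵢ)/error₁`, and per-target direction-bias
  tests using exact one-tailed binomial critical counts (for n = 26 at
  α = 0.05: ≥ 18 or ≤ 8 subjects biased the same way);
- quantifies **idiosyncrasy**: within-subject (same subject, different
  session) versus between-subject map similarity, as Pearson correlations of
  the 200 jointly flattened components (Fisher-Z + Welch's t) and as
  Euclidean map distances scaled by the number of targets (Wilcoxon), plus a
  tie-corrected Kendall's W trend test on between-subject distances across
  sessions;
- performs **person identification** with a small convolutional network
  (3 × 3 convolution, 13 filters, batch-norm, ReLU, dropout, fully connected,
  softmax; cross-entropy + SGD-momentum at lr 0.01, 350 epochs), implemented
  in base-R matrix algebra and trained on one or more sessions to identify
  subjects from a held-out session;
- scores **trajectory matching**: templates `x = αy + β·sin(πy)` (1 unit =
  211 mm), validity filtering (≥ 165 mm/s, no backward motion, no early
  start), motor error as the cut-point RMSE `√Σₖ₌₁³⁰ (x_k − x_{k,t})²` in cm,
  endpoint error, trajectory-local ("sandwich-target") localization error,
  subject-dummy regression and the motor-vs-localization correlation;
- ships a seedable **synthetic cohort generator** (smooth idiosyncratic
  vector fields, shared rightward/far-region group bias, session-wise
  learning shrinkage, i.i.d. measurement noise, curvature-dependent motor
  deviation) so the whole pipeline runs with no data download, plus CSV /
  JSON / YAML interfaces and an end-to-end seeded pipeline.

It is aimed at motor-control and psychophysics researchers who want these
analyses as tested, reusable functions rather than one-off scripts.

## Worked example

```r
library(propriomap)

co    <- cohort_config(seed = 1)          # 26 subjects, 3 sessions, calibrated defaults
trials <- generate_cohort(co)             # 7800 matching trials
maps  <- build_error_maps(trials)

sess <- sapply(maps, function(m) m$session)
mean(sapply(maps[sess == 1], mean_error_magnitude))
#> [1] 2.976508

res <- within_between_sets(maps, 1, 2)    # 26 within, 650 between coefficients
cmp <- compare_within_between(res)
c(within = cmp$mean_within, between = cmp$mean_between, p = cmp$p_value)
#>       within      between            p
#> 4.327884e-01 1.489324e-01 6.009783e-12

id <- identification_protocol(maps, train_sessions = c(1, 2), test_session = 3,
                              classifier_config(seed = 1))
id
#> identification: 19/26 correct (73.08%), chance 3.85%
```

A subject's session-1 mean error of about 3 cm, within-subject correlations
near 0.45 against between-subject correlations near 0.15, and identification
far above the 1/26 chance level are the signatures of a stable, idiosyncratic
localization map. The full pipeline — simulation, maps, similarity,
identification, trajectory scoring, report — runs as one call:

```r
bundle <- run_pipeline(run_config(cohort = co, output_dir = "out"))
cat(render_report(bundle, "markdown"))
```

A thin command-line wrapper with `simulate`, `maps`, `similarity`,
`identify`, `trajectory` and `all` subcommands is installed at
`inst/cli/propriomap.R`.

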