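---
title: "Models and methods behind propriomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind propriomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

propriomap analyses spatial maps of proprioceptive hand-localization error:
the vector field of differences between visual targets on a grid and where a
person, without seeing their hand, places it. Such maps are strongly
idiosyncratic — a subject's map resembles their own map from another session
far more than anyone else's — and the package quantifies that idiosyncrasy
with similarity statistics and a person-identification classifier, alongside
motor-error scoring in a trajectory-copying task performed in the same
workspace. Because the package must run end-to-end without any data
download, it ships a seedable synthetic-cohort generator that emulates the
statistical structure of the real measurements.

## The workspace and the error map

Targets form a 5 x 20 matrix inside a 487.6 x 269.6 mm workspace whose near
edge sits 200 mm in front of the body. Spacings are `width / n_cols` =
24.38 mm between columns and `depth / n_rows` = 53.92 mm between rows, with
targets at the centers of the implied cells; the cell-center convention is
used because the printed spacings equal extent/count rather than
extent/(count - 1). Row 1 is nearest the body and x = 0 is the body midline.

An error map is a `2 x 5 x 20` array in cm. The error vector is **hand minus
target** — its tail at the target, its head at the registered hand position
— so a positive x component is a rightward error and a positive y component
an error away from the body. The simulator works in mm; conversion to cm
happens once, when a map is built from trials.

## The synthetic cohort generator

Each subject `i` carries a latent idiosyncratic field: white noise per
target and component smoothed by a Gaussian kernel with correlation length
60 mm (smooth enough that neighbouring targets share error structure, the
salient feature of real maps). The smoothed field is rescaled so its RMS
vector magnitude equals `idio_scale` **in expectation**. The normalization
constant `E[RMS]` is computed exactly from the eigenvalues of the smoothing
kernel via the chi-square characteristic function, not as
`sqrt(E[RMS^2])` — with a 60 mm correlation length the field has few
effective degrees of freedom and the two differ by ~9%. Normalizing in
expectation (rather than rescaling each realization exactly) preserves
between-subject variation in overall map amplitude (~20% coefficient of
variation), which real cohorts clearly have and which the motor-coupling
analyses need.

All subjects share a group bias: a rightward x error growing linearly with
distance from the left shoulder (placed at x = -180 mm; 0.06 mm error per mm
of distance) plus a 4 mm forward y error. A distance-from-body gain of 1.5
multiplies the whole measured error in the two far rows. We apply this gain
to the full error, not only to the shared bias, because errors in real data
are larger away from the body as a property of proprioceptive uncertainty
itself; applied to the bias alone, the far > near regional contrast would
drown in the smooth field's regional fluctuations.

The measured session map is

```
map = learning_factor(session) * row_gain * (bias + field + noise),
```

with i.i.d. Gaussian noise (SD `noise_sd` = 13 mm per component per target).
The learning factor multiplies the *whole* measured map, noise included.
This is deliberate: real repeated measurements show the mean error shrinking
by ~22% by the third session while within-subject map correlations stay
flat, which is only possible if the trial-to-trial scatter shrinks along
with the systematic error. The defaults (1, 0.95, 0.78) concentrate the
improvement on the second day.

Defaults were calibrated once so that a default cohort reproduces the
summary structure of real data, and then frozen: session-1 mean error
~2.9 cm (real data ~3.1 cm), within-subject map correlation ~0.44, between
~0.15, far > near in ~99% of subjects, session-3 error reduction ~21.5%.
One root seed drives everything; per-subject and per-session streams are
derived by fixed offsets so adding subjects never changes existing ones, and
identical configs give bit-identical tables.

Trajectory trials copy templates `x = alpha * y + beta * sin(pi * y)` (one
template unit = 211 mm of depth) with constant depth speed over 1.2 s at
130 Hz. The produced trace is the template plus a smooth random deviation
(linear drift + two sinusoidal harmonics, normalized to unit RMS at the
scoring cut points) whose amplitude is `b0 + b1 * |beta|` mm (defaults 2.5
and 3), so motor error grows with curvature; mean RMSE under the defaults is
~2.1 cm. Every template appears twice in a row, in randomized order. A
`coupling` parameter (default 0) adds the subject's trajectory-local field
magnitude to the amplitude; at 0, motor and localization error are truly
independent, which is what the type-I calibration of the motor-localization
correlation tests.

### What the generator does not emulate

Trial-order effects, drift within a session, anisotropic or
distance-dependent noise, hand-dominance mirroring, movement kinematics
beyond constant depth speed, and any real spatial shape of individual maps.
Passing tests therefore show that the *analysis* recovers structure the
generator plants under realistic magnitudes — not that real maps have that
structure.

## Error-map statistics

- `mean_error_magnitude` is the mean over targets of the error-vector
  length, in cm.
- Regions: left/right split the 20 columns 10/10; near = rows 1–3,
  far = rows 4–5. The overall mean is the row-count-weighted mean
  `(3 near + 2 far) / 5`.
- `error_reduction(e1, ei) = 100 * (e1 - ei) / e1`, positive = improvement.
- Direction-bias tests count, per target, subjects whose session-averaged
  component is positive; components exactly 0 count as not-positive (a
  measure-zero event for continuous data). Significance uses exact
  one-tailed binomial criticals at each tail: for n = 26 at alpha = 0.05
  these are 18 and 8. One-tailed tails are used because those are the
  criticals consistent with that pair; a sentinel `NA` is returned when no
  count attains alpha (e.g. n = 4). Note 18/26 = 69.2%, so a "70%" shorthand
  for the critical fraction would be slightly off; the count rule is
  authoritative.

## Similarity

Two maps are correlated by Pearson's r over their 200 jointly flattened
components — x and y concatenated — because per-component averaging would
not yield one coefficient per map pair. Map distance is the Euclidean norm
of the 200-component difference divided by 100; this printed rule is kept
as-is even though it is not literally a per-target mean. For a session pair
with n subjects there are n within-subject and n(n-1) ordered
between-subject coefficients. Correlations are Fisher-Z transformed before
Welch's t-test by default (`transform = "none"` gives the raw comparison);
distances are compared with the Wilcoxon rank-sum test. Zero-variance maps
make the correlation undefined and raise an error rather than propagating
NaN. Subjects missing a session are dropped with a warning, never imputed.
The session-wise decline of between-subject distances is tested with a
tie-corrected Kendall's W (cross-checked in the tests against
`friedman.test`, since `chisq = m (k - 1) W`) and Bonferroni-corrected
pairwise Wilcoxon signed-rank post-hocs, the package's convention for
multiple testing across session pairs.

## The identification classifier

The classifier is a deliberately small image-style CNN over the
`2 x 5 x 20` map: 3 x 3 convolution with 13 filters (valid padding, so the
spatial output is 3 x 18), batch normalization, ReLU, dropout, one fully
connected layer, softmax; cross-entropy loss minimized by SGD with momentum
at initial learning rate 0.01, input sequence shuffled every epoch. It is
implemented directly in base-R matrix algebra (im2col); at these input sizes
(tens of maps of 200 numbers) a compiled deep-learning backend would add
nothing but a dependency.

Hyperparameters that the architecture fixes: kernel 3, 13 filters, learning
rate 0.01, 250–500 epochs with 350 as the default. The rest are set to the
conventional defaults of mainstream training frameworks and are all
configurable: dropout 0.5, momentum 0.9, valid padding, Glorot-uniform
initialization, `batch_size = min(128, N)`. Maps are fed in cm with no
input normalization beyond the batch-norm layer. The config seed governs
initialization, shuffling and dropout, so training is bit-reproducible; a
protocol result records its seed.

Protocols train on any set of sessions and test on a held-out one
(training/test overlap is an error). On the default 26-subject cohort,
training accuracy reaches 100% (52 training maps, heavily
over-parameterized) and test accuracy for the 1+2 -> 3 split is far above
the 1/26 chance level; with `idio_scale = 0` or permuted labels it returns
to chance, which the test suite checks against the exact binomial band.

## Trajectory scoring

Motor error is computed exactly as defined for the task: the trace is cut at
30 depth points `y = k/30` (k = 1..30 — the endpoint included, the common
start excluded; the only reading that makes a 30-term sum well-defined), the
trace's x is linearly interpolated at each cut (valid trials have monotone
y), and the score is `sqrt(sum(dev^2))` in cm — the square root of the sum,
with **no** division by 30, which matches the ~2 cm magnitudes the task
produces. A normalized per-point variant is available behind
`normalized = TRUE`, off by default. Useful closed forms: a constant offset
of d cm scores `d * sqrt(30)`; a beta = 0.1 deviation against a straight
template scores `2.11 * sqrt(15)` cm because the cut-point sin^2 sum is
exactly 15.

Validity follows the task rules: mean speed (path length over elapsed time)
at least 165 mm/s, no backward y step, no samples before the go cue.
Endpoint error is defined here as the absolute x deviation at y = 1 (the
quantity is otherwise underdetermined; a beta-only deviation has zero
endpoint error since sin(pi) = 0). Trajectory-local localization error
averages the map magnitude at the two column targets bracketing the
template's x on each row, clamped to the two outermost columns when the
template exits the grid laterally; row depths are taken relative to the
movement start at the near workspace edge, evaluating the analytic template
formula beyond y = 1 where a far row lies past the nominal template end.
The endpoint-specific variant uses the two far-row targets bracketing the
endpoint. The motor-vs-localization regression uses fixed subject dummies
with a common slope (residual df = N - n_subjects - 1); the subject-level
correlation is Pearson unless a Shapiro-Wilk pre-check fails for either
variable, in which case Spearman's rho is used.

The 15-template default set is an evenly spaced stand-in over the stated
parameter ranges (`alpha in {-1, -0.5, 0, 0.5, 1}` crossed with
`beta in {-0.9, -0.05, 0.8}`), since the individual pairs of the original
task are not published; it excludes the familiarization template (0, 0.1)
and is fully configurable.

## Numerical and design notes

- Internal units are mm; reported units cm; the conversion happens once at
  the error-map boundary.
- All randomness flows through one helper that sets and restores the RNG
  state, so library calls never perturb a caller's stream.
- Degenerate inputs fail loudly: incomplete maps name the missing (row,
  col); zero-variance correlations, constant correlation inputs, empty test
  sets, collinear regressions and unknown sessions all raise errors.
- Batch-norm uses eps = 1e-5 and running statistics with momentum 0.1 for
  inference.
- Kendall's W uses the tie-corrected formula; ties are broken by midranks.

## Problem sizes in the test suite

The tests run cohorts at the study's scale (26 subjects, 3 sessions, 100
targets) where the quantity under test depends on it — identification,
idiosyncrasy recovery, learning recovery (100 cohorts), null calibration of
the motor-localization correlation (200 cohorts), chance recovery of the
classifier (100 training runs at 250 epochs, the low end of the epoch
range) — and smaller cohorts (2–12 subjects) for structural and property
checks. These sizes are the package's choices for stable Monte-Carlo
estimates at interactive runtimes.

## Known limitations

- The generator's learning factor rescales the whole map homogeneously, so
  simulated between-subject distances decline across sessions more
  concordantly than real ones do (Kendall's W near 0.8 on default cohorts,
  versus ~0.2 in real data where learning is heterogeneous).
- The CNN is single-threaded base R: training one default protocol takes a
  few seconds; hundred-replicate sweeps take minutes.
- `shapiro.test` limits the auto-switching correlation to 5000 subjects,
  far beyond any realistic cohort.
- The trajectory deviation model is a 3-basis smooth field; it does not
  emulate submovement structure, speed-curvature coupling, or endpoint
  corrections.
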