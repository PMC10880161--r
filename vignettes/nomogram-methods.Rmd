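---
title: "Methods: coefficient-only nomograms for logistic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coefficient-only nomograms for logistic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nomolog)
```

## The model class and what a nomogram does

`nomolog` operates on fitted binary logistic regressions,
$p = \mathrm{sigmoid}(\beta_0 + \sum_{i=1}^d \beta_i x_i)$, presented as
coefficients only: no training data, no model object, just $\beta_0$, the
$\beta_i$, and a plausible range $[\min_i, \max_i]$ for each predictor,
optionally with a decision threshold $\theta \in (0,1)$ that splits
predictions into high and low risk (high iff $p > \theta$). A nomogram
replaces the $d$ multiplications, the summation, and the exponential with
graphical look-ups: read each value's points off its axis, add the points,
and read the probability off the total-points scale.

The construction rests on two affine maps.

**Point assignment.** Predictor influence is scored by
$|\beta_i| \cdot (\max_i - \min_i)$ — the largest absolute swing the
predictor can contribute to the linear predictor. The highest-scoring
predictor anchors the shared ruler at $P^{max}$ points and every other
predictor receives the proportional maximum
$P_i^{max} = P^{max} \, |\beta_i| \mathrm{range}_i / |\beta_j| \mathrm{range}_j$.
Values map linearly onto $[0, P_i^{max}]$; a negative coefficient reverses
the axis so more points always means more risk. Scores are invariant to a
joint rescaling of all coefficients, so the chart depends on the model
only through the direction and relative magnitude of its effects.

**Probability assignment.** The attainable range of the linear predictor
over the box $\prod_i [\min_i, \max_i]$ is computed in closed form
(positive-coefficient predictors contribute their minimum to the lower
bound and maximum to the upper; negative-coefficient predictors the
reverse). The total $P_{total} \in [0, \sum_i P_i^{max}]$ is mapped
affinely onto that range and through the sigmoid. Because the point maps
and the total map are built from the same scores, the composition cancels
exactly: the probability read from unrounded points equals the logistic
formula. This *round-trip identity* is the package's correctness core and
is property-tested to $10^{-9}$ absolute over 1200 random model/patient
pairs (models up to $d = 8$, coefficient scales 0.1–10).

The probability panel plots the sigmoid curve against a uniform
probability axis, instead of transferring the sigmoid's distortion onto an
unevenly spaced probability ruler as classical nomograms do; reading the
panel is a vertical drop from the total ruler followed by a horizontal
read on an even scale.

## Tunable parameters

* `p_max` (points, default 100): the ruler length anchored by the most
  influential predictor. Pure presentation — probabilities are invariant
  to it. 100 is the near-universal convention.
* `granularity` (points, default 10): tick step assumed in graphical-mode
  evaluation and the reading simulator. Published worked readings of such
  charts come in multiples of 10, which motivates the default; it is an
  assumption about readers, not about the model.
* `noise_sd` (points, default 0): per-axis Gaussian reading error in the
  simulator, applied before rounding — the simplest plausible model of an
  imprecise eye.
* `tick_target` (count, default 6): desired ticks per axis before the
  nice-step policy (steps from $\{1, 2, 2.5, 5\}\times 10^k$, endpoints
  always included, count kept within a factor 2 of the target).
* `n_bins` (default 10) and `conf_level` (default 0.95) in
  `summarize_readings()`: equal-width calibration bins on read
  probability, with normal-approximation intervals
  $\bar{p} \pm z_{1-\alpha/2}\, s/\sqrt{n}$ per bin. The normal
  approximation was chosen for transparency; with fewer than two cases in
  a bin no interval is reported.

## The metadata template

The interchange format is the six-column table `feature, coef, min, max,
type, position`, rows one and two reserved for the intercept and the
(possibly blank) threshold, read from CSV or the first sheet of an XLSX
workbook, written as CSV. Two deliberate reader conveniences: the header
`family coef` is accepted as a synonym for `coef`, and validation is
total — every malformed cell is reported with its row and column rather
than aborting at the first.

One-hot levels of a nominal variable are encoded as rows named
`parent::level` with range $[0, 1]$. This naming convention is this
package's choice of file syntax (the merging of one-hot levels onto a
single dashed axis is standard; a file convention for it is not), and the
reference level is implicit at 0 points. In the probability map each level
is treated as an independent $[0,1]$ predictor, exactly as the range
formulas state; because the levels are mutually exclusive the total-points
ruler then covers a superset of the attainable totals. We kept the
faithful formulas rather than tightening the range: the round-trip
identity holds for every *feasible* one-hot assignment either way, and
tightening would make the axis bounds depend on combinatorial structure
the formulas do not encode.

## Numerical and policy choices

* Sigmoid: branch-free stable form, inputs clipped at $\pm 700$ before
  exponentiation ($e^{710}$ overflows a double).
* Points are exact reals internally; rounding exists only in display and
  in graphical/simulated reading. This keeps `points_to_value()` an exact
  algebraic inverse and makes the template write→read→write cycle
  byte-stable (numbers are serialised with shortest-round-trip formatting).
* Initializer ties break to the earliest file row; predictor order is file
  order throughout, so every construction is deterministic.
* Boundary classification $p = \theta$ is *low*: the high-risk label is
  defined by a strict inequality, and the boundary must land somewhere
  deterministic.
* Degenerate inputs: `coef = 0` axes are drawn flat and warn (zero
  points everywhere); `max = min` with a nonzero coefficient is rejected
  (the value→points map would divide by zero); `max = min` with
  `coef = 0` is dropped with a warning. A model whose every score is zero
  has no initializer and is refused.
* Out-of-range patient values error by default (`strict = TRUE`) — out-of
  range clinical inputs are usually data errors — with an explicit lenient
  mode that clamps and warns.
* An unattainable threshold (outside the probability range the box can
  produce) omits the marker with a warning rather than failing the whole
  layout.

## Graphical reading error

Rounding each of the $d$ predictor axes and the total ruler to step $g$
perturbs the total by at most $(d+1)\,g/2$ points; the affine map scales
points to sigmoid input by $(\mathrm{max\_value}-\mathrm{min\_value}) /
P_{total}^{max}$, and the sigmoid is $\tfrac14$-Lipschitz, giving

$$|p_{read} - p_{exact}| \le \tfrac14 \cdot
\frac{\mathrm{max\_value}-\mathrm{min\_value}}{P_{total}^{max}}
\, (d+1) \, \frac{g}{2}.$$

Two consequences are tested as properties: noise-free misclassification
can only occur for cases whose exact probability lies within this bound
of $\theta$, and as $g \to 0$ graphical mode converges to exact mode. The
test suite also constructs a 154-reading study with cases at controlled
distances from the threshold and checks that every error falls on the
cases nearest it — the computational analogue of readers only fumbling
borderline patients.

## What the synthetic generator does and does not emulate

`random_model()` draws coefficients from a centred Gaussian and mixes four
range styles (unit, wide continuous, binary, and 3–4-level one-hot
groups); `random_patients()` draws uniformly inside the box, integer-
valued on discrete axes, with at most one active level per one-hot group.
This exercises the algebra — orientation, merging, degenerate and
near-degenerate scales — across a wide space of shapes, which is what the
construction depends on. It does **not** emulate real clinical data:
predictors are independent and uniform (no correlation structure, no
realistic prevalence), coefficients are not fitted to anything, and
simulated readers are rounding-plus-Gaussian, not humans. Passing tests
therefore certify the chart's mathematics and the error-propagation
bounds, not the clinical validity of any model drawn, and the simulator's
accuracy figures are not predictions of human reader performance.

The bundled CMV model carries published coefficients, intercept, and
threshold; its predictor *ranges* are package defaults (age 0–100, binary
0/1, prednisone dose 0–50, CD34⁺ count 0–20) because the publication
shows ranges only in figures. Exact-mode probabilities are provably
range-invariant, so the defaults affect only the printed axes and the
per-axis point breakdown.

## Problem sizes

The default suite uses models of $d \le 8$, 1200 pairs for the round-trip
identity, 200 models for template round-trips, 60 for the brute-force
formula oracles, 40 for the reading-error bound, and reading studies of
120–200 patients — sizes at which every property above is exercised in
about a minute on one core.

## Known limitations

* Strictly linear logistic models: no splines, interactions, or
  non-logistic links — a nonlinear term has no single affine axis.
* The template writer emits CSV only (XLSX is read but not written).
* SVG output is structured for programmatic inspection; byte-identical
  output across library versions is guaranteed only for the SVG path,
  not for PNG/PDF devices.
* The uneven-probability-ruler style of classical nomograms is not
  rendered; the uniform-axis sigmoid panel is the only probability
  display.
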