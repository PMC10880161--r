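# nomolog

Nomograms for logistic regression models, built from coefficients alone.

## The problem

Many published clinical prediction models are logistic regressions reported
only as a table of coefficients — the training data are unavailable and no
nomogram was ever drawn. Standard nomogram tooling (`rms::nomogram`,
`hdnom`) wants the fitted model object, so those published models are
effectively locked out of graphical use at the bedside.

`nomolog` needs nothing but the fitted coefficients and each predictor's
plausible range. From a six-column metadata table (`feature, coef, min,
max, type, position`, with the intercept and an optional decision
threshold in the first two rows) it constructs, draws, and numerically
evaluates the nomogram, and can quantify how much accuracy is lost to
reading the chart by eye.

## The method

For a model p = sigmoid(β₀ + Σᵢ βᵢxᵢ) with xᵢ ∈ [minᵢ, maxᵢ]:

**Point assignment.** Each predictor's influence score is
|βᵢ|·(maxᵢ − minᵢ). The highest-scoring predictor (the *initializer*) is
anchored to the full ruler, P^max points (100 by default); every other
predictor gets a maximum of

&nbsp;&nbsp;Pᵢ^max = P^max · |βᵢ|(maxᵢ − minᵢ) / |βⱼ|(maxⱼ − minⱼ),

with j the initializer. Values map affinely onto 0..Pᵢ^max, oriented so
that more points always means higher risk (reversed when βᵢ < 0).

**Probability assignment.** The linear predictor's attainable range over
the predictor box is [min_value, max_value] (each positive-β predictor
contributes its minimum to the lower bound, each negative-β its maximum,
and vice versa). A point total P_total ∈ [0, P_total^max = Σ Pᵢ^max] maps
to

&nbsp;&nbsp;p = sigmoid( min_value + (P_total / P_total^max)·(max_value − min_value) ),

drawn as a sigmoid curve against a *uniform* probability axis rather than
the unevenly spaced probability ruler of classical nomograms. The two
affine maps compose so that the point-sum probability equals the logistic
formula exactly — the package's property tests verify this round-trip to
1e-9 over a thousand random models.

**Axis design.** Continuous predictors get solid axes; nominal, ordinal
and discrete ones get dashed axes. One-hot indicator columns named
`parent::level` are merged onto a single dashed axis, each level labelled
at its own point value with the reference level implicitly at 0.

**Reading fidelity.** Reading a printed chart rounds each axis to tick
granularity g. The induced probability error is bounded by
¼·(max_value − min_value)/P_total^max·(d+1)·(g/2), and the simulated-reader
module (`simulate_readings()`, `summarize_readings()`) adds optional
Gaussian reading noise, then summarises discrimination (confusion matrix,
accuracy) and calibration (binned curve with 95% CIs).

## Worked example

The bundled `cmv_model()` is a published model for refractory/recurrent
cytomegalovirus infection after haploidentical stem-cell transplantation
(coefficients 0.0322 age, −0.0696 gender, 0.5492 underlying disease,
0.0963 cumulative prednisone dose, −0.0771 CD34⁺ cell count; intercept
−1.2926; threshold 0.5243).

```r
library(nomolog)

nomo <- nomogram(cmv_model())
nomo
#> <nomogram> 5 predictor(s), 0 nominal group(s)
#>   initializer: prednisone_dose (100 points)
#>   total points 0..211.7508 -> probability [0.05195, 0.9993]
#>   threshold: 0.5243

res <- evaluate_patients(c(50, 1, 1, 14, 7), nomo)
res$points[[1]]
#> # A tibble: 5 × 3
#>   feature            value points
#>   <chr>              <dbl>  <dbl>
#> 1 age                   50   33.4
#> 2 gender                 1    0
#> 3 underlying_disease     1   11.4
#> 4 prednisone_dose       14   28
#> 5 cd34_count             7   20.8
res[, c("total_points", "probability", "risk")]
#> # A tibble: 1 × 3
#>   total_points probability risk
#>          <dbl>       <dbl> <chr>
#> 1         93.7       0.833 high
```

The patient's values earn 93.7 of a possible 211.8 points, which the
probability scale converts to a risk of 0.8328 — identical to plugging the
values into the logistic formula (sigmoid(1.6055)) — and the risk exceeds
the 0.5243 threshold, so the patient is classified high-risk. (The point
breakdown depends on the predictor ranges chosen for the axes; the
probability does not.)

`render_nomogram(nomo, "cmv.svg")` draws the chart (SVG/PNG/PDF;
`autoplot(nomo)` gives the ggplot). A command-line wrapper covers the same
workflows:

```sh
Rscript inst/cli/nomogram.R build inst/extdata/cmv_model.csv -o cmv.svg
Rscript inst/cli/nomogram.R eval inst/extdata/cmv_model.csv --values 50,1,1,14,7
Rscript inst/cli/nomogram.R simulate inst/extdata/cmv_model.csv --n 200 --granularity 10 --seed 7
Rscript inst/cli/nomogram.R validate inst/extdata/cmv_model.csv
```

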