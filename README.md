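# caalrisk

Interpretable cross-attention risk classification for student
mental-health cohorts.

## The problem

Screening tools for student mental health must do two things at once:
predict a three-level risk category (Low / Medium / High) from a small
set of psychological, behavioral and demographic survey features, and
*explain* each prediction well enough that a counselor can act on it.
Linear models are legible but miss feature interactions (anxiety and
depression reinforce each other; low productivity means something
different when anxiety is high); black-box deep models capture the
interactions but hide the reasoning.

`caalrisk` implements a hybrid tabular classifier that is nonlinear
*and* intrinsically interpretable, together with the full evaluation
pipeline around it: entropy-based feature screening, LIME-style local
surrogates with quality metrics, calibration and uncertainty
diagnostics, a five-test statistical validation battery, an ablation
ladder of six architecture variants, and a synthetic cohort generator
with planted ground truth.

## The model

Each of the m = 10 features x_i is tokenized by a learned per-feature
affine map into a d-dimensional token. The model then runs two branches
and fuses them:

* **Feature attention** (FT-Transformer style): multi-head
  self-attention over the feature tokens,
  `A_T = softmax((xW_Q)(xW_K)^T / sqrt(d)) (xW_V)`,
  with residual and feed-forward sublayers, capturing which features
  interact.
* **Ordered-sequence LSTM**: features are ordered
  Emotional -> Behavioral -> Demographic, position-encoded by the
  scalar addend `sin(i / 10^(2i/d))`, and read by an LSTM whose final
  hidden state `h_T` summarizes the sequence,
  `h_T = LSTM(x_PE)`.
* **Cross-Attention Attribution Layer (CAAL)**: per head, each feature
  token is scored against the LSTM summary,
  `A_C = softmax((A_T W_F) (h_T W_L)^T)`,
  giving a simplex of per-feature attribution weights that both selects
  the context vector fed to the softmax risk head,
  `y_hat = softmax(Z W_O + b_O)`, and *is* the explanation.
* **Loss**: cross-entropy plus `lambda_xai` times the mean Shannon
  entropy of the attribution heads, a sharpness penalty that keeps the
  attribution concentrated and readable.

Ablation variants E1 (LSTM only) through E6 (full model) share one
training harness, so each architectural addition can be measured in
isolation.

## Worked example

```r
library(caalrisk)

# 1. a synthetic cohort of 2,000 student records with planted signal
cohort <- generate_cohort(generator_spec(n = 2000, seed = 1))
cohort <- order_features(cohort, "order3")
split  <- stratified_split(cohort, test_fraction = 0.2, seed = 1)
train  <- normalize_cohort(impute_and_encode(split$train))
test   <- normalize_cohort(impute_and_encode(split$test, medians = train$medians),
                           stats = train$norm_stats)

# 2. entropy screening on the training split
head(entropy_report(train), 4)
#>                       feature marginal_entropy conditional_entropy      mark
#> anxiety               anxiety         3.321914           0.6821501 uncertain
#> depression         depression         3.321926           0.6792229 uncertain
#> stress_level     stress_level         3.321920           1.3464403 uncertain
#> social_support social_support         3.321920           1.5113562 uncertain

# 3. train the full hybrid model (E6) and evaluate
model <- train_caal(build_variant("E6", caal_config(seed = 1)), train, test)
model
#> <caal_model E6: 10 features -> 3 classes, d=16, 45,539 params, trained>
metrics <- compute_metrics(test$data$risk_label, predict(model, test))
round(c(accuracy = metrics$accuracy, macro_f1 = metrics$macro_f1), 3)
#> accuracy macro_f1
#>    0.877    0.879

# 4. global attribution from the cross-attention layer
head(caal_attribution(model, test), 3)
#>      feature      score
#> 1    anxiety 0.44356859
#> 2 depression 0.44178440
#> 3 employment 0.06681409

# 5. a local explanation for one held-out student
lime_explain(model, split$test$data[7, ], seed = 1)
#> <explanation: R2 = 0.215, C+ = 0.149, C- = -1.124>
#>        feature       weight sign
#> 1      anxiety -0.051163715    -
#> 2   depression -0.021042612    -
#> 3  sleep_hours -0.016848721    -
#> 4 productivity  0.012349213    +
#> 5          age  0.001776479    +
```

The entropy screen ranks anxiety and depression as the most predictive
features (lowest conditional entropy, about 0.68 bits against a
1.58-bit label); the trained model reaches 87.7% test accuracy on this
noisy-label cohort, and its attribution map concentrates 89% of its
mass on the two planted emotional scales — the global and local views
agree with the generative ground truth. For this low-risk student the
local surrogate reads below-average anxiety and depression as the
factors holding risk down (negative weights toward the predicted
class's risk).

## Command line

A thin CLI over the same functions is installed under the package's
`exec/` directory:

```sh
caalrisk simulate --n 2000 --seed 1 --out cohort.csv --truth truth.json
caalrisk train    --data cohort.csv --variant E6 --seed 7 --out model.json
caalrisk evaluate --model model.json --data test.csv
caalrisk stats    --model model.json --data test.csv --out battery.csv
caalrisk explain  --model model.json --data test.csv --row 17
```

Model checkpoints are plain JSON (config, parameter arrays,
normalization statistics and category dictionaries), so encodings stay
stable across runs and machines.

## Scope

The package's synthetic generator plants known structure so that every
claim the pipeline makes — signal recovery, attribution faithfulness,
capacity separation, calibration — can be checked against ground truth.
It makes no claim of clinical validity on real cohorts; see the methods
vignette (`vignettes/caalrisk-methods.Rmd`) for the model's assumptions
and limitations.
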