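# fptree — fuzzy probability trees for interpretable clinical prediction

Clinicians weighing a diagnosis rarely get to treat a 48-year-old as
categorically different from a 51-year-old, or an 18 mm thyroid nodule as
categorically different from a 20 mm one — yet models built on crisp
thresholds do exactly that. `fptree` implements **fuzzy probability trees
(FPT)**: discrete probability trees induced from tabular patient records
over an expert-chosen feature order, extended with fuzzy linguistic
variables so that prediction traverses *all* matching branches weighted by
membership degrees instead of committing to one crisp path. The package is
aimed at biostatisticians and clinical-decision-support developers who need
fully inspectable models: every prediction decomposes into named conditions,
empirical transition probabilities and explicit membership weights.

## The model in brief

A probability tree node is a tuple $n = (w, \mathcal{S}, \mathcal{C})$ —
identifier, statements "X IS v", and ordered transitions $(\theta, m)$ with
$\theta_{w,m} = P(S_m \mid S_w)$ estimated as the empirical conditional
relative frequency. A total realization (root-to-leaf path) has probability
$\prod \theta$; events are Boolean combinations (¬, ∧, ∨) of statements
evaluated over realizations. For a fuzzy variable, a raw measurement $u$ is
converted to branch weights by piecewise-linear membership functions
$\mu(u) \in [0,1]$ (renormalized to sum to 1), and the prediction is the
membership-weighted average of the conditional class probabilities below
each branch — a convex combination of leaf class fractions, so the two class
probabilities always sum to 1. The predicted label is positive iff
$P(\text{positive}) \ge$ threshold (default 0.50, inclusive). Patients not
represented in the training data fall back to their largest represented
condition subset; removed variables are averaged uniformly over branches.
What-if queries substitute or remove conditions and re-traverse. A bootstrap
harness (stratified split, resampling with replacement, percentile 95% CIs
for accuracy/sensitivity/specificity/precision) evaluates models at any
threshold.

## Worked example

The package ships the worked demonstration as a generated fixture: a small
thyroid subtree (transition probabilities 1, 0.333, 0.667, 0.5, 0.5; benign
and malignant leaves) plus the demo patient — cytology TIR3B, female, age 48
years, no thyroiditis, no struma, nodule 18 mm.

```r
library(fptree)
fx <- make_demo_fixture()

predict(fx$model, fx$patient)        # fuzzy traversal
#> FPT prediction (threshold 0.50):
#>  prob_negative prob_positive label support
#>         0.5733        0.4267     0    2200

crisp_predict(fx$model, fx$patient)  # traditional crisp tree
#> FPT prediction (threshold 0.50):
#>  prob_negative prob_positive label support
#>              1             0     0     100
```

The crisp tree routes the patient down a single path (age 48 < 50, nodule
18 mm < 20 mm) into a pure benign leaf — probability 1, certainty that is an
artifact of the thresholds. The fuzzy traversal instead weights the age
branches 0.2/0.8 (a 48-year-old is mostly, but not entirely, in the 50-plus
group) and the nodule branches 0.2/0.8 (an 18 mm nodule is "large" to degree
0.80), yielding a weighted prediction of 0.4267 — the nuance the crisp model
discards. What-if queries re-traverse under edited evidence:

```r
counterfactual_query(fx$model,
  scenario(fx$patient, interventions = list(nodule_mm = 25)))
#> Counterfactual query
#>   set:   nodule_mm = 25
#>   factual : P(positive) = 0.4267  [label 0, support 2200]
#>   scenario: P(positive) = 0.4000  [label 0, support 1100]
```

Synthetic cohort generators (`thyroid_cohort_spec()`, `ckd_cohort_spec()`)
emulate the two case-study schemas — 160 and 512 possible realizations —
with invented marginals and known generating rules, so every stage is
testable without clinical data; `bootstrap_evaluate()` scores any model
conforming to a two-line trainer contract. A command-line interface wraps it
all:

```sh
Rscript inst/cli/fpt.R simulate --cohort thyroid --n 401 --seed 1 --out cohort.csv
Rscript inst/cli/fpt.R build --data cohort.csv --config inst/extdata/thyroid_config.yaml --out model.json
Rscript inst/cli/fpt.R predict --model model.json --patients cohort.csv
Rscript inst/cli/fpt.R export-dot --model model.json --out tree.dot
```

See `vignettes/fuzzy-probability-trees.Rmd` for the full account of the
model, the five-case prediction recursion, fuzzy-set defaults, the
evaluation protocol, and known limitations.

## Acceptance script

`scripts/acceptance.R` rebuilds the demonstration fixture from scratch and
recomputes its three headline quantities — the membership-weighted fuzzy
prediction for the demo patient, the crisp benign-class probability on the
same patient, and the membership degree of an 18 mm nodule in the default
large-nodule set — writing them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
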