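---
title: "Fuzzy probability trees: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy probability trees: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fptree)
options(fptree.quiet = TRUE)
```

## The model

A **probability tree** organises a cohort of patient records along a fixed,
expert-chosen sequence of discrete features. Every node carries a statement
"variable IS value"; every arc carries the empirical conditional probability
$P(S_m \mid S_w) = \theta_{w,m}$ of the child's statement given the path so
far, estimated as a raw relative frequency from the training records. A
root-to-leaf path (a *total realization*) has probability equal to the
product of its arc probabilities, and leaves store the per-class counts of a
binary outcome. *Events* — possibly composite propositions built with
negation, conjunction and disjunction — select sets of realizations and are
assigned the summed probability of the selected paths.

Because the transition probabilities are raw frequencies, branches never seen
in training are simply absent, and each leaf's class fraction equals the
conditional class probability given the full path. No smoothing or
pseudo-counts are applied: the printed worked example contains probability-1
leaves, which only raw frequencies produce. Queries whose conditions match no
training record are signalled as unsupported rather than silently answered;
prediction then falls back to the largest represented subset of conditions
(below).

A **fuzzy probability tree (FPT)** leaves the tree untouched but changes how
a patient is routed through it. Selected numeric variables (age, nodule
dimension, laboratory values, ...) are modelled as linguistic variables: a
partition of fuzzy sets over the variable's universe of discourse, each set
given by a piecewise-linear membership function $\mu(u) \in [0,1]$. At a
fuzzy split, the traversal does not commit to one branch; it follows *every*
branch, weighting each by the patient's (renormalized) membership degree in
that branch's term. The prediction is therefore a convex combination of leaf
class fractions, and the two class probabilities always sum to 1.

## The prediction recursion

`fuzzy_predict()` implements the traversal as a five-case recursion:

1. **Leaf** — return the class fraction of the leaf counts.
2. **No statements left** — return the conditional class probability of the
   path so far (the subtree's class fraction).
3. **Matching child** — when the next statement names the variable the
   children split on: a crisp value routes with weight 1 to the single
   matching child; a raw numeric value for a fuzzy variable is converted to
   branch weights, renormalized over the branches present, and the weighted
   recursive results are summed.
4. **Unseen value** — the variable splits here but the stated value has no
   matching child: the recursion returns the $\theta$-weighted average over
   all children.
5. **Absent variable** — the patient carries no statement for the splitting
   variable: children are averaged with weight $1/|\text{children}|$.

Classification applies an inclusive threshold: the positive class is
predicted when its probability is **greater than or equal to** the cut-off
(default 0.50). The threshold is a clinical dial, not a fitted parameter:
raising it restricts positive calls to the more certain cases, e.g. under
capacity constraints.

When no path fully represents a patient, `find_existing_conditions()`
returns the largest subset of the patient's statements that *is* represented.
We resolve "largest" as an exact maximum-cardinality search over statement
subsets (at most $2^{10}$ for the tree depths in scope), tie-broken toward
retaining features earlier in the tree order; an order-respecting greedy scan
would also be consistent with the method's description, but the exact search
is what the phrase "largest set" literally asks for and is cheap at these
depths. Dropped variables are then handled by case 5 (uniform weighting)
rather than being silently ignored, so the output remains a proper
probability; the reported `support` counts the training records compatible
with the conditions actually used.

The crisp, traditional probability-tree prediction is the degenerate case of
the same machinery: each fuzzy variable is collapsed to the single term its
crisp threshold selects (values at or above the cut go to the rising set),
which equals running the fuzzy traversal with step membership functions. This
identity — step memberships make FPT and PT coincide exactly — is enforced by
a property test.

## Fuzzy set defaults and their rationale

Only piecewise-linear membership families are provided (ramps; trapezoids via
four knots): that is the family the method was demonstrated with, and linear
interpolation keeps every value's degree exactly computable. Outside the knot
range the membership clamps to its boundary value, so out-of-universe
measurements degrade gracefully instead of erroring.

The shipped default knots are *constrained by, not copied from*, the
published material, whose figures are not numeric: the large-nodule set rises
from 10 mm to 20 mm — so an 18 mm nodule is "large" to degree 0.80 and the
crisp cut at 20 mm coincides with full membership — and the over-50 age set
rises from 40 to 50 years, so a 48-year-old carries weights 0.2/0.8 across
the two age branches. With this orientation the crisp traversal of the demo
patient reaches the pure benign leaf (probability 1), reproducing the printed
crisp prediction, and the fuzzy traversal evaluates to 0.42672 (printed:
0.427). The published text calls 0.427 the *benign* probability while also
reporting a crisp benign probability of 1 for the same patient; since the
worked expansion's leaf indicators mark the positive-class leaves, the
package reports both class probabilities and treats 0.427 as the value of the
worked expansion (computed here for the positive class) without adjudicating
the label. Every knot is user-configurable; the chronic-kidney-disease
template ships placeholder knots at clinically conventional cut regions
(creatinine 1.5–3.5 mg/dL, hemoglobin 10–13 g/dL, potassium 4.5–5.5 mmol/L,
...) that an expert should replace, since the authoritative shapes live in
supplementary material not available here.

When only one set of a binary partition is declared, its complement
($1-\mu$) is generated automatically, so binary partitions always sum to 1;
arbitrary user partitions are renormalized to a partition of unity before
being used as traversal weights, because the traversal's convexity argument
needs weights summing to 1 and the worked example's weights do.

## Synthetic cohorts: what they emulate and what they do not

No clinical data are deposited, so the package carries generators that
emulate the two case studies' *schemas* with known generating rules:

* `thyroid_cohort_spec()` — a 5-level cytology class plus five binarized
  covariates (160 possible realizations; the published cohort of 401 records
  averages 2.51 records per realization), default prevalence 0.08, matching
  the epidemiological statement that some 5–10% of thyroid nodules are
  malignant.
* `ckd_cohort_spec()` — a 4-level GFR stage plus seven binarized covariates
  (512 realizations; 2599 records average 5.08 per realization), default
  prevalence 0.25 for 2-year progression to end-stage renal disease. The
  published tables' sensitivity/precision around 56% at threshold 0.5 are
  consistent with a positive fraction in the 0.2–0.3 range; 0.25 was fixed
  once and not revisited.

Features are drawn **independently** from invented marginals, and the
outcome is Bernoulli with a stratum risk (growing with cytology class or GFR
stage and with the fuzzy memberships of the continuous drivers) rescaled so
the mean risk equals the requested prevalence. Independence is deliberate:
it makes every transition probability analytically equal to the child's
marginal, which is what the parameter-recovery tests exploit. It also means
the generators do **not** emulate the real cohorts' joint structure
(comorbidity correlations, referral bias, the clumping of common patient
profiles), so a green test establishes correctness of the machinery on a
known world — not clinical performance. The published performance tables are
out of reach by construction and are not reproduced.

One sizing caveat worth recording: at 50,000 records a balanced shallow
schema recovers every transition probability to within 0.02 (deepest branch
points hold thousands of records, standard errors around 0.006), but the
full 6-feature thyroid schema cannot meet that bound at that size — its
rarest strata hold tens of records, with sampling errors an order of
magnitude larger. The absolute recovery check therefore runs on a balanced
3-feature cohort, and the thyroid-schema check asserts convergence (error
shrinking from 1k to 50k records) instead.

## Evaluation protocol

`bootstrap_evaluate()` follows the protocol of the case studies where it is
stated and fills the gaps as follows: the data are split **once** into
stratified train/test partitions (proportions preserved to within one record
per class); each replicate resamples the *training* partition with
replacement, refits the tree, and scores the fixed test partition at the
given threshold; accuracy, sensitivity, specificity and precision are
reported as means with 2.5/97.5 percentile intervals across replicates.
Whether the original work refit trees per replicate or resampled predictions
is not stated; refitting is the simplest protocol consistent with "split
first, then bootstrap" and is documented as our choice, not the authors'.
Replicates that lose a class are skipped and counted; ratios with zero
denominators are flagged undefined and excluded per metric. Note that a
percentile interval estimates the metric's sampling spread — it stabilises
as replicates grow rather than shrinking, which is also why the published
intervals are wide. All randomness flows from one master seed through a
counter-based substream per replicate, so reports are bit-reproducible.
Baselines (logistic regression, decision trees) are not reimplemented; any
callable obeying the trainer contract (`function(train) -> function(test) ->
probabilities`) plugs into the same harness.

## Counterfactual semantics

`counterfactual_query()` implements what-if questions ("what if this patient
had taken RASI medication?") as **condition substitution and re-traversal**:
the intervened statements replace same-variable evidence, removed variables
become unknown (uniform branch weighting), and factual and scenario
probabilities are returned side by side. This is observational
re-conditioning, not structural counterfactual inference with exogenous
noise; the published examples are exactly substitution-style queries, and
whether they intend do-style semantics is not resolvable from the text. The
distinction matters: on these trees, substituting a condition equals direct
conditioning on the altered statement set, which the tests assert.

## Numerical choices and degenerate inputs

* Probabilities are kept as exact double ratios of counts; invariant checks
  (realization probabilities summing to 1, class probabilities summing to 1)
  are tested at tolerance 1e-9.
* Child ordering is the sorted order of child statement values — a
  determinism convention for serialization and traversal, not part of the
  method's description.
* A constant feature induces a degenerate single-branch level and is legal;
  an empty record set, unknown feature names, and missing values are errors
  (only complete profiles train the tree).
* A patient with *no* represented condition receives the class prior with a
  warning rather than an error.
* Recursion depth equals the feature count (≤ ~10 in scope), so plain
  recursion is safe.
* Model files are JSON with full-precision numbers; round-trips are
  lossless, and DOT exports print arc probabilities to 3 decimals.

## Known limitations

Binary targets only (the published method states multi-class support as
future work); fixed expert feature order with no structure learning or
feature selection; piecewise-linear memberships only; no probability
calibration or ROC analysis; counterfactuals are re-conditioning, as above.
The graphical user interface of the original tool is out of scope — the
functions, the `inst/cli/fpt.R` command-line script, and this vignette are
the interface.

## A worked run

```{r demo}
fx <- make_demo_fixture()
fx$patient

# membership-weighted traversal vs the crisp single path
predict(fx$model, fx$patient)
crisp_predict(fx$model, fx$patient)

# a what-if: the same patient with a 25 mm nodule
counterfactual_query(fx$model,
  scenario(fx$patient, interventions = list(nodule_mm = 25)))
```
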