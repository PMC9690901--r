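---
title: "Methods: extraction contract, synthetic generators and the Division-of-Labor system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extraction contract, synthetic generators and the Division-of-Labor system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodss)
```

This vignette is the package's own account of its models and design
choices: what is computed, under which assumptions, which parameters matter,
and what the synthetic data can and cannot show.

## 1. Rule-based extraction

### The regex models

Colorectal pathology findings state their staging in a compact formula
(e.g. `ypT3 ypN1a (2/25) L1 V0 R0 M0`) whose tokens come from closed value
domains: T ∈ {is, 0–4, 4a, 4b, X}, N ∈ {0, 1, 1a–1c, 2, 2a, 2b, X},
M ∈ {0, 1, 1a–1c, X}, L ∈ {0, 1, X}, V ∈ {0, 1, 2, X}, R ∈ {0, 1, 2, X}.
The extraction patterns are *generated from these domains* rather than
hand-tuned: each pattern is the feature letter followed by an alternation of
its admissible values (longest alternatives first, so `4a` is never
truncated to `4`), with optional clinical prefixes `c`, `p`, `r`, `y`, `yp`
before T/N/M, token-boundary lookarounds on both sides, and case-insensitive
matching. Deriving patterns from the domain keeps sensitivity high while
excluding nonsense values by construction; `feature_specs()` exposes the
compiled sources.

The lymph-node counts are read from a parenthetical fraction
`(affected/removed)` printed after the N value — so X2 is the numerator and
X1 the denominator — with a standalone `a/b Lymphknoten` phrasing accepted
as fallback. The fraction format is a pathology convention, not a printed
standard; it is therefore isolated in two patterns that can be revised
independently.

ICD-10 localization matches `C` codes and discards everything outside the
digestive range [C17.0, C22.1] *before* the class decision: findings may
legitimately cite out-of-scope codes (metastasis sites), and those must not
create spurious ambiguity. A surviving code is mapped to its localization
term through a versioned CSV table bundled under `inst/extdata/`; a code in
range but absent from the table is still returned, flagged `term_unmapped`,
because term mapping is best-effort display metadata, not extraction.

### The three-class contract

Every extractor returns one of three classes per feature:

* **concrete** — exactly one *distinct* matched value. Repeated identical
  mentions (`pT3 … pT3`) are a restatement, not a conflict, and stay
  concrete; "different values" is read as distinct values.
* **ambiguous** — two or more distinct values. The value is withheld and
  the document is queued for expert validation; all contributing spans are
  kept for highlighting.
* **empty** — zero hits, or a matched X for M, L, V, R (those findings
  state that no assessment was possible). The X-derived empty keeps its
  span as provenance and is *not* flagged for validation: it is a correct,
  complete answer. For T and N, X is an ordinary concrete value, because
  the no-statement reading is specific to M/L/V/R.

When an X co-occurs with a distinct non-X value for the same feature, the
result is ambiguous, not empty: the document contradicts itself and a human
must arbitrate. This preserves the invariant that adding a conflicting
mention can never produce a concrete result.

Provenance is recorded as 1-based character offsets into the ingested text.
The original deployment traced results back to scan pixels; OCR is out of
scope here, and offsets serve the same traceability contract for text
input.

### The neoadjuvant classifier

Neoadjuvant-therapy status has no fixed token, so it is extracted by
L1-regularized logistic regression over a bag-of-words frequency matrix.
The tokenizer lower-cases, splits on non-letter characters and drops tokens
shorter than two characters; raw counts are used (no tf-idf), matching the
frequency-matrix formulation as literally as possible. The lasso penalty
(`l1_strength`, default 0.01 on the glmnet lambda scale) keeps the model
sparse enough that the decisive tokens can be read off the weights; at very
large penalties the model provably collapses to the intercept-only prior.
The returned certainty is the probability of the *predicted* class
(max of the two class probabilities), read as confidence in the shown
result, and is banded green (p ≥ 0.95), yellow (p ≥ 0.90) or red
(p < 0.90), both thresholds inclusive on the more-confident side. Red
results are flagged for validation by default; yellow flagging is available
behind `flag_yellow = TRUE` because the conservative reading is to prompt
only when a result is genuinely too uncertain.

### Feedback

Expert corrections append to a persistent store; the neoadjuvant model is
then retrained *from scratch* on the original corpus plus the accumulated
store. Incremental updates would be faster but order-dependent; full
retraining is deterministic and reproducible, which matters more at this
corpus scale. Rule-based features are never auto-modified by feedback —
silent rule drift would break auditability — corrections to them only
accumulate per-feature discrepancy statistics for human rule revision.

## 2. Evaluation semantics

Per feature, an extraction is correct iff it is concrete and equal to the
truth, with the X-derived empty counting as correct when the truth itself
is X (for M/L/V/R). Ambiguous results and empties-with-truth-present count
as incorrect, so the automated accuracy is penalized for everything it
hands to the expert. At the document level the three outcomes are disjoint:
**true** (all features correct), **ambiguous** (any feature ambiguous —
this takes precedence over plain errors, because such documents are routed
to validation rather than silently wrong), else **false**. Complete-data
accuracy is true/total. No statistical inference is attached to the
accuracies.

## 3. The synthetic finding generator

The generator emulates the *structure* of resected-colorectal pathology
findings: slot-wise narrative filler (clinical information, macroscopy,
microscopy, assessment) interleaved with a neoadjuvant-status sentence, an
ICD-10 localization line and the TNM formula line. Truths are drawn from
the value domains with weights typical of a resected cohort (mostly T2/T3,
node-negative, M0, R0; X at a few percent for M/L/V/R); X1 is 8–40 removed
nodes and X2 respects both X1 and node-negativity; the neoadjuvant
prevalence defaults to 0.30, and neoadjuvant findings get the `yp` prefix.
Narrative sentences are linted at test time against every extraction
pattern, so clean-corpus accuracy measures the rules, not template luck.

Controlled imperfections reproduce the contract's failure modes, applied
independently per document at configured rates and always logged:
`conflicting_duplicate` (a second, different-valued mention appended),
`omission` (all mentions of a feature deleted), `x_value` (value replaced
by X; only legal for M/L/V/R), and `ocr_noise` (per-character substitution,
by default sparing the truth-critical tokens so robustness testing is
separable from contract testing).

What the generator does *not* emulate: real report layout variability,
scanner artifacts, genuine OCR error models, or the long-tail phrasing of
dictated findings. No real finding text was available to validate template
realism against, so passing tests demonstrate correctness of the contract
and patterns on well-formed findings — not field performance on arbitrary
hospital documents.

## 4. The synthetic cohort generator

The cohort emulates a registry analysis view: 38 pre-treatment attributes
(8 numeric, 30 categorical) and 6 binary therapy decisions (therapy
intention — encoded positive = curative —, operation, radiation, local
chemotherapy, systemic chemotherapy, other therapy). The categorical
cardinalities are a fixed fixture whose only engineered property is that
one-hot expansion plus the numeric pass-throughs yields exactly 160 encoded
features, the one dimensional constraint the setting provides.

Latent structure: each patient draws one of `n_segments` (default 3)
segments; numeric attributes are segment-shifted normals
(`segment_shift = 1.5` standard deviations, mapped onto clinical units)
and categoricals are segment-tilted multinomials (`segment_tilt = 4` on
each segment's preferred category). At these defaults a plain k-means on
the encoded matrix recovers the generator segments with adjusted Rand
index above 0.8 (typically ≈ 0.99 at n = 2000) — the documented
precondition for the Division-of-Labor system to have anything to exploit.

Decisions come from logistic rules over the one-hot columns of three rule
attributes (`t_classification`, `n_classification`, `clinical_state`) with
*independent segment-specific coefficients* (standard deviation
`effect_size = 2`): a pooled model is misspecified by construction, which
is exactly the regime in which per-segment Experts can win. The intercept
of each rule is calibrated by root finding so the expected prevalence hits
its target; defaults are 0.92 for operation and 0.02 for other therapy (the
stated registry imbalances) and minority-positive values for the remaining
four (0.35 intention, 0.30 radiation, 0.05 local, 0.25 systemic), chosen
once as plausible for a mixed head-and-neck cohort and so that the prior
classifier's characteristic zeros appear on those tasks. Missingness is
MCAR at `missing_rate = 0.1` — the mechanism is unspecified in the setting,
and MCAR is the minimal choice compatible with testing the
smallest-input-set behavior. Real attribute distributions and
inter-attribute correlations are unpublishable patient data; no claim of
distributional realism is made.

## 5. Encoding

One-hot expansion for categoricals (row-sum 1 when observed, all-zero
block when missing), numeric standardization by *training-set* statistics
with missing numerics imputed at the training mean (0 after
standardization). The column map is invertible to (attribute, category),
which is what makes attribute-level importance aggregation well-defined.
An all-missing patient encodes to the zero vector — a legal input by
design, so the decision-support system is total.

## 6. The Division-of-Labor system

* **Segmentation** — seeded k-means (`nstart = 5`) on the encoded matrix;
  `n_segments` from config (default 3), or `"auto"` selecting by mean
  silhouette over 2–6 (computed on a deterministic subsample of up to 400
  rows). Centroid clustering is the minimal concrete reading of "a
  clustering algorithm".
* **Routing** — Euclidean distance to centroids; ties break to the lowest
  segment id. Nearest-centroid is the minimal consistent reading of "most
  suitable Expert".
* **Experts, classification task** — one online logistic classifier per
  decision: stochastic-gradient updates of the L2-regularized logistic
  loss, one pass in stream (data) order, learning rate
  `eta_t = eta0 / (1 + eta0 * lambda * t)` with `eta0 = 0.5`,
  `lambda = 1e-4`, and `t` the Expert-local update count. With one segment
  the system reproduces, bit for bit, the standalone online model trained
  on the same stream (a tested invariant). An Expert that saw (essentially)
  one class of a decision falls back to a Laplace-smoothed prior for it.
* **Experts, importance task** — per decision, a lasso logistic fit on the
  Expert's accumulated data, penalty chosen by internal 3-fold CV with a
  deterministic fold assignment; when the minority class has fewer than 30
  samples the CV folds become unreliable and a fixed moderate penalty
  (lambda = 0.01) is used instead; below 3 minority samples there is no
  signal to extract and the coefficient vector is zero. The refresh happens
  once after the stream — refitting the lasso at every update would change
  nothing statistically and cost a factor of n.
* **Importance aggregation** — |coefficients| summed over an attribute's
  encoded columns, averaged over Experts weighted by their sample counts;
  "overall" averages the six per-decision profiles weighted by per-task
  sample counts. With complete labels all tasks share one sample count, so
  the default weights are equal; `overall_weighting = "positives"` switches
  to positive-sample weights, since the phrase "samples in the respective
  test sets" admits both readings. Only the *ranking* is meaningful; the
  score scale is not calibrated to any external reference.

## 7. The benchmark

Outer 10-fold cross-validation (90/10) per decision; encoding statistics
are refitted on each training fold. Hyper-parameters are tuned by an inner
3-fold grid search on the training fold, for the Division-of-Labor arm by
wrapping the whole cluster-then-fit pipeline inside the inner folds. Grids:
lasso and online-logistic penalties over 6 log-spaced values (10^-3 … 10^0),
tree depth 2–10 (CART via rpart), linear SVM cost over 5 log-spaced values
(10^-2 … 10^2). The linear probability model is an unpenalized least-squares
fit thresholded at 0.5, the lasso classifier a gaussian lasso regressor
thresholded at 0.5, the prior classifier the training-fold majority, and
the random guesser a fair coin (no DoL arm — wrapping it is vacuous).

F1 is computed for the positive class on the *pooled* outer test
predictions, with the convention F1 = 0 when positives exist but no
positive prediction was made — required so the majority-negative prior
classifier scores its characteristic zeros — and vacuously 1 when neither
exists; single-class test folds are logged on the result. Two analytic
oracles pin the harness down: the prior classifier on a majority-positive
task of prevalence q scores 2q/(1+q) (all-positive predictor: precision q,
recall 1), and the uniform guesser scores q/(q+0.5) in expectation
(precision q, recall 1/2). The overall column is the task-weighted mean
described above. A deep-network baseline is deliberately absent: at these
sample sizes it has no support and its architecture is unconstrained.

## 8. Problem sizes, determinism, degenerate inputs

Test and acceptance runs use 250–500 findings for extraction studies and
cohorts of 600–2000 patients with 10 outer / 3 inner folds — sizes chosen
to match the emulated studies (430 findings; a few thousand registry
records) while keeping a full run on one CPU comfortable. Every stochastic
step (generation, clustering, fold assignment, SGD stream order, guessing)
derives from explicit seeds via a fixed fan-out (`derive_seed()`), and
bit-for-bit reproducibility under a fixed seed is itself a tested property.
Degenerate inputs are defined behavior throughout: empty text extracts
all-empty, an all-missing patient predicts from priors, a single-class
training set falls back to the prior, and a one-segment system equals its
base model.

## 9. Known limitations

* Pattern equivalence with any particular deployed extraction system
  cannot be established — original pattern sources are not public; only
  the value-domain derivation is reproduced.
* Template realism is unvalidated against real findings (none are
  available); clean-corpus accuracies near 100% certify the contract, not
  clinical field performance.
* The cohort generator's segment structure is favorable to
  divide-and-conquer by construction; the benchmark ordering (DoL beating
  its standalone base model) is a property of that regime, and the printed
  magnitudes of any external study are not reproduced.
* Only the colorectal TNM domain tables ship; the domain layer is
  pluggable but untested for other entities.
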