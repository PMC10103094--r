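---
title: "Estimating drug effects on hospitalization from EHR snapshots: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating drug effects on hospitalization from EHR snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

`ehrcausal` emulates target trials of drug exposure on a binary
hospitalization outcome using observational EHR snapshots in an
OMOP-like layout: a person table (demographics, 3-digit zip, days of
pre-index history), a code-event table of pre-index diagnosis concepts,
a drug-exposure table, and a 5-level severity score per person.

For a treated cohort and a comparator cohort, the estimand is the
average treatment effect (ATE) on hospitalization,

$$\widehat{\mathrm{ATE}}_{\text{unadj}} =
  \frac{1}{n_T}\sum_{i \in T} h_i - \frac{1}{n_C}\sum_{i \in C} h_i,$$

where $h_i \in \{0, 1\}$ is the hospitalization outcome. Because
exposure is not randomized, the package's central estimator reweights
each person by the inverse of their propensity score
$p_i = p(\text{treated} \mid \text{health history, demographics})$,
using the Hajek (normalized) form

$$\widehat{\mathrm{ATE}}_{\text{IPTW}} =
  \frac{\sum_{i \in T} h_i / p_i}{\sum_{i \in T} 1 / p_i} -
  \frac{\sum_{i \in C} h_i / (1 - p_i)}{\sum_{i \in C} 1 / (1 - p_i)}.$$

The Hajek form was chosen over Horvitz–Thompson (available via
`normalize = FALSE`) because the self-normalization cancels weight-scale
noise and is markedly more stable in finite samples; with all-equal
weights it reduces *exactly* to the unadjusted contrast, a property the
test suite asserts to machine precision.

## Three cohort designs

* **User versus nonuser** (`build_nonuser_cohorts()`): users of one
  drug against persons using none of the retained study drugs. The
  "clean comparator" is a deliberate design choice: the looser literal
  reading — everyone not using *this* drug — lets users of same-class
  drugs contaminate the null arm; that variant remains available via
  `comparator = "drug_only"`.
* **Any drug versus none** (`build_any_drug_cohorts()`): the pooled
  exposure contrast; the two arms partition the eligible population.
* **Active comparator** (`build_active_comparator_cohorts()`): users of
  drug A against users of drug B, dual users excluded from both arms
  (the package assumes exclusion; the sources it follows are silent on
  dual users, and exclusion is the standard practice). The
  full grid is assembled by `comparator_matrix()`; since every cell
  refits its own propensity model, `ate(A,B)` and `-ate(B,A)` agree
  only approximately, and the gap is reported as a diagnostic rather
  than forced to zero.

Eligibility is age strictly over 13 years, at least 365 days of
pre-index history, and a non-missing 3-digit zip. The 5-level severity
score is binarized as levels 3–5 (the hospitalized levels) versus 1–2,
with a missing score counted as nonhospitalized on the grounds that a
hospitalization would have been recorded. Drugs are retained when their
distinct-user count strictly exceeds `min_users`; the full-scale rule
of 5000 users scales down to a default of 50 for desk-size synthetic
populations.

## Two confounder representations

**One-hot.** `build_vocabulary()` assigns one key per distinct concept
code plus one per observed demographic level (10-year age bins, gender,
race, ethnicity, zip3). Rows are binary *presence* indicators —
occurrence counts sit behind a flag — because the high-dimensional
sparse design is meant to encode "which conditions has this person
ever had", not utilization intensity.

**Averaged embeddings.** `train_embeddings()` learns one vector per
concept from uniform random walks over the concept graph with
skip-gram and negative sampling (the $p=q=1$ special case of node2vec;
biased walks are an extension hook, since only the consumption path of
the embeddings is load-bearing here). A patient vector is the
unweighted mean of their *distinct* codes' vectors — the code list is
treated as a set, with multiplicity weighting behind a flag — and
codes without an embedding are dropped (patients with no representable
code are excluded and counted). Because the propensity model should
condition on the same confounder set in both representations, the
embedding design appends one-hot demographics and a numeric age column
to the $d$-dimensional average.

The default embedding dimension is 128, matching the dimension of the
pretrained clinical concept embeddings this representation emulates;
the bundled analyses use $d = 16$ on the 500-code synthetic ontology,
where extra dimensions buy nothing. Walk hyperparameters (10 walks per
node of length 40, window 5, 5 negatives, 3 epochs) are conventional
word2vec-scale defaults, not reconstructions of any published setting;
the source embeddings' training recipe is not recoverable beyond its
dimension.

## Propensity models

* **Sparse logistic regression** (`family = "lr"`) for the one-hot
  design: L1-penalized, on the raw binary columns without
  standardization.
* **Probability random forest** (`family = "rf"`) for the dense
  embedding design, where a single unpenalized linear fit is a poor
  match: 200 trees, unbounded depth, minimum node size 100, grown
  single-threaded under a seed so fits are reproducible.

Two numerical choices here deserve their rationale:

* **Penalty selection targets balance, not deviance.** The L1 penalty
  is chosen from a small fixed grid (`0.01, 0.003, 0.001, 3e-4, 1e-4`)
  as the value whose clipped weights minimize the post-weighting
  maximum absolute standardized mean difference. Selecting by held-out
  log-loss (available as `selection = "cv"`) systematically prefers
  stronger shrinkage, and a shrunken propensity model under-adjusts —
  it predicts well but leaves residual confounding on the ATE scale.
  With balance-based selection the recovery tests find the weighted
  estimate within 0.02 of the potential-outcome oracle in every tested
  seed at $n = 20{,}000$. The weights exist to balance confounders, so
  balance is the selection target.
* **Training-sample forest scores are out-of-bag.** When scores are
  needed for the same persons the forest was fitted on
  (`predict_propensity(fit)` with no new matrix), each person is
  scored only by trees that did not see them. In-sample forest scores
  leak the person's own label into their weight and bias the weighted
  estimate even under randomized assignment; out-of-bag scores remove
  the leak, and the larger minimum node size keeps the per-person
  probability estimates smooth enough that their reciprocals do not
  blow up the weights.

Positivity is enforced by symmetric clipping of scores into
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.01$ (configurable).
Weights are the unstabilized $1/p_i$ and $1/(1-p_i)$; normalization
happens inside the Hajek estimator.

## Bootstrap inference

CIs come from a stratified nonparametric bootstrap
(`bootstrap_ate()`): each of $B = 100$ replicates resamples persons
with replacement *within each arm* (preserving arm sizes), refits the
propensity model on the resample, recomputes weights, and re-estimates
the ATE; the 95% CI is the 2.5/97.5 percentile interval of the
replicate estimates, taken with the $(B+1)$ order-statistic convention
(`quantile` type 6), since at $B = 100$ the default interpolated
quantiles are visibly anti-conservative. Refitting per
replicate is mandatory for reported intervals — the model-fitting
variability belongs inside the CI — with two reductions that keep the
replicates affordable: the L1 penalty is selected once on the full
sample and then held fixed, and the coordinate-descent threshold can be
relaxed (`thresh = 1e-5`), which has a negligible effect on the
weighted estimate relative to its sampling noise.

A sign-count p-value over 100 replicates cannot resolve below its
floor of $2/(B+1) \approx 0.02$, so two p-values are reported:
`p_sign`, the continuity-corrected two-sided sign count, and
`p_normal`, a normal approximation from the bootstrap standard error,
which is the headline `p_value`. This is the package's reconciliation
of a 100-replicate bootstrap with the sub-0.001 p-values such analyses
conventionally quote.

## Negative-control outcomes

`negative_control_suite()` reruns the identical pipeline with each
designated control code as the outcome (presence of the code in the
person's history), excluding that code from its own confounder
vocabulary — conditioning on the outcome would itself induce bias. The
synthetic generator plants five control codes drawn independently of
everything, so their true effect is exactly zero; a pipeline whose
control intervals stray from zero is exhibiting residual bias. A
control with degenerate prevalence in the cohort is reported as
inestimable rather than thrown.

## The synthetic generator as testing instrument

`generate_population()` draws, per person, latent health factors
$z \sim N(0, I_3)$ that drive everything:

* concept codes load on one factor each (contiguous subtree blocks of
  the ontology), with occurrence probability
  $\mathrm{logit}^{-1}(-2.2 + u_j + 1.5\, z_f)$, $u_j$ a per-code
  jitter;
* every drug shares the assignment model
  $\mathrm{logit}^{-1}(-3.9 + u_d + 0.3 z_1 + 0.3 z_2)$; "treated"
  means using any study drug;
* potential outcomes share one uniform draw per person:
  $y_0 = \mathbf{1}\{u_i < \mathrm{logit}^{-1}(\alpha + z^\top\beta)\}$
  and $y_1$ likewise with the treatment effect (default $-0.5$
  log-odds) added, $\beta = (1, 1, 0.5)$, and $\alpha$ calibrated so
  the untreated hospitalization rate is 0.20. The shared draw makes
  $y_1 = y_0$ exactly under a null effect and makes the finite-sample
  true ATE, `true_ate()`, an exact oracle;
* age and gender are correlated with $z$ (true demographic
  confounders); 30% of nonhospitalized persons lack a severity score;
  3% lack a zip and 10% have under a year of history, so the
  eligibility filters are exercised.

The treatment and outcome models share two latent factors, so
confounding is real: at the reference size ($n = 20{,}000$, 500 codes)
the unadjusted ATE is biased by about $+0.07$ — comfortably beyond the
0.05 the recovery tests require — while the one-hot IPTW estimate lands
within 0.02 of the oracle.

What the generator does *not* emulate: realistic disease co-occurrence,
code frequencies, OMOP vocabulary identifiers, time-varying exposure,
or informative missingness. Passing tests therefore demonstrate that
the estimators recover known effects under the stated generative model,
not that they would be unbiased on real claims data.

## Problem sizes in the bundled tests and analyses

The test suite runs the recovery study at $n = 20{,}000$ with 500 codes
over 20 seeds; bootstrap coverage at $n = 5{,}000$ over 40 simulation
replicates with $B = 100$ (penalty fixed at $3 \times 10^{-4}$,
relaxed threshold — the reduced settings described above); and the
negative-control study at $n = 4{,}000$ with 150 codes over 10 seeds.
These sizes were chosen as the smallest at which the asserted
properties hold with comfortable statistical margins; the numbered
scripts under `analysis/` run the same pipeline once at the reference
size and write their tables under `results/`.

## Known limitations

* The embedding path adjusts less sharply than the one-hot path: a
  16–128-dimensional average of code vectors discards code-level
  detail, and the forest propensity inherits that loss. On synthetic
  data this shows up as a small residual bias in confounded settings;
  the representation is provided as the comparison arm it is meant to
  be, not as the preferred estimator.
* Percentile intervals from 100 replicates are themselves noisy; the
  coverage test tolerates 33/40 rather than a sharp 95%.
* No survival modeling, dosing, duration, or multiple-testing
  correction across the comparator grid — per-cell intervals only.
* `true_ate()` is the finite-sample mean difference of the stored
  potential outcomes, not a super-population estimand; estimator bias
  is always measured against the realized cohort.
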