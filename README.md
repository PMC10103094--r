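# ehrcausal

Causal effect estimation for drug exposures on a binary hospitalization
outcome from OMOP-like electronic health record snapshots, by inverse
probability of treatment weighting (IPTW) with two complementary
confounder representations — built for epidemiologists and method
developers who want the full pipeline (cohorts, propensities, weights,
bootstrap, negative controls) testable against known ground truth.

## The method

Each analysis emulates a target trial: a treated cohort (users of a
drug, of any study drug, or of drug A) and a comparator cohort
(nonusers, or users of drug B). With `h_i ∈ {0,1}` the hospitalization
outcome, the package estimates the average treatment effect

```
ATE_unadj = mean(h_i | treated) − mean(h_i | comparator)
```

and its confounding-adjusted counterpart, the Hájek-normalized IPTW
estimator with propensity scores
`p_i = p(treated | health history, demographics)`:

```
ATE_IPTW = Σ_T (h_i/p_i) / Σ_T (1/p_i)  −  Σ_C (h_i/(1−p_i)) / Σ_C (1/(1−p_i))
```

The propensity is modeled two ways, deliberately different in what they
can express:

* **one-hot + sparse logistic regression** — every distinct diagnosis
  code and demographic level is one binary covariate (tens of
  thousands of columns at scale); an L1-penalized fit with the penalty
  chosen to minimize post-weighting covariate imbalance;
* **averaged concept embeddings + random forest** — node2vec-style
  vectors trained on the medical concept graph, averaged over each
  person's distinct codes (`v_i = mean_{c ∈ codes_i} e_c`), with
  demographics appended, fed to a probability forest scored out-of-bag.

95% CIs come from a stratified bootstrap that refits the propensity
model on every one of B = 100 replicates. Validity is checked with
negative-control outcomes (conditions causally unrelated to exposure
whose estimated effect should be null) and standardized-mean-difference
balance diagnostics.

Because real enclave EHR data cannot ship with a package, `ehrcausal`
includes a synthetic OMOP-like generator whose latent health state
drives code histories, demographics, exposure and outcome — with both
potential outcomes stored per person, so the true ATE of any cohort is
exactly computable (`true_ate()`) and estimator bias is measurable, not
assumed.

## Worked example

```r
library(ehrcausal)

cfg   <- sim_config(seed = 922)                      # 20,000 persons, 500 codes
graph <- generate_ontology(cfg$n_codes, seed = 922)
data  <- generate_population(graph, cfg)

eligible <- apply_eligibility(data$persons)          # age > 13, ≥1y history, valid zip
retained <- retain_common_drugs(data$exposures, 50)  # 16 drugs pass
pair     <- build_any_drug_cohorts(eligible, data$exposures, retained)

vocab <- build_vocabulary(data$code_events, data$persons)
dm    <- build_design_matrices(pair, "one_hot", data$persons,
                               data$code_events, vocab = vocab)
h     <- outcome_for(data$severities, dm$person_ids)

unadjusted_ate(h, dm$labels)                         #  0.0214
true_ate(data, dm$person_ids)                        # -0.0546

est <- bootstrap_ate(h, dm$labels, dm$x,
                     propensity_spec("lr", lambda = 3e-4, thresh = 1e-5),
                     B = 100, seed = 933)
est
#> <ate_estimate>  [one_hot_lr]
#>   ATE -0.0457  (95% CI -0.0584 to -0.0343; P = 1.9e-17; B = 100)
#>   n = 4924 treated / 12031 comparator
```

The raw contrast has the wrong sign (+0.021): sicker people are both
likelier to be treated and likelier to be hospitalized. Weighting by
the high-dimensional propensity recovers the protective truth (−0.046
against a stored potential-outcome ATE of −0.055), and the CI excludes
zero. The same run's five negative-control outcomes all retain the
null (see `analysis/04_negative_controls.R` output in
`results/04_negative_controls.csv`).

## The analysis workflow

The numbered scripts under `analysis/` run the full study once at the
reference size and write small tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generate the reference population (person-level tables go to `scratch/`) |
| `02_cohorts.R` | eligibility, drug retention, cohort construction, attrition table |
| `03_ate_user_vs_nonuser.R` | any-drug and 16 per-drug ATEs, unadjusted vs one-hot IPTW |
| `04_negative_controls.R` | the five null-outcome validations |
| `05_active_comparator.R` | head-to-head grid over a six-drug panel |
| `06_embedding_ate.R` | the embedding + random-forest arm of the comparison |

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

The methods vignette (`vignettes/iptw-ehr-methods.Rmd`) documents the
models, every tunable parameter, the generator's design, and the
numerical choices (penalty selection by balance, out-of-bag forest
scores, the (B+1) percentile convention, clipping at ε = 0.01).

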