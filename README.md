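# lynchtriage

Patient-facing Lynch syndrome risk triage, and the statistics to validate it.

Lynch syndrome (LS) is a hereditary mismatch-repair cancer predisposition.
Provider-facing prediction models estimate the probability that a person
carries an LS mutation from personal and family cancer history, and treat a
score ≥ 2.5% as clinically significant. Those models expect a provider to
choose the "affected side" of the family and to aggregate relatives into
first-/second-degree groups — tasks patients cannot be asked to do.

`lynchtriage` implements the patient-facing adaptation of that workflow and
the analytic-validity toolkit around it, for researchers building or
evaluating family-history triage tools:

* **Family-history model** — typed probands, relatives, diagnoses; per-side
  aggregation into risk-model predictors (`family_history()`,
  `aggregate_side()`), JSON/CSV serialization.
* **Skip-logic questionnaire engine** — declarative, validated question
  graphs with localization (en/es), timestamped sessions, compilation into
  family histories, exhaustive path enumeration, per-module timing, SNS-3
  numeracy scoring. The shipped inventory spans **2–46 questions**
  depending on answers.
* **Bilateral risk scoring** — config-driven logistic scoring
  (`score_bilateral()`): maternal and paternal scores, computational
  affected-side assignment (argmax, maternal tie-break), reported score
  $\max(p_m, p_p)$, inclusive 2.5% significance. Coefficients live in a
  versioned JSON file; the shipped set is a clearly labelled **synthetic
  stand-in**, not the published coefficients.
* **Eligibility router** — gate questions → randomized exposure to the LS
  score and a pluggable breast/ovarian screen → limited-family-history
  module (adoption, side knowledge, < 2 females over 45 on either side),
  with auditable seeds and a rendered report (`route()`).
* **Concordance analysis** — Lin's CCC with Lin's corrected asymptotic CI
  (bootstrap optional), zero-imputation of absent scores, threshold
  confusion counts, ≥ 5% discrepancy and ≥ 15% outlier flags, and CCC power
  analysis (`summarize_concordance()`, `ccc_power()`).
* **Synthetic cohorts** — seeded gold-standard families plus an
  overreport-biased misreport process, yielding paired scores with known
  ground truth (`generate_cohort()`, `build_paired_scores()`).

## Worked example

```r
library(lynchtriage)
co <- default_coefficients()   # synthetic stand-in set

fh <- family_history(
  proband("female", 35),
  list(relative("mother",  diagnoses = list(cancer_diagnosis("colorectal", 48))),
       relative("brother", diagnoses = list(cancer_diagnosis("colorectal", 42)))))

score_bilateral(fh, co)
#> <risk score> maternal 5.2% / paternal 2.9% -> maternal side, reported 5.2% (clinically significant)
```

The brother is unsided, so he raises both sides; the mother raises only the
maternal side, which wins the argmax and is reported. 5.2% ≥ 2.5%, so the
router qualifies this patient without exposing the limited-history module:

```r
out <- route(gate_answers(FALSE, TRUE), fh, co, rng_seed = 7)
cat(render_eligibility_report(out))
#> - Lynch syndrome risk score: 5.2% (maternal side)
#> - Breast/ovarian screen: negative
#> You qualify for genetic testing based on: risk score >= 2.5%
```

Validity analysis on a synthetic cohort with known truth (default misreport
is overreport-biased, so errors surface as false positives, never false
negatives):

```r
pairs <- build_paired_scores(generate_cohort(cohort_params(n_families = 150, seed = 42)), co)
summarize_concordance(pairs)
#> | n pairs | 150 |
#> | CCC (all pairs) | 0.93 [0.90, 0.95] |
#> | TP / TN / FP / FN | 48 / 100 / 2 / 0 |
#> | sensitivity | 1.000 |
#> | specificity | 0.980 |

ccc_power(0.80, 0.87, n = 124, alpha = 0.05)
#> [1] 0.8276509
```

The power call reproduces the reference design computation: 124 paired
scores give 83% power to reject CCC = 0.80 when the true CCC is 0.87
(one-sided α = 0.05, Fisher-z method under no location/scale shift).

## Command line

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lynchtriage.R",package="lynchtriage"))')" \
  power --ccc0 0.80 --ccc1 0.87 --n 124
#> power = 0.8277 (83%)
```

Subcommands: `assess` (scripted questionnaire → session, family history,
routing outcome, report), `score`, `route`, `validate` (paired CSV →
concordance report), `power`, `paths`, `simulate`. Exit codes: 0 success,
2 validation error, 3 incomplete session.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline desk-scale
quantities from scratch — the closed-form CCC power for the reference
design (as a rounded percent) and the minimum question count of the shipped
questionnaire by exhaustive path enumeration — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/lynch-triage-methods.Rmd`) documents the
scoring model and its assumptions, the questionnaire abstraction, the
statistics, what the synthetic generator does and does not emulate, and the
package's design decisions and limitations.
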