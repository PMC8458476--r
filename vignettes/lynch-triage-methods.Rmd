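---
title: "Methods: patient-facing Lynch syndrome triage and its analytic validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-facing Lynch syndrome triage and its analytic validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchtriage)
```

## The problem

Lynch syndrome (LS) is the most common hereditary colorectal and endometrial
cancer predisposition, caused by mismatch-repair gene mutations. Validated
provider-facing prediction models estimate the probability that a person
carries an LS mutation from their personal and family cancer history, with a
score of at least 2.5% conventionally treated as clinically significant —
enough to justify genetic testing. Those models assume a trained provider who
can pick the "affected side" of the family and aggregate relatives into
first- and second-degree groups.

`lynchtriage` implements a *patient-facing* adaptation of that workflow: the
patient answers a skip-logic questionnaire about relatives in familially
meaningful groups (mother, father, brothers/sisters/children, each side's
grandparents and aunts/uncles), the software aggregates both parental
lineages, scores each side separately, and assigns the affected side
computationally as the side with the higher score. The package also
implements the statistics used to ask whether such a tool *works*: agreement
between patient-derived and genetic-counselor-derived scores (Lin's
concordance correlation coefficient), threshold misclassification, and power
analysis — together with a seeded synthetic cohort generator so the whole
pipeline is testable without patient data.

## Bilateral scoring model

Each parental side is summarized into a predictor record: proband sex, age,
colorectal cancer count and youngest diagnosis age; endometrial and
other-LS-cancer indicators; the same cells for first-degree (FDR) and
second-degree (SDR) relatives on that side; and the youngest endometrial age
overall. Siblings and children share both lineages, so they (and the
proband's own history) enter *both* side aggregations; explicitly sided
relatives enter only theirs. The score is a logistic model

$$p = \operatorname{logit}^{-1}\Big(\beta_0 + \sum_j \beta_j\, t_j(x_j)\Big)$$

whose terms and transforms live in a versioned JSON coefficient file, not in
code. The reported score is $\max(p_\text{maternal}, p_\text{paternal})$ and
the affected side is the argmax, ties broken maternal. The argmax rule is a
design choice: the source workflow states the side is assigned
computationally but not how; the argmax reproduces the "side generating the
risk" semantics deterministically, and the maternal tie-break makes mirror
histories reproducible.

### Coefficients, transforms, absent ages

The published model's coefficients are not redistributed here. The shipped
default (`premm5-coefficients-synthetic.json`) is a clearly labelled
*synthetic* set that mirrors the published model's structure: positive
cancer-history coefficients, counts capped at 2, and "youth" age transforms
$t(a) = \max(0, (45 - a)/10)$ so younger diagnoses raise the score and ages
at or beyond 45 contribute nothing. This shape makes two invariants hold
structurally: adding an affected relative can never lower a side score, and
lowering a diagnosis age can never lower it either. Every test in the
package runs against documented synthetic coefficient sets, so correctness
never depends on a transcription.

Unknown ages at diagnosis are first-class: they are excluded from
minimum-age aggregation, and the coefficient file *must* declare an
absent-age policy — either a reference age substituted before the transform
(the default, 45, which under the youth transform contributes zero) or
`zero_contribution`. Files without a policy are refused, because silent
handling of missing ages is exactly the kind of unit bug this layer exists
to prevent.

The synthetic intercept is −4.3 (baseline carrier probability 1.3%). This
was chosen once, on realism grounds: with the default generator rates it
makes roughly 30% of a healthy synthetic cohort clinically significant,
the same order as the ~25% observed when such a tool is fielded in an
unselected 18–49-year-old population. It was not revisited after measuring
any test outcome.

## The questionnaire engine

Questionnaires are data, not code: a JSON/YAML graph of questions, each with
an ordered list of skip rules (predicate over prior answers → next question)
ending in a mandatory default. Configs are validated at load: acyclicity,
resolvable ids, choice kinds with choices, and — when localization tables
are supplied — every text and literacy-aid key resolving in every declared
language (English and Spanish tables ship with example strings; real
translations are content, not code). Sessions record typed, timestamped
answers; re-answering an earlier question truncates everything downstream so
the recorded path always replays identically. Module timing attributes each
answer's inter-answer gap to its module tag, matching a tracker that logs
answer-input times only.

The shipped default inventory spans **2 to 46 questions**: two gate
questions (personal and family history of cancer), proband blocks, mother /
father blocks, a combined brothers-sisters-children block, four second-degree
group blocks, and a half-sibling block. A patient with no cancer history
answers exactly the two gate questions; the limited-family-history module
(adoption, per-side knowledge, females over 45 per side, prior testing) is a
*separate* 7-question config exposed by the router, because the 2–46
envelope describes the risk-assessment application alone.

`enumerate_paths()` verifies the envelope exhaustively. Answer domains are
abstracted to branch-relevant classes — yes/no and single-choice branches
expand fully, multi-select answers collapse to subsets of the values that
skip rules actually reference, counts and ages to one representative per
predicate-induced equivalence class — and the traversal is memoized dynamic
programming keyed on the current question plus the restriction of the answer
environment to variables that reachable predicates can still read. The
shipped config enumerates in well under a second.

## Eligibility routing

Routing is a small total state machine. No history at the gate → only the
limited module is exposed and decides. History present → both screens
always run (the LS score and a pluggable hereditary breast/ovarian screen),
in an order randomized by a recorded seed; a positive screen (score ≥ 2.5%,
inclusive, or a moderate/high breast/ovarian result) qualifies the patient
and suppresses the limited module; two negative screens expose the limited
module, whose rules (adoption or unknown side history; fewer than 2 female
relatives living beyond 45 on either side) decide. Prior genetic testing is
flagged in the outcome but does not change eligibility — the source
workflow screens for it without stating a consequence, so the package
records rather than decides (an explicitly open question). The shipped
breast/ovarian screen is a non-validated stub behind a plug-in boundary;
injected implementations are used verbatim.

## Analytic-validity statistics

Agreement uses Lin's concordance correlation coefficient with population
(1/n) moments,
$$\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$
the conventional estimator (a sample-moment variant differs at $O(1/n)$ and
is rejected for reproducibility). Patients routed past the scoring
questions have no score; such scores are synthetically set to 0 before
analysis so false-negative candidates enter the comparison. Confidence
intervals Fisher-transform the estimate and use Lin's corrected asymptotic
variance (a bootstrap CI is available as an option). Misclassification at
the 2.5% threshold defines TP/TN/FP/FN with inclusive comparisons on both
raters; pairs differing by ≥ 5 percentage points are "highly discrepant"
and ≥ 15 points are "extreme outliers", with the CCC reported both with and
without the outliers. All scores are probabilities in [0, 1] end to end;
only display formatting converts to percent — this removes the classic
percent-vs-probability bug at the 2.5% boundary.

Power for a one-sided test of $H_0\!: \rho_c = \rho_0$ against
$\rho_1 > \rho_0$ uses the Fisher-z method under no location/scale shift
($u = 0$, $r = \rho_1$), where the z-scale variance collapses to
$1/(n-2)$:
$$\text{power} = \Phi\big((\operatorname{atanh}\rho_1 -
\operatorname{atanh}\rho_0)\sqrt{n-2} - z_{1-\alpha}\big).$$
The no-shift assumption is the one that reproduces the reference design
calculation (83% at $\rho_0 = 0.80$, $\rho_1 = 0.87$, $n = 124$,
$\alpha = 0.05$):

```{r power}
ccc_power(0.80, 0.87, n = 124, alpha = 0.05)
```

The acceptance suite cross-checks this closed form by simulating 5,000
bivariate-normal studies and running the test as an analyst would (Fisher-z
with Lin's *estimated* variance). At $n = 124$ the empirical rejection rate
sits slightly (under one percentage point) below the asymptotic value —
the familiar finite-sample downward bias of $\hat\rho_c$ — comfortably
inside the ±1.5% tolerance of the check. The same asymptotics give 95% CI
coverage within ±2% of nominal at this sample size.

## The synthetic cohort: what it does and does not emulate

`generate_truth()` draws gold-standard families: fixed parents and
grandparents, Poisson-sized sibling (mean 2) and per-side aunt/uncle
(mean 1.5) sets, probands uniform over 18–49 and 80% female (matching the
population such tools are fielded in), diagnoses per relative-class rates
with ages from a truncated normal (mean 62, sd 12, range 25–90). The
misreport process then produces what the *patient* would report: with
probability `overreport_prob` (default 0.15, the order of the ~16% false
positives observed in the field, all of which were overreport) one spurious
LS diagnosis is added; with probability `underreport_prob` (default 0.02)
one true diagnosis is dropped; known ages get rounded Gaussian jitter (sd 3
years). The proband's own diagnosis ages are treated as accurately
reported. Misreport operates on diagnoses rather than questionnaire
answers, so diagnosis-level errors compose with any questionnaire config.
Randomness is organized in named substreams (structure, diagnoses,
misreport) derived from one master seed, so changing one rate never
reshuffles unrelated draws.

The generator makes *structural* claims testable: a zero-error cohort has
CCC exactly 1 and an empty confusion off-diagonal; an overreport-only
cohort can only inflate patient scores, so every misclassification is a
false positive — reproducing the qualitative field finding by
construction; raising the overreport rate monotonically degrades mean CCC.
What it does not emulate: demographically calibrated incidence, pedigree
topology beyond the questionnaire's reach (consanguinity, multiple
marriages), recruitment and dropout, or questionnaire-level misreading. A
green test therefore establishes that the pipeline's logic and statistics
behave as specified under a known truth — not that any particular field
CCC value (such as 0.51 or 0.86 on real pairs, whose underlying data are
unpublished) is reproduced.

```{r cohort}
co <- default_coefficients()
params <- cohort_params(n_families = 150, seed = 42)
cohort <- generate_cohort(params)
pairs <- build_paired_scores(cohort, co)
summarize_concordance(pairs)
```

## Numerical and design choices

* Inclusive comparisons everywhere a boundary is stated: a score of exactly
  0.025 is significant; a difference of exactly 0.05 (or 0.15) is flagged.
* Tie-break for the affected side is maternal; mirror-symmetric histories
  are therefore deterministic.
* `lin_ccc` refuses $n < 2$ and two constant vectors; `ccc_ci` refuses
  $|\hat\rho_c| = 1$ (degenerate) and $n < 3$.
* Ages are integers in [0, 120] or unknown; counts non-negative; violations
  are rejected at the questionnaire boundary with the offending field named.
* Path enumeration abstracts numeric answers to predicate-induced classes;
  this is exact for min/max path length and counts abstract (not concrete)
  terminal paths.
* The half-sibling block is an optional questionnaire block whose side is
  asked explicitly, since the relation itself does not encode a lineage.
* Open design points resolved here: argmax side assignment (above); prior
  genetic testing recorded but not eligibility-changing; group-level
  relative reports materialized as canonical group members preserving the
  count and youngest-age cells the model consumes.

## Limitations

The shipped coefficients are synthetic stand-ins; clinical use requires
transcribing the published model into the coefficient schema. The
breast/ovarian screen is a stub. The Spanish localization table contains
example strings, not reviewed translations. Field CCC values depend on
unpublished patient data and are out of scope; the package reproduces the
*methods*, with desk-scale checks of every statistic against independent
oracles.
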