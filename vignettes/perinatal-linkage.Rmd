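---
title: "Probabilistic mother-infant record linkage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic mother-infant record linkage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perilink)
```

## The problem

Perinatal research joins three record streams: the statutory birth
registration (one record per infant, carrying both maternal and infant
identifiers and the pregnancy outcome), the mother's hospital delivery
admission, and the infant's hospital birth admission. Without a unique
person identifier the join is probabilistic, and the analysis population
splits into linkage groups — *complete* (both admissions linked),
*mothers only*, *infants only*, and *unlinked* birth records, plus
identified hospital admissions that linked to nothing. Because linkage
failure correlates with record quality, and record quality correlates
with clinical risk (very preterm infants, stillbirths near the border of
viability, private hospitals that do not collect names), the unlinked
groups are informative and must be quantified, not discarded.

`perilink` implements the pipeline end to end and pairs it with a
synthetic generator that knows the truth, so linkage quality is measured
exactly rather than estimated from clerical samples.

## The synthetic cohort

`generate_cohort()` simulates deliveries and derives the three streams.
Structural features it reproduces:

* one birth record per infant; multiples share a delivery id, maternal
  identifiers, hospital and birth date, and differ in birth order (and
  possibly sex and given name);
* stillbirths are recorded on the mother's admission and generate no
  infant admission, except for a small misclassification fraction coded
  as liveborn;
* maternal and infant admissions carry ICD-10-AM diagnosis and ACHI
  procedure codes consistent with the simulated characteristics
  (delivery and outcome codes, caesarean and induction procedures,
  diabetes/hypertension/praevia/abruption conditions, Z38 liveborn and
  P-series perinatal codes);
* non-birth admissions (antenatal episodes, infant readmissions) are
  mixed into the hospital streams so identification has true negatives;
* hospital-side identifiers are corrupted copies of the registration
  identifiers.

Default parameters are set once to values representative of a
state-level perinatal population over several years: 1.6% of deliveries
are multiple pregnancies, a 0.6% marginal stillbirth rate, 25% private
hospital births, and a gestational-age distribution with ~7% preterm
(<37 weeks) mass down to 20 completed weeks. Birthweight is drawn from a
gestation-specific mean/SD table (means 350 g at 20 weeks to ~3.7 kg at
42, SD 12% of the mean), which makes gestation- and birthweight-stratified
rate reports meaningful. Stillbirth risk is logit-shifted toward low
gestational age with the shift normalized to unit mean odds factor, so
the marginal rate stays at the configured value while risk at 20 weeks is
roughly 20 times the term risk; the degenerate rates 0 and 1 are exact.

Record availability is controlled separately from identifier quality:
0.4% of deliveries lack a maternal admission, 1.2% of live births lack an
infant admission (severely ill or transferred infants not coded as a
birth admission), 1.5% of stillbirths are misclassified into an infant
admission, and 0.2% of true birth admissions have a coding gap that makes
them unidentifiable by the rules. A designated birth admission otherwise
always carries at least one identifying code, so rule identification on
clean data recovers the designated set exactly — this is the construction
oracle several tests rely on.

### The error model

`error_model()` rates are per field on the hospital-side copies:

| parameter | default | note |
|---|---|---|
| `typo_rate` | 0.02 | substitution or adjacent transposition; always changes the string |
| `name_missing_rate_public` | 0.03 | per name field |
| `name_missing_rate_private` | 0.35 | name collection is discretionary in private hospitals |
| `dob_digit_swap_rate` | 0.005 | calendar-valid day/month or day-digit swap |
| `alias_rate` | 0.03 | recorded alias (maiden name) substituted for surname |
| `address_change_rate` | 0.10 | family moved between registration and admission |
| `gestation_missing_knot` / `_max` | 30 / 0.35 | extra name missingness growing linearly below 30 weeks |

No published figures exist for these rates; they are assumptions chosen
to be demanding but realistic, fixed before any evaluation, and exposed
so users can stress the pipeline. The gestational gradient reproduces the
empirical pattern that complete linkage falls steeply below ~30 weeks.
In addition, 20% of newborns are discharged before being named, so infant
given names are blanked at that rate even under a zero error model — the
construction oracle therefore joins on hospital + MRN, not on names.

What the generator does **not** emulate: real name frequency
distributions, correlated comorbidity structure beyond what the variable
list needs, record duplication, or cross-hospital transfers. Passing
tests on this generator demonstrate the machinery is correct and
well-calibrated under these conditions; they do not certify performance
on any particular real collection.

## Identifier standardization and phonetics

`normalize_identifiers()` uppercases, transliterates to ASCII, deletes
apostrophes, replaces other punctuation with spaces and collapses
whitespace; it is idempotent. Both classic phonetic encoders are
implemented: American Soundex (vowels separate, H/W transparent, 4-char
codes) and NYSIIS. The American Soundex variant was chosen because it is
the reference variant in wide use; non-ASCII letters are transliterated
before encoding. Empty input returns a sentinel code (`"#"`) rather than
an error so encoders can run over fields with missingness. Which encoder
a production system applies per field is generally not published; both
are exposed, and the default clue set uses Soundex and NYSIIS codes as
separate clues and lets the learned weights arbitrate.

## The linkage engine

**Blocking.** Candidate pairs are the union over blocking keys of all
cross-stream pairs sharing the key value. Defaults: hospital + MRN,
surname Soundex + date of birth, date of birth alone, and surname Soundex
+ hospital. On clean data every true pair shares the hospital + MRN key,
so blocking is sound by construction; under the error model a true pair
escapes blocking only if the DOB, the MRN and the name keys are all
corrupted simultaneously (≈3×10⁻⁵ per pair at defaults), and the count of
such escapes is reported (`blocking_missed`), never silently ignored.
Blocks whose pair count would exceed `max_block_size` (default 1,000
pairs) are split by appending the first letter of the given name; blocks
still oversized are dropped and counted. The default budget was chosen as
a round figure that keeps the largest single-date blocks comfortably
below quadratic blowup at the simulated scales.

**Clues.** Each clue compares one field pair and returns agree, disagree
or missing. The default mother-stream set covers given name and surname
(exact, Soundex, NYSIIS), alias surname, full date of birth plus year and
month-day components, address token overlap (≥2 shared tokens), country
of birth, hospital code, MRN, and containment of the birth date in the
admission interval; the infant stream replaces the interval clue with
admission-date proximity (±1 day) and adds sex, birth order and
plurality. A real system's clue list and learned weights are proprietary;
this set mirrors the fields such systems report using and is labeled as a
default assumption.

**Scoring.** Clue outcomes are combined through the maximum-entropy
model in its standard dual form: a binary logistic model over agree and
disagree indicator features, with missing as the zero-contribution
reference level (a disagreement should penalize, an absence should not).
Fitting is a damped Newton iteration on the L2-penalized log-likelihood
(penalty 1e-4, intercept unpenalized, tolerance 1e-8) — regularization is
kept for reproducibility and separable-data stability rather than tuned
for accuracy. The fit is deterministic given data and settings, and is
cross-checked in the tests against an independent `glm` fit at negligible
penalty.

**Thresholds.** Pairs with probability ≥ upper are auto-matches, ≤ lower
auto-non-matches, and in between fall into the clerical-review band
(conventional starting cut-offs 0.75/0.25; boundary inclusivity is a
documented convention, the continuous score makes it immaterial in
practice). `tune_thresholds()` grid-searches (step 0.02) for the
configuration meeting the missed-link and false-positive targets among
auto-decided pairs while minimizing the review band, breaking ties toward
the widest band — the cut-offs sit at the edges of the empty score gap,
the most robust placement — and reports infeasibility explicitly instead
of falling back.

**Review and assignment.** Review-band pairs are resolved by a pluggable
policy: in synthetic mode the ground-truth oracle stands in for clerical
review (assumed accurate), in blind mode review pairs are rejected.
Accepted pairs then get a greedy one-to-one assignment in descending
probability with stable id-order tie-breaks; the tests verify greedy
equals the exhaustive optimum under those tie rules on small fixtures.

**Stratified passes.** Singleton and multiple pregnancies are linked in
separate passes, because multiples generate infant records with
near-identical identifiers. Cross-stratum candidate pairs are discarded
before scoring, so the strata never compete for an assignment. Admissions
whose plurality cannot be classified from their codes are routed to the
singleton (majority) pass — a deterministic choice that avoids any record
entering both passes. Weights and thresholds are fitted on the pooled
stream (the multiple stratum alone is too small for stable estimation);
only candidate restriction and assignment are stratified.

**Mother-side linkage level.** The mother's linkage operates at delivery
level (multiples share one maternal admission, and a one-to-one map per
birth record would be structurally wrong); the delivery-level link is
then propagated to each birth record of the delivery.

## Admission identification rules

Infant birth admissions require age 0–1 days (the calculated-age interval
[0, 0.0028] years read as integer day-age in {0, 1}), first admission,
and any of: a Z38 liveborn code, a born-in-hospital source of referral,
or a recorded birthweight together with a perinatal-period P code.
Maternal delivery admissions require any delivery diagnosis (O80–O84,
Z37, O60.1–O60.3) or delivery-associated procedure code. Code matching is
prefix-hierarchical ("O24" matches "O24.4") and case-insensitive, with
ranges confined to a letter class; the code lists ship as a YAML
vocabulary (`inst/extdata/birth_admission_codes.yml`) and every literal
in it is round-trip tested against its own rule.

Two conventions worth flagging. The duration-of-pregnancy rule
(O90.1–O90.3) appears in identification tables under a "< 25 weeks" label
while variable lists and comparison tables say "< 26 weeks"; the package
keys the output `duration_lt26wk` and records both labels in the
vocabulary file rather than resolving the discrepancy. "First admission"
is read as admission order 1 in the infant's record sequence. When
several maternal admissions qualify for one delivery, the one whose
interval contains the birth date is preferred, then the earliest — in the
pipeline this resolution is subsumed by the probabilistic assignment
(the admission-interval clue makes the containing admission score
higher), with `check_link_constraints()` available as the deterministic
filter.

## Groups, reporting and quality

`assign_groups()` is exhaustive and mutually exclusive over birth
records, so group counts always sum to the number of birth records
(tested on every run); `stratify()` partitions by plurality ×
live/stillbirth with an explicit `unknown` stratum rather than a hidden
remainder. Percentages are computed half-up to one decimal
(`round_half_up()`), matching how such tables are conventionally printed;
base R's round-half-to-even would differ in the second decimal's
boundary cases. Every emitted percentage recomputes from its own count
and column N (self-consistency is a test).

`evaluate_quality()` reports missed links per 1,000 true pairs and false
positives per 1,000 declared links, from exact integer counts. The
true-pair denominator is the ground-truth pairs whose records were both
available to the linkage: record non-existence and identification misses
are availability losses, reported by `identification_coverage()`, not
linkage errors. This separation is deliberate — with a 1.2% infant-record
missingness the two notions differ by an order of magnitude, and
conflating them would make the quality metric meaningless as a property
of the decision procedure.

One consequence of simulating with an accurate review oracle and strong
administrative identifiers (MRN) is that linkage quality is excellent
(well under 1 missed link per 1,000 at defaults) while the partial-linkage
groups are still populated — in this generator the groups are driven
mainly by record availability, whereas in real collections a larger share
comes from identifier failure. The group-size pattern is structurally
faithful; its causal composition is not claimed to be.

## Problem sizes and runtime

The test suite runs cohorts of 100–4,000 deliveries for structural and
statistical checks and one 10,000-delivery default cohort (~20,000 true
pairs, ~100,000 candidate pairs) for the end-to-end quality bound; the
acceptance script averages the 10,000-delivery run over three seeds.
These sizes were chosen so that binomial checks have power and the
quality bound is measured on a denominator where 1 per 1,000 is a
meaningful resolution, while a full run stays around half a minute on a
single core. Parameter recovery for the maximum-entropy weights uses
50,000 simulated pairs, where the sampling error of each weight is well
below the 0.1 tolerance.

## Known limitations

* Clerical review is an oracle or a rejection; no error model for human
  reviewers is provided.
* The generator's clean-side registration identifiers are uncorrupted;
  all corruption lives on the hospital copies. Real registrations carry
  their own errors, which would lower quality symmetrically.
* Blocking keys and clues assume the MRN and hospital code exist in both
  streams; collections without administrative identifiers would need a
  weaker key set and would not reach the same quality bounds.
* Threshold tuning optimizes on the labeled training split; with very
  small streams the grid optimum can overfit the split. The review band
  and the oracle policy absorb most of that risk in synthetic mode.
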