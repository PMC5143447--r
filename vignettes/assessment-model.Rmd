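---
title: "Rule-based assessment of adolescent obesity phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based assessment of adolescent obesity phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenokb)
```

## The model

phenokb classifies timestamped anthropometric assessments of adolescents
into obesity-related health-condition classes. It separates three kinds
of knowledge the way modular ontology systems separate TBox, RBox and
ABox:

* a **taxonomy** — a rooted tree of condition classes. `HealthCondition`
  is the root; domain families (physical constitution, physical
  activity, physiology, nutrition) hang below it; the
  physical-constitution branch carries the assessable leaves: the four
  body-mass classes (obese / overweight / normal weight / underweight),
  the two fat-distribution phenotypes (android / gynoid), central
  obesity, and adiposity. Each assessable leaf is annotated with which
  of five measured criteria can establish it: (1) body mass index,
  (2) waist-to-hip ratio, (3) waist circumference, (4) waist-to-height
  ratio, (5) body fat mass. Central obesity is assessable from *any one*
  of criteria 2–4, which is why its rules each test a single criterion.

* **rules** — DL-safe conjunctive Horn clauses: an antecedent of class
  atoms, property atoms and builtins, and a single consequent atom.
  Variables bind only to named individuals and literals already present
  in the fact base (DL-safety), there is no negation and no
  disjunction, so forward chaining reaches a least fixpoint in finitely
  many sweeps, the fixpoint does not depend on rule order, and adding
  facts can only grow it. These three properties — termination,
  order-independence, monotonicity — are asserted by property tests
  against an exhaustive-enumeration oracle.

* a **fact store** partitioned three ways for privacy: persons (gender,
  date of birth), conditions (assessments and their inferred classes —
  never a person identifier), and links. Person-identifying data and
  health data are only joinable through the link store, and a link is
  accepted only when both endpoints resolve.

Classification rules never assert a class on the person; they classify
the *condition individual* the person is linked to. A person therefore
accumulates a timeline of classified conditions, and because inference
is monotone, re-assessment never invalidates earlier conclusions — the
key property for longitudinal tracking.

## The teen rule pack

The adolescent pack is generated from reference tables rather than
written by hand, because cutoff values are the volatile part of this
knowledge: when a reference standard is revised, only the table changes.
With the shipped tables the pack holds **76 classification rules**:

| family            | rules | structure                                        |
|-------------------|-------|--------------------------------------------------|
| body mass         | 56    | 2 genders × 7 one-year age bands (11–17) × 4 BMI classes |
| fat distribution  | 4     | 2 genders × {android, gynoid}                    |
| central obesity   | 8     | per gender: WHR, waist (ages 10–14), waist (15–19), WHtR |
| adiposity         | 8     | 2 genders × 4 age bands                          |

plus four derived-parameter rules (age, BMI, WHR, WHtR) that let raw
measurements classify without pre-computation.

Only the total counts of the four families, the female android
threshold (waist-to-hip ratio ≥ 0.85 at ages 13–17) and the body-mass
pattern are fixed by the published design; the internal decomposition
of each family is a package choice. We use the smallest structure
consistent with the counts: 56 factors naturally as 2 × 7 × 4 over
one-year bands at ages 11–17; the central-obesity family gets one rule
per criterion per gender with the waist-circumference criterion split
into two age bands (circumference cutoffs grow substantially during
adolescence, unlike the two ratio cutoffs); the adiposity family uses
four age bands per gender with a single consequent class, because the
taxonomy defines exactly one adiposity class — decomposing by body-fat
*level* would require leaf classes that do not exist in the tree. The
male android threshold (0.90) and all numeric cutoffs other than the
0.85/13–17 values are implementer-supplied, WHO-2007-*style* synthetic
fixtures, clearly labelled as such in the table citations; tests depend
only on table-driven behaviour, never on the fixture numbers being
epidemiologically authoritative.

Boundary convention: lower bounds are inclusive ("greater or equal", as
the android threshold is stated), upper bounds exclusive. Together with
a validator that rejects tables whose per-age BMI intervals do not
partition the positive axis, this guarantees every (gender, covered
age, BMI) triple fires exactly one body-mass leaf — sibling
disjointness is enforced by data validation, not by negation, keeping
the engine monotone.

## Parameters and units

| quantity | unit | notes |
|---|---|---|
| body mass | kg | strictly positive |
| height | m | strictly positive |
| BMI | kg/m² | stored unrounded; cutoff comparisons use unrounded values |
| waist, hip circumference | cm | |
| waist-to-hip ratio | — | in (0, 3) |
| waist-to-height ratio | — | waist converted to metres before division |
| body fat mass | % of body mass | |
| age | completed years | integer |

Age follows completed-calendar-years, anniversary-inclusive semantics:
the count increments on the birthday itself, and a February-29 birthday
rolls to March 1 in non-leap years. We use whole years because the
rules compare age against integer bounds (13, 17), and whole years is
the convention age-banded growth references assume. Where a ratio and
its components are both supplied they must agree within **0.005** —
half the two-decimal precision that published thresholds like 0.85
imply; a larger discrepancy is a data error, not rounding.

## Numerical choices

* Threshold comparisons use a tolerance of 1e-9, so a stored `0.85`
  satisfies `≥ 0.85` regardless of binary-float representation; the
  tolerance is far below the 0.005 data precision, so it can never
  flip a classification that the data could distinguish.
* Literals are carried as canonical decimal strings; term equality is
  numeric whenever both sides parse as numbers.
* Taxonomy subsumption is compiled into rules (`Child(?x) → Parent(?x)`),
  so one evaluation mechanism serves both domain rules and the class
  hierarchy.
* The fixpoint loop carries an iteration cap of
  (individuals + 1) × (classes + rules + 1) sweeps with an internal
  assertion; for negation-free DL-safe rules the cap is unreachable.
* Degenerate inputs: an assessment dated before the person's birth, or
  an internally inconsistent record, is excluded from classification
  and logged per assessment — one bad record never aborts a batch. The
  age builtin likewise yields *no binding* (rather than an error) for
  an invalid date pair.

The engine accepts data-property consequents in addition to class
consequents. Class-only heads would be enough for classification, but
the derived-parameter rules (age from dates, BMI from mass and height,
the two ratios) naturally have property heads, and realising them in
the same forward-chaining mechanism keeps derivation and
classification in one fixpoint. The date-difference builtin
(`ageInYears`) is exposed as a single engine builtin with the
completed-years semantics above, rather than a chain of
date-decomposition arithmetic.

## The synthetic cohort generator

`generate_cohort()` emulates a teen study population: ages 10–19,
gender-balanced by default, heights and masses drawn from gender- and
age-indexed normal distributions with growth-chart-shaped means
(fixtures, not epidemiological claims), waist/hip circumferences scaled
from height, and per-field missingness for the optional measurements.
All randomness flows from the single spec seed, so cohorts are
bit-reproducible. A longitudinal mode spaces repeat assessments exactly
one year apart, which exercises the reclassification that age-dependent
cutoffs produce under a constant BMI.

What the generator does **not** emulate: within-person correlation of
height and mass over waves (each wave resamples), measurement error
models, secular trends, or realistic missingness mechanisms (fields are
missing completely at random). Passing tests therefore demonstrate the
machinery — table-driven rule generation, monotone inference,
round-trips — on realistic *marginals*, not validity of any cutoff for
real adolescents.

## Problem sizes

The shipped tests run the engine-versus-oracle comparison on 200
randomised instances of at most 5 rules and 8 individuals (small enough
for the oracle's exhaustive enumeration to stay exact), sweep the BMI
partition at every table boundary ± 0.005 for three representative ages
per gender, and drive the android-threshold sweeps over ratios
0.50–1.20 in steps of 0.01 and ages 8–25. These sizes were chosen so
that the whole suite exercises every code path at desk scale.

## Known limitations

* Subsumption over a tree only: no equivalence, no multiple
  inheritance, no existential or cardinality reasoning. The published
  person/condition restrictions are realised as data-model invariants
  (a link needs both endpoints; a person may have any number of
  conditions), not as description-logic axioms.
* Rule packs for the behavioural domains (physical activity,
  physiology, nutrition, application context) are supported by the
  format and engine but ship only as illustrative stubs; their
  published rule content is not available.
* The store is append-only by design; there is no retraction API.
  Correcting a wrong assertion means rebuilding the store without it.
* Access separation between the three fact partitions is a structural
  contract, not access control; deployments would layer authentication
  on top.
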