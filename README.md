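# phenokb

Rule-based, age- and gender-specific assessment of obesity-related
health conditions in adolescents.

Public-health screening classifies a teenager's physical constitution —
obese / overweight / normal weight / underweight, android vs gynoid fat
distribution, central obesity, adiposity — from anthropometric
measurements, against cutoffs that change with age and differ by gender.
phenokb implements this as a small knowledge-base system, for
researchers and engineers building personalised health-assessment
pipelines who want the classification knowledge *externalised and
inspectable* rather than buried in code:

* a **condition taxonomy**: a tree rooted at `HealthCondition`, whose
  physical-constitution branch carries the assessable classes, each
  annotated with which measured criteria can establish it — (1) BMI,
  (2) waist-to-hip ratio, (3) waist circumference, (4) waist-to-height
  ratio, (5) body fat mass;
* a **forward-chaining rule engine** for DL-safe conjunctive rules
  (no negation, no disjunction): for rules *B₁ ∧ … ∧ Bₙ → H* over class
  atoms, property atoms and comparison/arithmetic builtins, it computes
  the least fixpoint *F* ⊇ facts with monotone, order-independent,
  terminating semantics, and can **explain** every inferred fact by the
  rule and bindings that produced it;
* a **table-driven rule generator** producing the 76-rule teenager
  physical-status pack (56 body-mass + 4 fat-distribution + 8
  central-obesity + 8 adiposity rules) from reference-value tables, e.g.
  the female android rule: *Female(p) ∧ isInHealthCondition(p,h) ∧
  isAssessedAtAge(h,age) ∧ 13 ≤ age ≤ 17 ∧ WHR(h) ≥ 0.85 →
  AndroidCondition(h)*;
* a **partitioned fact store** (persons / conditions / links) in which
  condition records never expose person identity, plus derived-measure
  computation (age in completed years, BMI = mass/height², WHR, WHtR),
  CSV/JSON cohort IO, Turtle/N-Triples export, a seeded synthetic-cohort
  generator and a CLI.

Because inference is monotone, a person accumulates classified
conditions over time and re-assessment never invalidates earlier
conclusions — the age-dependent cutoffs make the *same* BMI classify
differently a year later, which is the longitudinal behaviour the
package is built around.

## Worked example

A boy born in October 2000 is assessed in two consecutive Novembers with
the same BMI of 24.3 kg/m²:

```r
library(phenokb)

kb <- knowledge_base(rule_packs = list(assemble_teen_pack()))
kb <- add_person(kb, person_record("tom", "Male", "2000-10-15"))
kb <- add_assessment(kb, assessment_record("tomcond1", "2014-11-20",
                                           body_mass_index = 24.3))
kb <- add_assessment(kb, assessment_record("tomcond2", "2015-11-20",
                                           body_mass_index = 24.3))
kb <- link_assessment(kb, "tom", "tomcond1")
kb <- link_assessment(kb, "tom", "tomcond2")
kb <- classify_all(kb)

q <- query_conditions(kb, "tom", class_filter = "BodyMassCondition")
for (x in q)
  cat(x$assessment$assessment_date, "->",
      paste(x$classes, collapse = ", "), "\n")
#> 2014-11-20 -> ObeseCondition, BodyMassCondition
#> 2015-11-20 -> OverweightCondition, BodyMassCondition
```

At age 14 a BMI of 24.3 is at or above the obese cutoff (24.0), so the
first assessment is `ObeseCondition`; by 15 the cutoff has risen to
24.8, so the unchanged BMI now falls in the overweight interval
[22.7, 24.8) — the second assessment is `OverweightCondition`. (Both
also match the `BodyMassCondition` filter itself via reflexive
subsumption.) Every inference is explainable:

```r
explain_condition(kb, "tomcond2", "OverweightCondition")$antecedent
#> ["Male(tom)","isInHealthCondition(tom, tomcond2)",
#>  "isAssessedAtAge(tomcond2, 15)", ...,
#>  "greaterThanOrEqual(24.3, 22.7)","lessThan(24.3, 24.8)"]
```

The shipped cutoff tables (`inst/extdata/reference-tables.csv`) are
WHO-2007-style synthetic fixtures — growth-reference-shaped but not
authoritative; swap in your own via `read_reference_tables()` and
`assemble_teen_pack()`. The same example is runnable from the shell:

```sh
Rscript inst/cli/phenokb.R assess \
  --cohort inst/extdata/tom-cohort --out /tmp/tom-kb
```

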