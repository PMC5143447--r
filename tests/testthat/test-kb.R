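test_that("stores accept fresh records and reject duplicates and dangles", {
  kb <- tom_kb()
  expect_equal(nrow(kb$persons), 1)
  expect_equal(nrow(kb$assessments), 2)
  expect_equal(nrow(kb$links), 2)

  expect_error(add_person(kb, person_record("tom", "Male", "2001-01-01")),
               "duplicate person_id")
  expect_error(add_assessment(kb, assessment_record("tomcond1",
                                                    "2016-01-01")),
               "duplicate assessment_id")
  expect_error(link_assessment(kb, "tom", "nothere"),
               "does not resolve: assessment")
  expect_error(link_assessment(kb, "nobody", "tomcond1"),
               "does not resolve: person")
})

test_that("a constant BMI flips from obese to overweight a year later", {
  kb <- classify_all(tom_kb())
  cls <- function(aid) kb$inferred$class[kb$inferred$assessment_id == aid]
  expect_true("ObeseCondition" %in% cls("tomcond1"))
  expect_false("OverweightCondition" %in% cls("tomcond1"))
  expect_true("OverweightCondition" %in% cls("tomcond2"))
  expect_false("ObeseCondition" %in% cls("tomcond2"))
  # subsumption propagates to the family classes
  expect_true("BodyMassCondition" %in% cls("tomcond1"))
  expect_true("PhysicalConstitutionCondition" %in% cls("tomcond2"))
  # ages were derived and asserted at classify time
  expect_equal(kb$assessments$age_at_assessment, c(14L, 15L))

  # classification is idempotent
  again <- classify_all(kb)
  expect_equal(again$inferred[, c("assessment_id", "class", "rule_id")],
               kb$inferred[, c("assessment_id", "class", "rule_id")])
})

test_that("unlinked assessments are not classified", {
  kb <- knowledge_base(rule_packs = list(assemble_teen_pack()))
  kb <- add_person(kb, person_record("p1", "Male", "2001-01-01"))
  kb <- add_assessment(kb, assessment_record("a1", "2015-06-01",
                                             body_mass_index = 30))
  kb <- classify_all(kb)
  expect_equal(nrow(kb$inferred), 0)
})

test_that("classification requires a registered rule pack", {
  expect_error(classify_all(knowledge_base()), "no rule pack")
})

test_that("enrichment failures are logged per assessment, not fatal", {
  kb <- knowledge_base(rule_packs = list(assemble_teen_pack()))
  kb <- add_person(kb, person_record("p1", "Male", "2010-01-01"))
  # assessed before birth: enrichment fails for this record only
  kb <- add_assessment(kb, assessment_record("bad", "2005-06-01",
                                             body_mass_index = 30))
  kb <- add_person(kb, person_record("p2", "Male", "2001-06-02"))
  kb <- add_assessment(kb, assessment_record("good", "2015-06-01",
                                             body_mass_index = 30))
  kb <- link_assessment(kb, "p1", "bad")
  kb <- link_assessment(kb, "p2", "good")
  kb <- classify_all(kb)
  expect_true(any(grepl("^bad:", kb$classify_log)))
  expect_true("ObeseCondition" %in%
                kb$inferred$class[kb$inferred$assessment_id == "good"])
  expect_false("bad" %in% kb$inferred$assessment_id)
})

test_that("explanations survive in the store with provenance", {
  kb <- classify_all(tom_kb())
  ex <- explain_condition(kb, "tomcond2", "OverweightCondition")
  expect_equal(nrow(ex), 1)
  expect_match(ex$rule_id, "body_mass.*Male.*OverweightCondition")
  expect_match(ex$antecedent, "isCharacterizedByBodyMassIndex\\(tomcond2")
  expect_true(nzchar(ex$inferred_at))
  expect_error(explain_condition(kb, "nothere"), "unknown assessment")
})

test_that("queries sort by date and filter by subsumption and as_of", {
  kb <- classify_all(tom_kb())
  q <- query_conditions(kb, "tom", class_filter = "BodyMassCondition")
  expect_length(q, 2)
  expect_equal(q[[1]]$assessment$assessment_id, "tomcond1")
  # the filter matches by subsumption, reflexively: the leaf and the
  # body-mass family class itself
  expect_setequal(q[[1]]$classes, c("ObeseCondition", "BodyMassCondition"))
  expect_setequal(q[[2]]$classes,
                  c("OverweightCondition", "BodyMassCondition"))

  everything <- query_conditions(kb, "tom", class_filter = "HealthCondition")
  expect_true(all(vapply(everything, function(x) length(x$classes) >= 3,
                         logical(1))))

  first_only <- query_conditions(kb, "tom", as_of = "2015-01-01")
  expect_length(first_only, 1)
  expect_equal(first_only[[1]]$assessment$assessment_id, "tomcond1")

  expect_error(query_conditions(kb, "ghost"), "unknown person")
})

test_that("the condition store never exposes person identity", {
  kb <- classify_all(tom_kb())
  cs <- condition_store(kb)
  expect_false("person_id" %in% names(cs))
  expect_false("person_id" %in% names(attr(cs, "inferred")))
  expect_true("person_id" %in% names(person_store(kb)))
  # the association is only recoverable through the link store
  expect_true(all(c("person_id", "assessment_id") %in%
                    names(link_store(kb))))
})

test_that("merging modules is union-like and preserves inferences", {
  kb <- classify_all(tom_kb())
  n_inferred <- nrow(kb$inferred)

  # merging an empty knowledge base is identity on the stores
  merged <- merge_modules(kb, knowledge_base())
  expect_equal(merged$persons, kb$persons)
  expect_equal(merged$inferred, kb$inferred)

  # merging a stub rule pack from another domain leaves results unchanged
  stub <- rule_pack("activity_R2_stub", list(
    rule("sedentary_stub",
         list(atom("data_property", "hasDailyActivityMinutes",
                   c("?h", "?m")),
              atom("builtin", "lessThan", c("?m", "30"))),
         atom("class", "SedentaryCondition", "?h"),
         family = "physical_activity")))
  kb2 <- classify_all(merge_modules(kb, stub))
  expect_true(all(paste(kb$inferred$assessment_id, kb$inferred$class) %in%
                    paste(kb2$inferred$assessment_id, kb2$inferred$class)))

  # classify, merge new assessments, classify again: monotone
  kb3 <- merge_modules(kb, stub)
  kb3 <- add_person(kb3, person_record("ann", "Female", "2000-03-10"))
  kb3 <- add_assessment(kb3, assessment_record(
    "anncond1", "2015-06-01", waist_circumference = 76.5,
    hip_circumference = 90))
  kb3 <- link_assessment(kb3, "ann", "anncond1")
  kb3 <- classify_all(kb3)
  expect_true(all(paste(kb$inferred$assessment_id, kb$inferred$class) %in%
                    paste(kb3$inferred$assessment_id, kb3$inferred$class)))
  expect_true("AndroidCondition" %in%
                kb3$inferred$class[kb3$inferred$assessment_id == "anncond1"])
  expect_gte(nrow(kb3$inferred), n_inferred)

  # conflicting record under the same id is a merge conflict
  other <- knowledge_base()
  other <- add_person(other, person_record("tom", "Male", "1999-01-01"))
  expect_error(merge_modules(kb, person_store(other)), "merge conflict")
})

test_that("classification commutes with splitting the cohort", {
  mk <- function(pid, gender, dob, aid, bmi, date) {
    kb <- knowledge_base(rule_packs = list(assemble_teen_pack()))
    kb <- add_person(kb, person_record(pid, gender, dob))
    kb <- add_assessment(kb, assessment_record(aid, date,
                                               body_mass_index = bmi))
    link_assessment(kb, pid, aid)
  }
  kb_a <- mk("pa", "Male", "2002-01-10", "aa", 25.5, "2015-06-01")
  kb_b <- mk("pb", "Female", "2001-07-20", "ab", 14.0, "2015-06-01")

  split_then_merge <- merge_modules(classify_all(kb_a), classify_all(kb_b))
  merge_then_classify <- classify_all(merge_modules(kb_a, kb_b))
  key <- function(kb) sort(paste(kb$inferred$assessment_id,
                                 kb$inferred$class))
  expect_equal(key(split_then_merge), key(merge_then_classify))
})

test_that("the default import graph matches the layered topology", {
  g <- default_import_graph()
  expect_length(validate_import_graph(g), 0)
  rboxes <- names(g)[startsWith(names(g), "R_")]
  expect_length(rboxes, 5)
  for (r in rboxes) {
    tb <- g[[r]][startsWith(g[[r]], "T_")]
    expect_length(tb, 1)
    expect_equal(tb, sub("^R_", "T_", r))
    expect_true("Common" %in% g[[r]])
  }
  expect_true("ABox_Person" %in% g$ABox_Integration)
  expect_true("ABox_HealthCondition" %in% g$ABox_Integration)

  cyc <- list(A = "B", B = "A")
  expect_true(any(grepl("cycle", validate_import_graph(cyc))))
  expect_error(knowledge_base(import_graph = cyc), "invalid import graph")
})
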