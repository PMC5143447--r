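ax10_rule <- function() {
  rule("Ax10",
       list(atom("class", "Female", "?p"),
            atom("object_property", "isInHealthCondition", c("?p", "?h")),
            atom("data_property", "isAssessedAtAge", c("?h", "?age")),
            atom("builtin", "greaterThanOrEqual", c("?age", "13")),
            atom("builtin", "lessThanOrEqual", c("?age", "17")),
            atom("data_property", "isCharacterizedByWaistToHipRatio",
                 c("?h", "?whr")),
            atom("builtin", "greaterThanOrEqual", c("?whr", "0.85"))),
       atom("class", "AndroidCondition", "?h"))
}

android_facts <- function(age = 15, whr = 0.85) {
  facts <- fact_base()
  facts <- assert_class(facts, "f1", "Female")
  facts <- assert_property(facts, "f1", "isInHealthCondition", "h1")
  facts <- assert_property(facts, "h1", "isAssessedAtAge", age)
  assert_property(facts, "h1", "isCharacterizedByWaistToHipRatio", whr)
}

test_that("matching the android rule binds person, condition and age", {
  b <- match_bindings(ax10_rule(), android_facts())
  expect_equal(nrow(b), 1)
  expect_equal(b[["?p"]], "f1")
  expect_equal(b[["?h"]], "h1")
  expect_equal(as.numeric(b[["?age"]]), 15)
  # threshold is inclusive: just below it, no binding
  expect_equal(nrow(match_bindings(ax10_rule(), android_facts(whr = 0.84))),
               0)
  expect_equal(nrow(match_bindings(ax10_rule(), android_facts(age = 12))),
               0)
})

test_that("fixpoint adds the inferred condition and nothing else", {
  out <- evaluate_to_fixpoint(list(ax10_rule()), android_facts())
  expect_true(has_class(out, "h1", "AndroidCondition"))
  expect_equal(nrow(out$inferred_classes), 1)
  expect_equal(out$classes, android_facts()$classes)

  untouched <- evaluate_to_fixpoint(list(), android_facts())
  expect_equal(nrow(untouched$inferred_classes), 0)
  expect_equal(untouched$classes, android_facts()$classes)
})

test_that("a builtin over a variable that can never bind errors", {
  r <- rule("stuck",
            list(atom("class", "Female", "?p"),
                 atom("builtin", "greaterThanOrEqual", c("?loose", "1"))),
            atom("class", "C", "?p"))
  expect_error(match_bindings(r, android_facts()), "cannot be bound")
})

test_that("derived-parameter rules bind arithmetic results", {
  facts <- fact_base()
  facts <- assert_property(facts, "h1", "isCharacterizedByBodyMass", 80)
  facts <- assert_property(facts, "h1", "isCharacterizedByHeight", 2)
  out <- evaluate_to_fixpoint(derived_parameter_rules(), facts)
  ip <- out$inferred_props
  bmi <- ip$object[ip$predicate == "isCharacterizedByBodyMassIndex"]
  expect_equal(as.numeric(bmi), 20)
})

test_that("explanations cite the rule, binding and grounded antecedent", {
  out <- evaluate_to_fixpoint(list(ax10_rule()), android_facts())
  ex <- explain(out, "h1", "AndroidCondition")
  expect_equal(ex$status, "inferred")
  expect_equal(ex$rule_id, "Ax10")
  expect_equal(ex$binding[["?h"]], "h1")
  expect_true(any(grepl("isCharacterizedByWaistToHipRatio\\(h1, 0.85\\)",
                        ex$antecedent)))
  expect_equal(explain(out, "f1", "Female")$status, "asserted")
  expect_error(explain(out, "h1", "GynoidCondition"), "no assertion")
})

test_that("explanations replay: grounded antecedents hold in the facts", {
  tables <- default_reference_tables()
  rules <- c(rules_from_taxonomy(build_default_taxonomy()),
             assemble_teen_pack(tables)$rules)
  facts <- android_facts()
  facts <- assert_property(facts, "h1", "isCharacterizedByBodyMassIndex",
                           26.5)
  out <- evaluate_to_fixpoint(rules, facts)
  expect_gt(nrow(out$inferred_classes), 2)
  ac <- phenokb:::.all_classes(out)
  ap <- phenokb:::.all_props(out)
  for (i in seq_len(nrow(out$inferred_classes))) {
    ex <- explain(out, out$inferred_classes$individual[i],
                  out$inferred_classes$class[i])
    for (ga in ex$antecedent) {
      m <- regmatches(ga, regexec("^([A-Za-z]+)\\((.*)\\)$", ga))[[1]]
      pred <- m[2]
      args <- trimws(strsplit(m[3], ",")[[1]])
      if (pred %in% c("greaterThanOrEqual", "lessThanOrEqual", "greaterThan",
                      "lessThan", "equal")) {
        x <- as.numeric(args[1]); y <- as.numeric(args[2])
        ok <- switch(pred, greaterThanOrEqual = x >= y,
                     lessThanOrEqual = x <= y, greaterThan = x > y,
                     lessThan = x < y, equal = x == y)
        expect_true(ok, info = ga)
      } else if (length(args) == 1) {
        expect_true(any(ac$individual == args[1] & ac$class == pred),
                    info = ga)
      } else {
        expect_true(any(ap$subject == args[1] & ap$predicate == pred &
                          phenokb:::.term_equal(ap$object, args[2])),
                    info = ga)
      }
    }
  }
})

test_that("fixpoint agrees with the exhaustive-enumeration oracle", {
  withr::with_seed(101, {
    for (case in 1:60) {
      inst <- random_instance()
      facts <- fact_base(inst$classes, inst$props)
      got <- evaluate_to_fixpoint(inst$rules, facts)
      want <- oracle_fixpoint(inst$rules, inst$classes, inst$props)
      expect_equal(sorted_class_set(phenokb:::.all_classes(got)),
                   sorted_class_set(want), info = paste("case", case))
    }
  })
})

test_that("evaluation is monotone, idempotent and order-independent", {
  withr::with_seed(202, {
    for (case in 1:30) {
      inst <- random_instance()
      facts <- fact_base(inst$classes, inst$props)
      out <- evaluate_to_fixpoint(inst$rules, facts)
      base_set <- sorted_class_set(phenokb:::.all_classes(out))

      # facts are contained in the fixpoint
      expect_true(all(sorted_class_set(inst$classes) %in% base_set))

      # idempotence
      again <- evaluate_to_fixpoint(inst$rules, out)
      expect_equal(sorted_class_set(phenokb:::.all_classes(again)), base_set)

      # monotone under added facts
      extra <- data.frame(individual = "i1", class = "C9",
                          stringsAsFactors = FALSE)
      bigger <- evaluate_to_fixpoint(
        inst$rules, fact_base(rbind(inst$classes, extra), inst$props))
      expect_true(all(base_set %in%
                        sorted_class_set(phenokb:::.all_classes(bigger))))

      # rule order does not change the fixpoint
      shuffled <- evaluate_to_fixpoint(sample(inst$rules), facts)
      expect_equal(sorted_class_set(phenokb:::.all_classes(shuffled)),
                   base_set)
    }
  })
})
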