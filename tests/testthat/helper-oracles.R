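# Test helpers: an exhaustive-enumeration fixpoint oracle, a random
# small-instance generator, and fixture builders shared across tests.

# ---- brute-force fixpoint oracle -------------------------------------
# Enumerates every assignment of rule variables to terms occurring in the
# facts, checks the grounded antecedent naively, and iterates until
# stable. Independent of the engine's join-based matcher.

oracle_atom_holds <- function(a, asg, classes, props) {
  val <- function(t) if (startsWith(t, "?")) asg[[t]] else t
  if (a$kind == "class") {
    return(any(classes$individual == val(a$args[1]) &
                 classes$class == a$predicate))
  }
  if (a$kind %in% c("object_property", "data_property")) {
    return(any(props$subject == val(a$args[1]) &
                 props$predicate == a$predicate &
                 props$object == val(a$args[2])))
  }
  # comparison builtins over numeric literals only
  x <- suppressWarnings(as.numeric(val(a$args[1])))
  y <- suppressWarnings(as.numeric(val(a$args[2])))
  if (is.na(x) || is.na(y)) return(FALSE)
  switch(a$predicate,
         greaterThanOrEqual = x >= y,
         lessThanOrEqual = x <= y,
         greaterThan = x > y,
         lessThan = x < y,
         equal = x == y,
         FALSE)
}

oracle_fixpoint <- function(rules, classes, props) {
  terms <- unique(c(classes$individual, props$subject, props$object))
  repeat {
    added <- FALSE
    for (r in rules) {
      vars <- unique(unlist(lapply(c(r$antecedent, list(r$consequent)),
                                   function(a) {
                                     a$args[startsWith(a$args, "?")]
                                   })))
      grids <- rep(list(terms), length(vars))
      grid <- do.call(expand.grid,
                      c(grids, list(stringsAsFactors = FALSE)))
      for (gi in seq_len(max(1, nrow(grid)))) {
        asg <- if (length(vars) == 0) list()
               else as.list(stats::setNames(unlist(grid[gi, ]), vars))
        ok <- all(vapply(r$antecedent, oracle_atom_holds, logical(1),
                         asg = asg, classes = classes, props = props))
        if (!ok) next
        h <- r$consequent
        ind <- if (startsWith(h$args[1], "?")) asg[[h$args[1]]] else h$args[1]
        if (!any(classes$individual == ind & classes$class == h$predicate)) {
          classes <- rbind(classes,
                           data.frame(individual = ind, class = h$predicate,
                                      stringsAsFactors = FALSE))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  classes
}

# ---- random small instances ------------------------------------------

random_instance <- function() {
  inds <- paste0("i", seq_len(sample(2:8, 1)))
  classes_pool <- paste0("C", 1:4)
  props_pool <- paste0("q", 1:2)
  lits <- c("1", "2", "3")
  n_c <- sample(2:6, 1)
  cls <- unique(data.frame(
    individual = sample(inds, n_c, replace = TRUE),
    class = sample(classes_pool, n_c, replace = TRUE),
    stringsAsFactors = FALSE))
  n_p <- sample(2:6, 1)
  prp <- unique(data.frame(
    subject = sample(inds, n_p, replace = TRUE),
    predicate = sample(props_pool, n_p, replace = TRUE),
    object = sample(c(inds, lits), n_p, replace = TRUE),
    stringsAsFactors = FALSE))
  n_rules <- sample(1:5, 1)
  rules <- lapply(seq_len(n_rules), function(ri) {
    body <- list(atom("class", sample(classes_pool, 1), "?x"))
    if (stats::runif(1) < 0.7) {
      body <- c(body, list(atom("object_property", sample(props_pool, 1),
                                c("?x", "?y"))))
    }
    if (stats::runif(1) < 0.4 && length(body) == 2) {
      body <- c(body, list(atom("builtin", sample(
        c("greaterThanOrEqual", "lessThan", "equal"), 1),
        c("?y", sample(lits, 1)))))
    }
    body_vars <- unique(unlist(lapply(body, function(a) {
      a$args[startsWith(a$args, "?")]
    })))
    rule(paste0("r", ri), body,
         atom("class", sample(classes_pool, 1), sample(body_vars, 1)))
  })
  list(rules = rules, classes = cls, props = prp)
}

sorted_class_set <- function(df) {
  s <- unique(paste(df$individual, df$class))
  sort(s)
}

# ---- shared fixtures --------------------------------------------------

# one-gender one-age body-mass table with the given cutoffs
tiny_bmi_table <- function(gender = "Male", age = 14,
                           u = 15, n = 21, o = 24) {
  reference_table("body_mass", data.frame(
    gender = gender, age_min = age, age_max = age,
    class = c("UnderweightCondition", "NormalWeightCondition",
              "OverweightCondition", "ObeseCondition"),
    criterion = "bmi",
    bound_kind = c("upper_exclusive", "interval", "interval",
                   "lower_inclusive"),
    value_1 = c(u, u, n, o), value_2 = c(NA, n, o, NA),
    stringsAsFactors = FALSE), citation = "test fixture")
}

# body-mass table over an age span with strictly rising cutoffs
random_rising_bmi_table <- function(ages) {
  base_u <- runif(1, 13, 15)
  base_n <- runif(1, 18, 20)
  base_o <- base_n + runif(1, 1.5, 3)
  rows <- list()
  for (g in c("Male", "Female")) {
    u <- base_u; n <- base_n; o <- base_o
    for (a in ages) {
      u <- u + runif(1, 0.1, 0.5)
      n <- n + runif(1, 0.3, 0.9)
      o <- o + runif(1, 0.5, 1.2)  # obese bound strictly increasing
      rows[[length(rows) + 1L]] <- data.frame(
        gender = g, age_min = a, age_max = a,
        class = c("UnderweightCondition", "NormalWeightCondition",
                  "OverweightCondition", "ObeseCondition"),
        criterion = "bmi",
        bound_kind = c("upper_exclusive", "interval", "interval",
                       "lower_inclusive"),
        value_1 = c(u, u, n, o), value_2 = c(NA, n, o, NA),
        stringsAsFactors = FALSE)
    }
  }
  reference_table("body_mass", do.call(rbind, rows),
                  citation = "randomised test fixture")
}

# run a single (gender, age, value) case through the engine and return
# the inferred classes for the condition individual
classify_single <- function(rules, gender, age, property, value) {
  facts <- fact_base()
  facts <- assert_class(facts, "p1", gender)
  facts <- assert_property(facts, "p1", "isInHealthCondition", "h1")
  facts <- assert_property(facts, "h1", "isAssessedAtAge", age)
  facts <- assert_property(facts, "h1", property, value)
  out <- evaluate_to_fixpoint(rules, facts)
  out$inferred_classes$class[out$inferred_classes$individual == "h1"]
}

bmi_leaves <- c("ObeseCondition", "OverweightCondition",
                "NormalWeightCondition", "UnderweightCondition")

# the worked longitudinal fixture: boy born October 2000, constant BMI,
# assessed in two consecutive Novembers
tom_kb <- function(pack = assemble_teen_pack(), bmi = 24.3) {
  kb <- knowledge_base(rule_packs = list(pack))
  kb <- add_person(kb, person_record("tom", "Male", "2000-10-15"))
  kb <- add_assessment(kb, assessment_record("tomcond1", "2014-11-20",
                                             body_mass_index = bmi))
  kb <- add_assessment(kb, assessment_record("tomcond2", "2015-11-20",
                                             body_mass_index = bmi))
  kb <- link_assessment(kb, "tom", "tomcond1")
  link_assessment(kb, "tom", "tomcond2")
}
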