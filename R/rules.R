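#' @title DL-safe rules and the fact base
#' @description
#' Rules are conjunctive Horn clauses over class atoms, property atoms and
#' a small set of builtins — the decidable, negation-free fragment used in
#' rule-based health assessment. Variables (written `?x`) may bind only to
#' named individuals or to literals already present in the fact base
#' (DL-safety), which guarantees that forward chaining terminates.
#' @name rules
NULL

.COMPARISON_BUILTINS <- c("greaterThanOrEqual", "lessThanOrEqual",
                          "greaterThan", "lessThan", "equal")
.ARITHMETIC_BUILTINS <- c("subtract", "divide", "multiply", "add")
# ageInYears(result, assessment_date, date_of_birth): completed calendar
# years between two ISO dates; the engine's date builtin
.DATE_BUILTINS <- "ageInYears"
.KNOWN_BUILTINS <- c(.COMPARISON_BUILTINS, .ARITHMETIC_BUILTINS, .DATE_BUILTINS)
.ATOM_KINDS <- c("class", "object_property", "data_property", "builtin")

.NUM_EPS <- 1e-9

#' Canonical literal formatting for engine terms
#' @param x numeric vector.
#' @return character vector.
#' @keywords internal
fmt_num <- function(x) {
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

is_rule_var <- function(term) startsWith(as.character(term), "?")

#' Construct a rule atom
#'
#' @param kind one of `"class"`, `"object_property"`, `"data_property"`,
#'   `"builtin"`.
#' @param predicate class name, property name, or builtin name.
#' @param args arguments: variables (`"?x"`) or constants. Numerics are
#'   stored in a canonical decimal form.
#' @return an object of class `rule_atom`.
#' @export
atom <- function(kind, predicate, args) {
  if (!kind %in% .ATOM_KINDS) stop("unknown atom kind: ", kind, call. = FALSE)
  args <- vapply(args, function(a) {
    if (is.numeric(a)) fmt_num(a) else as.character(a)
  }, character(1))
  a <- structure(list(kind = kind, predicate = as.character(predicate),
                      args = unname(args)), class = "rule_atom")
  .check_atom_arity(a)
  a
}

.check_atom_arity <- function(a) {
  n <- length(a$args)
  ok <- switch(a$kind,
    class = n == 1,
    object_property = n == 2,
    data_property = n == 2,
    builtin = {
      if (!a$predicate %in% .KNOWN_BUILTINS) {
        stop("unknown builtin: ", a$predicate, call. = FALSE)
      }
      if (a$predicate %in% .COMPARISON_BUILTINS) n == 2 else n == 3
    })
  if (!ok) {
    stop("wrong arity for ", a$kind, " atom ", a$predicate, ": ", n,
         " arguments", call. = FALSE)
  }
  invisible(a)
}

#' Construct a DL-safe rule
#'
#' The consequent is a single class atom (classification rules) or a
#' single data-property atom (derived-parameter rules such as the age
#' rule); every consequent variable must occur in the antecedent.
#' Negation and disjunction are not representable.
#'
#' @param rule_id identifier string.
#' @param antecedent list of [atom()]s, read as a conjunction.
#' @param consequent a single class or data-property [atom()].
#' @param provenance free-text source annotation.
#' @param family optional rule-family tag (used by rule packs).
#' @return an object of class `rule`.
#' @export
rule <- function(rule_id, antecedent, consequent, provenance = "",
                 family = NA_character_) {
  r <- structure(list(rule_id = as.character(rule_id),
                      antecedent = antecedent, consequent = consequent,
                      provenance = as.character(provenance),
                      family = as.character(family)),
                 class = "rule")
  validate_rule(r)
  r
}

#' Validate a rule against the DL-safe invariants
#' @param r a `rule`.
#' @return `r` invisibly; raises naming the rule on violation.
#' @export
validate_rule <- function(r) {
  err <- function(...) stop("rule ", r$rule_id, ": ", ..., call. = FALSE)
  if (!length(r$antecedent)) err("empty antecedent")
  for (a in r$antecedent) {
    if (!inherits(a, "rule_atom")) err("antecedent atom is not a rule_atom")
    .check_atom_arity(a)
  }
  h <- r$consequent
  if (!inherits(h, "rule_atom")) err("consequent is not a rule_atom")
  if (!h$kind %in% c("class", "data_property")) {
    err("consequent must be a class or data-property atom, got ", h$kind)
  }
  body_vars <- unique(unlist(lapply(r$antecedent,
                                    function(a) a$args[is_rule_var(a$args)])))
  head_vars <- h$args[is_rule_var(h$args)]
  missing <- setdiff(head_vars, body_vars)
  if (length(missing) > 0) {
    err("unsafe head variable(s) not bound in antecedent: ",
        paste(missing, collapse = ", "))
  }
  invisible(r)
}

#' @export
print.rule <- function(x, ...) {
  fa <- function(a) paste0(a$predicate, "(", paste(a$args, collapse = ", "), ")")
  cat("<rule>", x$rule_id, "\n  ",
      paste(vapply(x$antecedent, fa, character(1)), collapse = " ^ "),
      "\n  -> ", fa(x$consequent), "\n", sep = "")
  invisible(x)
}

# ---- fact base --------------------------------------------------------

.empty_classes <- function() {
  data.frame(individual = character(0), class = character(0),
             stringsAsFactors = FALSE)
}
.empty_props <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), stringsAsFactors = FALSE)
}
.empty_inferred_classes <- function() {
  data.frame(individual = character(0), class = character(0),
             rule_id = character(0), binding = character(0),
             antecedent = character(0), stringsAsFactors = FALSE)
}
.empty_inferred_props <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), rule_id = character(0),
             binding = character(0), stringsAsFactors = FALSE)
}

#' Construct a fact base
#'
#' Holds asserted class assertions and property assertions, plus the
#' inferred assertions produced by [evaluate_to_fixpoint()] (kept disjoint
#' from the asserted set, each carrying rule and binding provenance).
#' Append-only: no operation removes a fact.
#'
#' @param class_assertions data.frame with columns `individual`, `class`.
#' @param property_assertions data.frame with columns `subject`,
#'   `predicate`, `object` (literals as canonical strings).
#' @return an object of class `fact_base`.
#' @export
fact_base <- function(class_assertions = .empty_classes(),
                      property_assertions = .empty_props()) {
  ca <- as.data.frame(class_assertions, stringsAsFactors = FALSE)
  pa <- as.data.frame(property_assertions, stringsAsFactors = FALSE)
  if (nrow(ca)) ca[] <- lapply(ca, as.character)
  if (nrow(pa)) pa[] <- lapply(pa, as.character)
  structure(list(classes = unique(ca), props = unique(pa),
                 inferred_classes = .empty_inferred_classes(),
                 inferred_props = .empty_inferred_props()),
            class = "fact_base")
}

#' Assert a class membership / property fact
#' @param facts a `fact_base`.
#' @param individual,class_name,subject,predicate,object identifiers or
#'   literals (numerics canonicalised).
#' @return the updated `fact_base`.
#' @export
assert_class <- function(facts, individual, class_name) {
  add <- data.frame(individual = individual, class = class_name,
                    stringsAsFactors = FALSE)
  facts$classes <- unique(rbind(facts$classes, add))
  facts
}

#' @rdname assert_class
#' @export
assert_property <- function(facts, subject, predicate, object) {
  if (is.numeric(object)) object <- fmt_num(object)
  add <- data.frame(subject = subject, predicate = predicate,
                    object = as.character(object), stringsAsFactors = FALSE)
  facts$props <- unique(rbind(facts$props, add))
  facts
}

# union views the evaluator works over
.all_classes <- function(facts) {
  unique(rbind(facts$classes,
               facts$inferred_classes[, c("individual", "class")]))
}
.all_props <- function(facts) {
  unique(rbind(facts$props,
               facts$inferred_props[, c("subject", "predicate", "object")]))
}

#' Number of class/property facts visible to evaluation
#' @param facts a `fact_base`.
#' @return integer count.
#' @export
n_facts <- function(facts) {
  nrow(.all_classes(facts)) + nrow(.all_props(facts))
}

#' Does the fact base contain a class assertion (asserted or inferred)?
#' @param facts a `fact_base`.
#' @param individual,class_name identifiers.
#' @return logical scalar.
#' @export
has_class <- function(facts, individual, class_name) {
  ac <- .all_classes(facts)
  any(ac$individual == individual & ac$class == class_name)
}

#' @export
print.fact_base <- function(x, ...) {
  cat("<fact_base>", nrow(x$classes), "asserted class facts,",
      nrow(x$props), "asserted property facts,",
      nrow(x$inferred_classes), "inferred class facts,",
      nrow(x$inferred_props), "inferred property facts\n")
  invisible(x)
}

# ---- rule packs -------------------------------------------------------

#' Construct a rule pack
#' @param pack_id identifier string.
#' @param rules list of [rule()]s.
#' @return an object of class `rule_pack` with a `family_counts` table
#'   over the rules' family tags.
#' @export
rule_pack <- function(pack_id, rules) {
  for (r in rules) validate_rule(r)
  fams <- vapply(rules, function(r) r$family, character(1))
  fc <- table(fams[!is.na(fams)])
  structure(list(pack_id = as.character(pack_id), rules = rules,
                 family_counts = stats::setNames(as.integer(fc), names(fc))),
            class = "rule_pack")
}

#' @export
print.rule_pack <- function(x, ...) {
  cat("<rule_pack>", x$pack_id, "with", length(x$rules), "rules\n")
  if (length(x$family_counts)) {
    for (f in names(x$family_counts)) {
      cat("  ", f, ": ", x$family_counts[[f]], "\n", sep = "")
    }
  }
  invisible(x)
}

.atom_to_list <- function(a) {
  list(kind = a$kind, predicate = a$predicate, args = as.list(a$args))
}

.atom_from_list <- function(x, where) {
  if (!is.list(x) || is.null(x$kind) || is.null(x$predicate) ||
      is.null(x$args)) {
    stop(where, ": malformed atom (need kind/predicate/args)", call. = FALSE)
  }
  if (!is.null(x$negated) && isTRUE(x$negated)) {
    stop(where, ": negated atoms are not supported", call. = FALSE)
  }
  atom(x$kind, x$predicate, unlist(x$args, use.names = FALSE))
}

#' Serialise a rule pack to its document form
#' @param pack a `rule_pack`.
#' @return a plain list (YAML/JSON-ready).
#' @export
rule_pack_to_list <- function(pack) {
  list(pack_id = pack$pack_id,
       rules = lapply(pack$rules, function(r) {
         rec <- list(id = r$rule_id,
                     body = lapply(r$antecedent, .atom_to_list),
                     head = .atom_to_list(r$consequent))
         if (!is.na(r$family)) rec$family <- r$family
         if (nzchar(r$provenance)) rec$provenance <- r$provenance
         rec
       }))
}

#' Write a rule pack to a YAML or JSON file
#' @param pack a `rule_pack`.
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path` invisibly.
#' @export
save_rule_pack <- function(pack, path) {
  doc <- rule_pack_to_list(pack)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Load and validate a rule pack
#'
#' Accepts a file path (YAML or JSON) or an already-parsed document list.
#' Every rule is validated (atom arity, known builtins, DL-safe head);
#' documents containing negation or disjunction constructs are rejected.
#' Errors name the offending rule.
#'
#' @param source path or list.
#' @return a `rule_pack`; rules in document order.
#' @export
load_rule_pack <- function(source) {
  doc <- if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) stop("no such rule-pack file: ", source,
                                   call. = FALSE)
    if (grepl("\\.json$", source)) jsonlite::read_json(source)
    else yaml::read_yaml(source)
  } else if (is.list(source)) {
    source
  } else {
    stop("rule-pack source must be a path or a parsed document list",
         call. = FALSE)
  }
  if (is.null(doc$pack_id)) stop("rule pack has no pack_id", call. = FALSE)
  rules <- lapply(doc$rules, function(rr) {
    rid <- if (is.null(rr$id)) "<unnamed>" else rr$id
    if (!is.null(rr$or) || !is.null(rr$disjunction)) {
      stop("rule ", rid, ": disjunction is not supported", call. = FALSE)
    }
    body <- lapply(rr$body, .atom_from_list, where = paste("rule", rid))
    head <- .atom_from_list(rr$head, where = paste("rule", rid))
    rule(rid, body, head,
         provenance = if (is.null(rr$provenance)) "" else rr$provenance,
         family = if (is.null(rr$family)) NA_character_ else rr$family)
  })
  rule_pack(doc$pack_id, rules)
}

#' Subsumption rules generated from a taxonomy
#'
#' One rule per child-parent edge (`Child(?x) -> Parent(?x)`), so that
#' class subsumption is realised by the same forward-chaining mechanism
#' as the domain rules.
#'
#' @param taxonomy a `condition_taxonomy`.
#' @return list of [rule()]s.
#' @export
rules_from_taxonomy <- function(taxonomy) {
  cl <- taxonomy$classes
  edges <- cl[!is.na(cl$parent), c("name", "parent")]
  lapply(seq_len(nrow(edges)), function(i) {
    rule(paste0("subsume_", edges$name[i], "_", edges$parent[i]),
         list(atom("class", edges$name[i], "?x")),
         atom("class", edges$parent[i], "?x"),
         provenance = "taxonomy subsumption edge",
         family = "subsumption")
  })
}
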