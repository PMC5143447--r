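#' @title Forward-chaining evaluation to a fixpoint
#' @description
#' The evaluator repeatedly applies every rule to the union of asserted
#' and inferred facts until no new assertion is produced. Because rules
#' are negation-free and DL-safe (variables range only over named
#' individuals and literals present in the facts), the fixpoint exists,
#' is least, and is reached in finitely many sweeps; adding facts can
#' only grow it (monotonicity).
#' @name engine
NULL

# one-row, zero-column data.frame: the single empty binding
.unit_binding <- function() data.frame(row.names = "1")[, 0, drop = FALSE]

.no_bindings <- function(vars) {
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(vars)),
                                      vars), stringsAsFactors = FALSE)
  df
}

.join_bindings <- function(x, y) {
  if (ncol(x) == 0) return(if (nrow(x) == 0) y[0, , drop = FALSE] else y)
  if (ncol(y) == 0) return(if (nrow(y) == 0) x[0, , drop = FALSE] else x)
  merge(x, y, by = intersect(names(x), names(y)))
}

# candidate tuple table for a non-builtin atom, columns named by variables
.atom_candidates <- function(a, all_classes, all_props) {
  tup <- if (a$kind == "class") {
    rows <- all_classes[all_classes$class == a$predicate, , drop = FALSE]
    data.frame(t1 = rows$individual, stringsAsFactors = FALSE)
  } else {
    rows <- all_props[all_props$predicate == a$predicate, , drop = FALSE]
    data.frame(t1 = rows$subject, t2 = rows$object, stringsAsFactors = FALSE)
  }
  keep_idx <- integer(0)
  keep_names <- character(0)
  for (i in seq_along(a$args)) {
    arg <- a$args[i]
    if (is_rule_var(arg)) {
      prev <- match(arg, a$args[seq_len(i - 1)])
      if (!is.na(prev)) {
        tup <- tup[.term_equal(tup[[i]], tup[[prev]]), , drop = FALSE]
      } else {
        keep_idx <- c(keep_idx, i)
        keep_names <- c(keep_names, arg)
      }
    } else {
      tup <- tup[.term_equal(tup[[i]], arg), , drop = FALSE]
    }
  }
  tup <- tup[, keep_idx, drop = FALSE]
  names(tup) <- keep_names
  unique(tup)
}

# term equality: numeric when both sides parse as numbers, else string
.term_equal <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0) return(logical(0))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  an <- suppressWarnings(as.numeric(a))
  bn <- suppressWarnings(as.numeric(b))
  num <- !is.na(an) & !is.na(bn)
  out <- a == b
  out[num] <- abs(an[num] - bn[num]) <= .NUM_EPS
  out
}

.resolve_term <- function(arg, bindings) {
  if (is_rule_var(arg)) bindings[[arg]] else rep(arg, nrow(bindings))
}

.builtin_ready <- function(a, bound_vars) {
  args <- a$args
  need <- if (a$predicate %in% .COMPARISON_BUILTINS) args else args[-1]
  all(!is_rule_var(need) | need %in% bound_vars)
}

.apply_builtin <- function(a, bindings) {
  if (nrow(bindings) == 0) return(bindings)
  p <- a$predicate
  if (p %in% .COMPARISON_BUILTINS) {
    x <- suppressWarnings(as.numeric(.resolve_term(a$args[1], bindings)))
    y <- suppressWarnings(as.numeric(.resolve_term(a$args[2], bindings)))
    keep <- switch(p,
      greaterThanOrEqual = x >= y - .NUM_EPS,
      lessThanOrEqual = x <= y + .NUM_EPS,
      greaterThan = x > y + .NUM_EPS,
      lessThan = x < y - .NUM_EPS,
      equal = abs(x - y) <= .NUM_EPS)
    keep[is.na(keep)] <- FALSE
    return(bindings[keep, , drop = FALSE])
  }
  # arity-3 builtins: (result, operand, operand)
  val <- if (p %in% .ARITHMETIC_BUILTINS) {
    x <- suppressWarnings(as.numeric(.resolve_term(a$args[2], bindings)))
    y <- suppressWarnings(as.numeric(.resolve_term(a$args[3], bindings)))
    switch(p, subtract = x - y, divide = x / y, multiply = x * y,
           add = x + y)
  } else {  # ageInYears(result, assessment_date, date_of_birth)
    d1 <- .resolve_term(a$args[2], bindings)
    d2 <- .resolve_term(a$args[3], bindings)
    # an invalid pair (bad date, assessment before birth) yields no binding
    vapply(seq_len(nrow(bindings)), function(i) {
      tryCatch(as.numeric(compute_age(d2[i], d1[i])),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  res <- a$args[1]
  if (is_rule_var(res) && !res %in% names(bindings)) {
    bindings[[res]] <- fmt_num(val)
    return(bindings[!is.na(val), , drop = FALSE])
  }
  cur <- suppressWarnings(as.numeric(.resolve_term(res, bindings)))
  keep <- !is.na(cur) & !is.na(val) & abs(cur - val) <= .NUM_EPS
  bindings[keep, , drop = FALSE]
}

#' Match a rule's antecedent against a fact base
#'
#' Returns every variable binding that jointly satisfies all antecedent
#' atoms over the union of asserted and inferred facts. Builtins are
#' evaluated only once their operands are bound (an arithmetic result
#' slot may be unbound, in which case it is computed and bound); a
#' builtin whose operands can never be bound raises an evaluation error.
#'
#' @param rule a [rule()].
#' @param facts a [fact_base()].
#' @return a data.frame with one column per rule variable and one row per
#'   satisfying binding (zero rows if the rule does not fire).
#' @export
match_bindings <- function(rule, facts) {
  all_classes <- .all_classes(facts)
  all_props <- .all_props(facts)
  pending <- rule$antecedent
  bindings <- .unit_binding()
  while (length(pending) > 0) {
    if (nrow(bindings) == 0) return(bindings)
    idx <- 0
    for (i in seq_along(pending)) {
      a <- pending[[i]]
      if (a$kind != "builtin" || .builtin_ready(a, names(bindings))) {
        idx <- i
        break
      }
    }
    if (idx == 0) {
      bad <- pending[[1]]
      stop("rule ", rule$rule_id, ": builtin ", bad$predicate,
           " applied to variable(s) that cannot be bound", call. = FALSE)
    }
    a <- pending[[idx]]
    pending <- pending[-idx]
    bindings <- if (a$kind == "builtin") {
      .apply_builtin(a, bindings)
    } else {
      .join_bindings(bindings, .atom_candidates(a, all_classes, all_props))
    }
  }
  unique(bindings)
}

.ground_atom <- function(a, binding) {
  args <- vapply(a$args, function(t) {
    if (is_rule_var(t) && t %in% names(binding)) as.character(binding[[t]])
    else as.character(t)
  }, character(1))
  paste0(a$predicate, "(", paste(args, collapse = ", "), ")")
}

.binding_json <- function(binding) {
  jsonlite::toJSON(as.list(binding), auto_unbox = TRUE)
}

#' Evaluate rules to their least fixpoint
#'
#' Repeatedly applies all rules, adding each new consequent (class
#' assertions, or property assertions for derived-parameter rules) with
#' provenance (rule id, binding, grounded antecedent), until a full sweep
#' adds nothing. Input facts are never removed. An internal iteration cap
#' of |individuals| x |classes| sweeps (plus property head room) guards
#' against implementation error; it is unreachable for valid rule sets.
#'
#' @param rules list of [rule()]s (or a [rule_pack()]).
#' @param facts a [fact_base()].
#' @return the expanded `fact_base`.
#' @export
evaluate_to_fixpoint <- function(rules, facts) {
  if (inherits(rules, "rule_pack")) rules <- rules$rules
  for (r in rules) validate_rule(r)
  inds <- unique(c(.all_classes(facts)$individual, .all_props(facts)$subject))
  classes <- unique(c(.all_classes(facts)$class,
                      vapply(rules, function(r) r$consequent$predicate,
                             character(1))))
  cap <- max(10L, (length(inds) + 1L) * (length(classes) + length(rules) + 1L))
  sweep <- 0L
  repeat {
    sweep <- sweep + 1L
    if (sweep > cap) {
      stop("fixpoint iteration cap exceeded (internal error)", call. = FALSE)
    }
    changed <- FALSE
    for (r in rules) {
      b <- match_bindings(r, facts)
      if (nrow(b) == 0) next
      h <- r$consequent
      for (i in seq_len(nrow(b))) {
        bi <- b[i, , drop = FALSE]
        if (h$kind == "class") {
          ind <- if (is_rule_var(h$args[1])) as.character(bi[[h$args[1]]])
                 else h$args[1]
          if (has_class(facts, ind, h$predicate)) next
          facts$inferred_classes <- rbind(facts$inferred_classes, data.frame(
            individual = ind, class = h$predicate, rule_id = r$rule_id,
            binding = as.character(.binding_json(bi)),
            antecedent = as.character(jsonlite::toJSON(
              vapply(r$antecedent, .ground_atom, character(1), binding = bi))),
            stringsAsFactors = FALSE))
          changed <- TRUE
        } else {
          subj <- if (is_rule_var(h$args[1])) as.character(bi[[h$args[1]]])
                  else h$args[1]
          obj <- if (is_rule_var(h$args[2])) as.character(bi[[h$args[2]]])
                 else h$args[2]
          ap <- .all_props(facts)
          hit <- ap$subject == subj & ap$predicate == h$predicate &
            .term_equal(ap$object, obj)
          if (any(hit)) next
          facts$inferred_props <- rbind(facts$inferred_props, data.frame(
            subject = subj, predicate = h$predicate, object = obj,
            rule_id = r$rule_id,
            binding = as.character(.binding_json(bi)),
            stringsAsFactors = FALSE))
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  facts
}

#' Explain a class assertion
#'
#' For an inferred assertion, returns the rule that produced it, the
#' variable binding, and the grounded antecedent facts it used; for an
#' asserted fact, a marker record with status `"asserted"`.
#'
#' @param facts a [fact_base()] (after evaluation).
#' @param individual,class_name the assertion to explain.
#' @return a list with `status` (`"asserted"`/`"inferred"`) and, when
#'   inferred, `rule_id`, `binding` (named list) and `antecedent`
#'   (character vector of grounded atoms).
#' @export
explain <- function(facts, individual, class_name) {
  if (any(facts$classes$individual == individual &
          facts$classes$class == class_name)) {
    return(list(status = "asserted", individual = individual,
                class = class_name))
  }
  ic <- facts$inferred_classes
  hit <- which(ic$individual == individual & ic$class == class_name)
  if (length(hit) == 0) {
    stop("no assertion ", class_name, "(", individual, ") in fact base",
         call. = FALSE)
  }
  i <- hit[1]
  list(status = "inferred", individual = individual, class = class_name,
       rule_id = ic$rule_id[i],
       binding = jsonlite::fromJSON(ic$binding[i]),
       antecedent = unlist(jsonlite::fromJSON(ic$antecedent[i])))
}
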