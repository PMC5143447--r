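#' @title The modular knowledge base
#' @description
#' A knowledge base bundles the condition taxonomy (the terminological
#' component), registered rule packs (the rule component), and a
#' three-way partitioned fact store: a *person store* (demographic facts
#' only), a *condition store* (timestamped assessments and the condition
#' classes inferred for them — never a person identifier), and a *link
#' store* holding the person-to-assessment associations. The partition
#' mirrors a privacy constraint: person-identifying facts and
#' health-condition facts are only joinable through the link store, and a
#' link is accepted only when both endpoints resolve.
#'
#' All stores are append-only; classification is monotone, so re-running
#' it, or adding new persons, assessments or rule modules, never retracts
#' a previously inferred condition.
#' @name kb
NULL

.empty_persons <- function() {
  data.frame(person_id = character(0), gender = character(0),
             date_of_birth = character(0), stringsAsFactors = FALSE)
}
.empty_assessments <- function() {
  df <- data.frame(assessment_id = character(0), assessment_date = character(0),
                   stringsAsFactors = FALSE)
  for (f in .MEASURE_FIELDS) df[[f]] <- numeric(0)
  df$age_at_assessment <- integer(0)
  df
}
.empty_links <- function() {
  data.frame(person_id = character(0), assessment_id = character(0),
             stringsAsFactors = FALSE)
}
.empty_kb_inferred <- function() {
  data.frame(assessment_id = character(0), class = character(0),
             rule_id = character(0), binding = character(0),
             antecedent = character(0), inferred_at = character(0),
             stringsAsFactors = FALSE)
}

#' The default module import graph
#'
#' The terminological module of each domain imports the common module;
#' each rule module imports its own terminological module plus the common
#' module; the person partition imports the common module, the
#' health-condition partition imports the rule modules, and the
#' integration partition imports both fact partitions.
#'
#' @return named list mapping module name to the character vector of its
#'   imports.
#' @export
default_import_graph <- function() {
  doms <- c("PhysicalStatus", "PhysicalActivityBehaviour",
            "PhysiologicalStatus", "NutritionalHabits", "ApplicationContext")
  g <- list(Common = character(0))
  for (d in doms) g[[paste0("T_", d)]] <- "Common"
  for (d in doms) g[[paste0("R_", d)]] <- c(paste0("T_", d), "Common")
  g$ABox_Person <- "Common"
  g$ABox_HealthCondition <- paste0("R_", doms)
  g$ABox_Integration <- c("ABox_Person", "ABox_HealthCondition")
  g
}

#' Validate a module import graph
#' @param graph named list as returned by [default_import_graph()].
#' @return character vector of violations; empty if valid.
#' @export
validate_import_graph <- function(graph) {
  out <- character(0)
  nodes <- names(graph)
  for (n in nodes) {
    dangling <- setdiff(graph[[n]], nodes)
    if (length(dangling) > 0) {
      out <- c(out, paste0(n, " imports unknown module(s): ",
                           paste(dangling, collapse = ", ")))
    }
  }
  # cycle check via repeated leaf removal (Kahn)
  remaining <- nodes
  repeat {
    leaves <- remaining[vapply(remaining, function(n) {
      length(intersect(graph[[n]], remaining)) == 0
    }, logical(1))]
    if (length(leaves) == 0) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining) > 0) {
    out <- c(out, paste0("import cycle among: ",
                         paste(remaining, collapse = ", ")))
  }
  rboxes <- nodes[startsWith(nodes, "R_")]
  for (r in rboxes) {
    tb <- graph[[r]][startsWith(graph[[r]], "T_")]
    if (length(tb) != 1 || !"Common" %in% graph[[r]]) {
      out <- c(out, paste0(r, " must import exactly one TBox plus Common"))
    }
  }
  unique(out)
}

#' Create a knowledge base
#'
#' @param taxonomy a [condition_taxonomy()] (default: the shipped tree).
#' @param rule_packs list of [rule_pack()]s to register.
#' @param import_graph module import graph (default:
#'   [default_import_graph()]).
#' @return an object of class `knowledge_base`.
#' @export
knowledge_base <- function(taxonomy = build_default_taxonomy(),
                           rule_packs = list(),
                           import_graph = default_import_graph()) {
  bad <- validate_taxonomy(taxonomy)
  if (length(bad) > 0) {
    stop("invalid taxonomy: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  bad <- validate_import_graph(import_graph)
  if (length(bad) > 0) {
    stop("invalid import graph: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  kb <- structure(list(
    taxonomy = taxonomy,
    rule_packs = list(),
    persons = .empty_persons(),
    assessments = .empty_assessments(),
    links = .empty_links(),
    inferred = .empty_kb_inferred(),
    import_graph = import_graph,
    classify_log = character(0)
  ), class = "knowledge_base")
  for (p in rule_packs) kb <- register_rule_pack(kb, p)
  kb
}

#' Register a rule pack with a knowledge base
#' @param kb a `knowledge_base`.
#' @param pack a [rule_pack()].
#' @return the updated `knowledge_base`.
#' @export
register_rule_pack <- function(kb, pack) {
  stopifnot(inherits(kb, "knowledge_base"), inherits(pack, "rule_pack"))
  if (pack$pack_id %in% names(kb$rule_packs)) {
    if (identical(rule_pack_to_list(kb$rule_packs[[pack$pack_id]]),
                  rule_pack_to_list(pack))) {
      return(kb)
    }
    stop("conflicting rule pack under id ", pack$pack_id, call. = FALSE)
  }
  kb$rule_packs[[pack$pack_id]] <- pack
  kb
}

.assessment_to_row <- function(rec) {
  row <- data.frame(assessment_id = rec$assessment_id,
                    assessment_date = format(rec$assessment_date),
                    stringsAsFactors = FALSE)
  for (f in .MEASURE_FIELDS) row[[f]] <- rec[[f]]
  row$age_at_assessment <- rec$age_at_assessment
  row
}

.row_to_assessment <- function(row) {
  do.call(assessment_record, c(
    list(assessment_id = row$assessment_id,
         assessment_date = row$assessment_date),
    stats::setNames(lapply(.MEASURE_FIELDS, function(f) row[[f]]),
                    .MEASURE_FIELDS),
    list(age_at_assessment = row$age_at_assessment)))
}

#' Add a person / an assessment / a link
#'
#' Append-only updates. Ids must be fresh; a link is accepted only when
#' both of its endpoints already resolve in the person and condition
#' stores (the concurrent-access contract of the partition).
#'
#' @param kb a `knowledge_base`.
#' @param person a [person_record()].
#' @param assessment an [assessment_record()].
#' @param person_id,assessment_id endpoint identifiers for `link_assessment`.
#' @return the updated `knowledge_base`.
#' @export
add_person <- function(kb, person) {
  stopifnot(inherits(kb, "knowledge_base"), inherits(person, "person_record"))
  if (person$person_id %in% kb$persons$person_id) {
    stop("duplicate person_id: ", person$person_id, call. = FALSE)
  }
  kb$persons <- rbind(kb$persons, data.frame(
    person_id = person$person_id, gender = person$gender,
    date_of_birth = format(person$date_of_birth), stringsAsFactors = FALSE))
  kb
}

#' @rdname add_person
#' @export
add_assessment <- function(kb, assessment) {
  stopifnot(inherits(kb, "knowledge_base"),
            inherits(assessment, "assessment_record"))
  validate_assessment(assessment)
  if (assessment$assessment_id %in% kb$assessments$assessment_id) {
    stop("duplicate assessment_id: ", assessment$assessment_id,
         call. = FALSE)
  }
  kb$assessments <- rbind(kb$assessments, .assessment_to_row(assessment))
  kb
}

#' @rdname add_person
#' @export
link_assessment <- function(kb, person_id, assessment_id) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (!person_id %in% kb$persons$person_id) {
    stop("link endpoint does not resolve: person ", person_id, call. = FALSE)
  }
  if (!assessment_id %in% kb$assessments$assessment_id) {
    stop("link endpoint does not resolve: assessment ", assessment_id,
         call. = FALSE)
  }
  add <- data.frame(person_id = person_id, assessment_id = assessment_id,
                    stringsAsFactors = FALSE)
  kb$links <- unique(rbind(kb$links, add))
  kb
}

#' Store accessors (the three ABox partitions)
#'
#' `condition_store` deliberately exposes no person identifier: condition
#' facts are joinable to persons only through the link store.
#'
#' @param kb a `knowledge_base`.
#' @return a classed data.frame (`person_store`, `condition_store` with an
#'   `inferred` attribute, or `link_store`).
#' @export
person_store <- function(kb) {
  structure(kb$persons, class = c("person_store", "data.frame"))
}

#' @rdname person_store
#' @export
condition_store <- function(kb) {
  structure(kb$assessments, inferred = kb$inferred,
            class = c("condition_store", "data.frame"))
}

#' @rdname person_store
#' @export
link_store <- function(kb) {
  structure(kb$links, class = c("link_store", "data.frame"))
}

#' Project the stores into a fact base
#'
#' Persons become individuals typed by their gender class with a
#' date-of-birth property; assessments become health-condition
#' individuals carrying their assessment date, age (when known) and the
#' measured data properties; links become `isInHealthCondition`
#' assertions. Previously inferred condition classes are re-asserted so
#' evaluation is monotone across calls.
#'
#' @param kb a `knowledge_base`.
#' @param exclude_assessments assessment ids whose measured facts are
#'   withheld (used for per-assessment enrichment failures).
#' @return a [fact_base()].
#' @export
kb_to_facts <- function(kb, exclude_assessments = character(0)) {
  facts <- fact_base()
  for (i in seq_len(nrow(kb$persons))) {
    p <- kb$persons[i, ]
    facts <- assert_class(facts, p$person_id, p$gender)
    facts <- assert_property(facts, p$person_id, "hasDateOfBirth",
                             p$date_of_birth)
  }
  prop_of <- c(body_mass = "isCharacterizedByBodyMass",
               height = "isCharacterizedByHeight",
               body_mass_index = "isCharacterizedByBodyMassIndex",
               waist_circumference = "isCharacterizedByWaistCircumference",
               hip_circumference = "isCharacterizedByHipCircumference",
               waist_to_hip_ratio = "isCharacterizedByWaistToHipRatio",
               waist_to_height_ratio = "isCharacterizedByWaistToHeightRatio",
               body_fat_mass = "isCharacterizedByBodyFatMass")
  for (i in seq_len(nrow(kb$assessments))) {
    a <- kb$assessments[i, ]
    facts <- assert_class(facts, a$assessment_id, "HealthCondition")
    facts <- assert_property(facts, a$assessment_id, "isAssessedAtDate",
                             a$assessment_date)
    if (a$assessment_id %in% exclude_assessments) next
    if (!is.na(a$age_at_assessment)) {
      facts <- assert_property(facts, a$assessment_id, "isAssessedAtAge",
                               as.numeric(a$age_at_assessment))
    }
    for (f in names(prop_of)) {
      if (!is.na(a[[f]])) {
        facts <- assert_property(facts, a$assessment_id, prop_of[[f]],
                                 as.numeric(a[[f]]))
      }
    }
  }
  for (i in seq_len(nrow(kb$links))) {
    facts <- assert_property(facts, kb$links$person_id[i],
                             "isInHealthCondition", kb$links$assessment_id[i])
  }
  for (i in seq_len(nrow(kb$inferred))) {
    facts <- assert_class(facts, kb$inferred$assessment_id[i],
                          kb$inferred$class[i])
  }
  facts
}

#' Classify every linked assessment
#'
#' Enriches each linked assessment with its derived measures (failures
#' are collected per assessment in the `classify_log`, not fatal),
#' projects the stores into a fact base together with the taxonomy's
#' subsumption rules and every registered rule pack, evaluates to the
#' fixpoint, and writes the inferred condition classes (with rule and
#' binding provenance plus a generation timestamp) back into the
#' condition store. Idempotent, and monotone: previously inferred classes
#' are always preserved.
#'
#' @param kb a `knowledge_base` with a taxonomy and at least one
#'   registered rule pack.
#' @return the updated `knowledge_base`.
#' @export
classify_all <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (length(kb$rule_packs) == 0) {
    stop("no rule pack registered; nothing to classify with", call. = FALSE)
  }
  excluded <- character(0)
  persons_by_id <- kb$persons
  for (i in seq_len(nrow(kb$links))) {
    aid <- kb$links$assessment_id[i]
    pid <- kb$links$person_id[i]
    j <- match(aid, kb$assessments$assessment_id)
    p <- persons_by_id[match(pid, persons_by_id$person_id), ]
    res <- tryCatch({
      rec <- .row_to_assessment(kb$assessments[j, ])
      enrich_assessment(person_record(p$person_id, p$gender, p$date_of_birth),
                        rec)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, aid)
      kb$classify_log <- c(kb$classify_log,
                           paste0(aid, ": ", conditionMessage(res)))
    } else {
      kb$assessments[j, ] <- .assessment_to_row(res)
    }
  }
  facts <- kb_to_facts(kb, exclude_assessments = excluded)
  rules <- c(rules_from_taxonomy(kb$taxonomy),
             unlist(lapply(kb$rule_packs, function(p) p$rules),
                    recursive = FALSE))
  facts <- evaluate_to_fixpoint(rules, facts)
  ic <- facts$inferred_classes
  ic <- ic[ic$individual %in% kb$assessments$assessment_id &
             ic$class %in% kb$taxonomy$classes$name, , drop = FALSE]
  if (nrow(ic) > 0) {
    new <- data.frame(assessment_id = ic$individual, class = ic$class,
                      rule_id = ic$rule_id, binding = ic$binding,
                      antecedent = ic$antecedent,
                      inferred_at = format(Sys.time(), tz = "UTC",
                                           usetz = TRUE),
                      stringsAsFactors = FALSE)
    keep <- !paste(new$assessment_id, new$class) %in%
      paste(kb$inferred$assessment_id, kb$inferred$class)
    kb$inferred <- rbind(kb$inferred, new[keep, , drop = FALSE])
  }
  kb
}

#' Explain an inferred condition class
#'
#' @param kb a classified `knowledge_base`.
#' @param assessment_id an assessment identifier.
#' @param class_name optional: restrict to one condition class.
#' @return data.frame of provenance records (class, rule id, binding and
#'   grounded antecedent as JSON, generation timestamp).
#' @export
explain_condition <- function(kb, assessment_id, class_name = NULL) {
  if (!assessment_id %in% kb$assessments$assessment_id) {
    stop("unknown assessment: ", assessment_id, call. = FALSE)
  }
  out <- kb$inferred[kb$inferred$assessment_id == assessment_id, ,
                     drop = FALSE]
  if (!is.null(class_name)) {
    out <- out[out$class == canonical_class_name(class_name), , drop = FALSE]
  }
  out
}

#' Merge a module into a knowledge base
#'
#' Accepts a `person_store`, `condition_store`, `link_store`,
#' [rule_pack()] or another `knowledge_base`. Union semantics: identical
#' records under the same id are idempotent, conflicting records raise a
#' merge-conflict error, and previously inferred facts are preserved
#' unchanged.
#'
#' @param kb a `knowledge_base`.
#' @param module the module to merge.
#' @return the updated `knowledge_base`.
#' @export
merge_modules <- function(kb, module) {
  stopifnot(inherits(kb, "knowledge_base"))
  merge_df <- function(cur, new, id_col, what) {
    new <- as.data.frame(new, stringsAsFactors = FALSE)
    for (id in new[[id_col]][new[[id_col]] %in% cur[[id_col]]]) {
      a <- cur[cur[[id_col]] == id, , drop = FALSE]
      b <- new[new[[id_col]] == id, names(cur), drop = FALSE]
      rownames(a) <- rownames(b) <- NULL
      if (!isTRUE(all.equal(a, b, check.attributes = FALSE))) {
        stop("merge conflict for ", what, " id ", id, call. = FALSE)
      }
    }
    unique(rbind(cur, new[, names(cur), drop = FALSE]))
  }
  if (inherits(module, "rule_pack")) {
    return(register_rule_pack(kb, module))
  }
  if (inherits(module, "person_store")) {
    kb$persons <- merge_df(kb$persons, module, "person_id", "person")
    return(kb)
  }
  if (inherits(module, "condition_store")) {
    kb$assessments <- merge_df(kb$assessments, module, "assessment_id",
                               "assessment")
    inf <- attr(module, "inferred")
    if (!is.null(inf) && nrow(inf) > 0) {
      keep <- !paste(inf$assessment_id, inf$class) %in%
        paste(kb$inferred$assessment_id, kb$inferred$class)
      kb$inferred <- rbind(kb$inferred, inf[keep, , drop = FALSE])
    }
    return(kb)
  }
  if (inherits(module, "link_store")) {
    links <- as.data.frame(module, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(links))) {
      kb <- link_assessment(kb, links$person_id[i], links$assessment_id[i])
    }
    return(kb)
  }
  if (inherits(module, "knowledge_base")) {
    kb$persons <- merge_df(kb$persons, module$persons, "person_id", "person")
    kb$assessments <- merge_df(kb$assessments, module$assessments,
                               "assessment_id", "assessment")
    kb$links <- unique(rbind(kb$links, module$links))
    keep <- !paste(module$inferred$assessment_id, module$inferred$class) %in%
      paste(kb$inferred$assessment_id, kb$inferred$class)
    kb$inferred <- rbind(kb$inferred, module$inferred[keep, , drop = FALSE])
    for (p in module$rule_packs) kb <- register_rule_pack(kb, p)
    return(kb)
  }
  stop("cannot merge object of class ", paste(class(module), collapse = "/"),
       call. = FALSE)
}

#' Query a person's assessed conditions over time
#'
#' @param kb a `knowledge_base`.
#' @param person_id a person identifier.
#' @param as_of optional date: only assessments on or before this date.
#' @param class_filter optional condition class: keep inferred classes
#'   that are subclasses of it (taxonomy subsumption, reflexive).
#' @return list with one element per assessment (sorted by assessment
#'   date), each a list of `assessment` (one-row data.frame) and
#'   `classes` (character vector of matching inferred classes).
#' @export
query_conditions <- function(kb, person_id, as_of = NULL,
                             class_filter = NULL) {
  if (!person_id %in% kb$persons$person_id) {
    stop("unknown person: ", person_id, call. = FALSE)
  }
  aids <- kb$links$assessment_id[kb$links$person_id == person_id]
  rows <- kb$assessments[kb$assessments$assessment_id %in% aids, ,
                         drop = FALSE]
  rows <- rows[order(as.Date(rows$assessment_date)), , drop = FALSE]
  if (!is.null(as_of)) {
    rows <- rows[as.Date(rows$assessment_date) <= as.Date(as_of), ,
                 drop = FALSE]
  }
  lapply(seq_len(nrow(rows)), function(i) {
    aid <- rows$assessment_id[i]
    cls <- kb$inferred$class[kb$inferred$assessment_id == aid]
    if (!is.null(class_filter)) {
      cls <- cls[vapply(cls, function(cl) {
        is_subclass_of(kb$taxonomy, cl, class_filter)
      }, logical(1))]
    }
    list(assessment = rows[i, , drop = FALSE], classes = unname(cls))
  })
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>\n",
      " persons:     ", nrow(x$persons), "\n",
      " assessments: ", nrow(x$assessments), "\n",
      " links:       ", nrow(x$links), "\n",
      " inferred:    ", nrow(x$inferred), " condition classes\n",
      " rule packs:  ", paste(names(x$rule_packs), collapse = ", "), "\n",
      sep = "")
  if (length(x$classify_log) > 0) {
    cat("  classify log:", length(x$classify_log), "entries\n")
  }
  invisible(x)
}
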