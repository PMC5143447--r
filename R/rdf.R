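#' @title RDF export and knowledge-base persistence
#' @description
#' The knowledge base exports to Turtle or N-Triples under a stable IRI
#' scheme (a project base namespace plus the opaque record ids), so
#' repeated exports of an unchanged knowledge base are byte-identical.
#' Inferred condition classes are exported both as `rdf:type` assertions
#' and under the `inferredCondition` annotation property, which is what
#' distinguishes them from asserted types on re-import.
#'
#' Persistence follows the ABox partition: one N-Triples file per
#' partition (`persons.nt`, `conditions.nt`, `links.nt`) plus a JSON
#' manifest carrying the import graph and the inference provenance
#' (which plain triples cannot express without reification).
#' @name rdf
NULL

PKB_BASE <- "http://example.org/phenokb#"
.RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
.RDFS_SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
.XSD <- "http://www.w3.org/2001/XMLSchema#"

.iri <- function(local) paste0(PKB_BASE, local)

.triple <- function(s, p, o, literal = FALSE, datatype = NA_character_) {
  data.frame(subject = s, predicate = p, object = o, is_literal = literal,
             datatype = datatype, stringsAsFactors = FALSE)
}

.measure_props <- c(
  body_mass = "isCharacterizedByBodyMass",
  height = "isCharacterizedByHeight",
  body_mass_index = "isCharacterizedByBodyMassIndex",
  waist_circumference = "isCharacterizedByWaistCircumference",
  hip_circumference = "isCharacterizedByHipCircumference",
  waist_to_hip_ratio = "isCharacterizedByWaistToHipRatio",
  waist_to_height_ratio = "isCharacterizedByWaistToHeightRatio",
  body_fat_mass = "isCharacterizedByBodyFatMass")

#' Project a knowledge base into RDF triples
#'
#' @param kb a [knowledge_base()].
#' @param parts which graph parts to include (default all): `"tbox"`
#'   (taxonomy subclass-of triples), `"persons"`, `"conditions"`,
#'   `"links"`.
#' @return a data.frame of triples (`subject`, `predicate`, `object`,
#'   `is_literal`, `datatype`), sorted for stable output.
#' @export
kb_triples <- function(kb, parts = c("tbox", "persons", "conditions",
                                     "links")) {
  out <- list()
  if ("tbox" %in% parts) {
    cl <- kb$taxonomy$classes
    edges <- cl[!is.na(cl$parent), , drop = FALSE]
    for (i in seq_len(nrow(edges))) {
      out[[length(out) + 1L]] <- .triple(.iri(edges$name[i]), .RDFS_SUBCLASS,
                                         .iri(edges$parent[i]))
    }
  }
  if ("persons" %in% parts) {
    for (i in seq_len(nrow(kb$persons))) {
      p <- kb$persons[i, ]
      s <- .iri(paste0("person-", p$person_id))
      out[[length(out) + 1L]] <- .triple(s, .RDF_TYPE, .iri(p$gender))
      out[[length(out) + 1L]] <- .triple(s, .iri("hasDateOfBirth"),
                                         p$date_of_birth, literal = TRUE,
                                         datatype = paste0(.XSD, "date"))
    }
  }
  if ("conditions" %in% parts) {
    for (i in seq_len(nrow(kb$assessments))) {
      a <- kb$assessments[i, ]
      s <- .iri(paste0("assessment-", a$assessment_id))
      out[[length(out) + 1L]] <- .triple(s, .RDF_TYPE,
                                         .iri("HealthCondition"))
      out[[length(out) + 1L]] <- .triple(s, .iri("isAssessedAtDate"),
                                         a$assessment_date, literal = TRUE,
                                         datatype = paste0(.XSD, "date"))
      if (!is.na(a$age_at_assessment)) {
        out[[length(out) + 1L]] <- .triple(
          s, .iri("isAssessedAtAge"), fmt_num(a$age_at_assessment),
          literal = TRUE, datatype = paste0(.XSD, "integer"))
      }
      for (f in names(.measure_props)) {
        if (!is.na(a[[f]])) {
          out[[length(out) + 1L]] <- .triple(
            s, .iri(.measure_props[[f]]), fmt_num(a[[f]]), literal = TRUE,
            datatype = paste0(.XSD, "decimal"))
        }
      }
    }
    for (i in seq_len(nrow(kb$inferred))) {
      s <- .iri(paste0("assessment-", kb$inferred$assessment_id[i]))
      cls <- .iri(kb$inferred$class[i])
      out[[length(out) + 1L]] <- .triple(s, .RDF_TYPE, cls)
      out[[length(out) + 1L]] <- .triple(s, .iri("inferredCondition"), cls)
    }
  }
  if ("links" %in% parts) {
    for (i in seq_len(nrow(kb$links))) {
      out[[length(out) + 1L]] <- .triple(
        .iri(paste0("person-", kb$links$person_id[i])),
        .iri("isInHealthCondition"),
        .iri(paste0("assessment-", kb$links$assessment_id[i])))
    }
  }
  tr <- if (length(out) == 0) {
    .triple(character(0), character(0), character(0), logical(0),
            character(0))
  } else {
    unique(do.call(rbind, out))
  }
  tr[order(tr$subject, tr$predicate, tr$object), , drop = FALSE]
}

.nt_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  gsub('"', '\\\\"', x)
}

.format_object_nt <- function(tr) {
  ifelse(tr$is_literal,
         paste0('"', .nt_escape(tr$object), '"',
                ifelse(is.na(tr$datatype), "",
                       paste0("^^<", tr$datatype, ">"))),
         paste0("<", tr$object, ">"))
}

.write_ntriples <- function(tr, path) {
  lines <- paste0("<", tr$subject, "> <", tr$predicate, "> ",
                  .format_object_nt(tr), " .")
  writeLines(lines, path)
}

.qname <- function(iri) {
  if (is.na(iri)) return("")  # vectorised callers guard with ifelse
  pre <- c(pk = PKB_BASE,
           rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
           rdfs = "http://www.w3.org/2000/01/rdf-schema#",
           xsd = .XSD)
  for (p in names(pre)) {
    if (startsWith(iri, pre[[p]])) {
      local <- substring(iri, nchar(pre[[p]]) + 1)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local)) {
        return(paste0(p, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

.write_turtle <- function(tr, path) {
  header <- c(paste0("@prefix pk: <", PKB_BASE, "> ."),
              "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
              "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
              paste0("@prefix xsd: <", .XSD, "> ."),
              "")
  obj <- ifelse(tr$is_literal,
                paste0('"', .nt_escape(tr$object), '"',
                       ifelse(is.na(tr$datatype), "",
                              paste0("^^",
                                     vapply(tr$datatype, .qname,
                                            character(1))))),
                vapply(tr$object, .qname, character(1)))
  lines <- paste0(vapply(tr$subject, .qname, character(1)), " ",
                  vapply(tr$predicate, .qname, character(1)), " ", obj, " .")
  writeLines(c(header, lines), path)
}

#' Export a knowledge base as RDF
#'
#' @param kb a [knowledge_base()].
#' @param path output file.
#' @param syntax `"turtle"` or `"ntriples"`.
#' @param parts see [kb_triples()].
#' @return `path` invisibly.
#' @export
export_rdf <- function(kb, path, syntax = c("turtle", "ntriples"),
                       parts = c("tbox", "persons", "conditions", "links")) {
  syntax <- match.arg(syntax)
  tr <- kb_triples(kb, parts)
  if (syntax == "ntriples") .write_ntriples(tr, path)
  else .write_turtle(tr, path)
  invisible(path)
}

#' Read an N-Triples file
#'
#' Minimal reader for the line-based N-Triples subset this package
#' writes (IRIs and typed/plain literals; no blank nodes).
#'
#' @param path an N-Triples file.
#' @return a triple data.frame in the [kb_triples()] layout.
#' @export
read_ntriples <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pat <- paste0("^<([^>]*)>\\s+<([^>]*)>\\s+",
                "(?:<([^>]*)>|\"((?:[^\"\\\\]|\\\\.)*)\"",
                "(?:\\^\\^<([^>]*)>)?)\\s*\\.\\s*$")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad) > 0) {
    stop("unparseable N-Triples line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  unesc <- function(x) gsub('\\\\"', '"', gsub("\\\\\\\\", "\\\\", x))
  tr <- do.call(rbind, lapply(m, function(g) {
    if (nzchar(g[4])) {
      .triple(g[2], g[3], g[4])
    } else {
      .triple(g[2], g[3], unesc(g[5]), literal = TRUE,
              datatype = if (nzchar(g[6])) g[6] else NA_character_)
    }
  }))
  tr[order(tr$subject, tr$predicate, tr$object), , drop = FALSE]
}

#' Persist / load a knowledge base on disk
#'
#' Writes one N-Triples file per ABox partition (`persons.nt`,
#' `conditions.nt`, `links.nt`), the taxonomy (`taxonomy.json`), each
#' registered rule pack (`pack-<id>.yaml`), and `manifest.json` with the
#' import graph and inference provenance.
#'
#' @param kb a [knowledge_base()].
#' @param dir target directory (created if needed).
#' @return `save_kb` returns `dir` invisibly; `load_kb` returns the
#'   reconstructed `knowledge_base`.
#' @export
save_kb <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_ntriples(kb_triples(kb, "persons"), file.path(dir, "persons.nt"))
  .write_ntriples(kb_triples(kb, "conditions"),
                  file.path(dir, "conditions.nt"))
  .write_ntriples(kb_triples(kb, "links"), file.path(dir, "links.nt"))
  write_taxonomy(kb$taxonomy, file.path(dir, "taxonomy.json"))
  for (pid in names(kb$rule_packs)) {
    save_rule_pack(kb$rule_packs[[pid]],
                   file.path(dir, paste0("pack-", pid, ".yaml")))
  }
  manifest <- list(
    format = "phenokb-kb",
    import_graph = kb$import_graph,
    packs = as.list(names(kb$rule_packs)),
    inferred = if (nrow(kb$inferred) == 0) list() else
      lapply(seq_len(nrow(kb$inferred)), function(i) as.list(kb$inferred[i, ])),
    classify_log = as.list(kb$classify_log))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.strip_iri <- function(x, prefix) {
  sub(paste0("^", PKB_BASE, prefix), "", x)
}

#' @rdname save_kb
#' @export
load_kb <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  graph <- lapply(manifest$import_graph, function(v) {
    as.character(unlist(v))
  })
  kb <- knowledge_base(taxonomy = read_taxonomy(file.path(dir,
                                                          "taxonomy.json")),
                       import_graph = graph)
  for (pid in unlist(manifest$packs)) {
    kb <- register_rule_pack(
      kb, load_rule_pack(file.path(dir, paste0("pack-", pid, ".yaml"))))
  }
  ptr <- read_ntriples(file.path(dir, "persons.nt"))
  pids <- unique(.strip_iri(ptr$subject, "person-"))
  for (pid in pids) {
    sub <- ptr[ptr$subject == .iri(paste0("person-", pid)), ]
    gender <- .strip_iri(sub$object[sub$predicate == .RDF_TYPE], "")
    dob <- sub$object[sub$predicate == .iri("hasDateOfBirth")]
    kb <- add_person(kb, person_record(pid, gender, dob))
  }
  ctr <- read_ntriples(file.path(dir, "conditions.nt"))
  aids <- unique(.strip_iri(ctr$subject, "assessment-"))
  inv_props <- stats::setNames(names(.measure_props),
                               vapply(.measure_props, .iri, character(1)))
  for (aid in aids) {
    sub <- ctr[ctr$subject == .iri(paste0("assessment-", aid)), ]
    args <- list(assessment_id = aid,
                 assessment_date = sub$object[
                   sub$predicate == .iri("isAssessedAtDate")][1])
    age <- sub$object[sub$predicate == .iri("isAssessedAtAge")]
    if (length(age) == 1) args$age_at_assessment <- as.integer(age)
    for (i in seq_len(nrow(sub))) {
      f <- inv_props[sub$predicate[i]]
      if (!is.na(f)) args[[f]] <- as.numeric(sub$object[i])
    }
    kb <- add_assessment(kb, do.call(assessment_record, args))
  }
  ltr <- read_ntriples(file.path(dir, "links.nt"))
  for (i in seq_len(nrow(ltr))) {
    kb <- link_assessment(kb, .strip_iri(ltr$subject[i], "person-"),
                          .strip_iri(ltr$object[i], "assessment-"))
  }
  if (length(manifest$inferred) > 0) {
    kb$inferred <- do.call(rbind, lapply(manifest$inferred, function(r) {
      data.frame(assessment_id = r$assessment_id, class = r$class,
                 rule_id = r$rule_id, binding = r$binding,
                 antecedent = r$antecedent, inferred_at = r$inferred_at,
                 stringsAsFactors = FALSE)
    }))
  }
  kb$classify_log <- as.character(unlist(manifest$classify_log))
  kb
}
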