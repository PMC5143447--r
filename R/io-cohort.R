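#' @title Cohort file readers and writers
#' @description
#' Data dictionary (units fixed): `persons` has `person_id`, `gender`
#' (`Male`/`Female`), `date_of_birth` (ISO-8601); `assessments` has
#' `assessment_id`, `assessment_date` (ISO-8601) and the optional numeric
#' measurements `body_mass` (kg), `height` (m), `body_mass_index`
#' (kg/m^2), `waist_circumference` (cm), `hip_circumference` (cm),
#' `waist_to_hip_ratio`, `waist_to_height_ratio`, `body_fat_mass`
#' (percent), `age_at_assessment` (completed years); `links` has
#' `person_id`, `assessment_id`. CSV dialect: UTF-8, comma-separated,
#' header required, dot decimal separator, empty cell for a missing
#' value.
#' @name io_cohort
NULL

.cohort_files <- c(persons = "persons.csv", assessments = "assessments.csv",
                   links = "links.csv")

.build_cohort <- function(persons_df, assessments_df, links_df, where) {
  errors <- character(0)
  persons <- list()
  for (i in seq_len(nrow(persons_df))) {
    r <- persons_df[i, ]
    res <- tryCatch(person_record(as.character(r$person_id),
                                  as.character(r$gender),
                                  as.character(r$date_of_birth)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(where$persons, " row ", i, ": ",
                                 conditionMessage(res)))
    } else {
      persons[[length(persons) + 1L]] <- res
    }
  }
  assessments <- list()
  num <- function(x) if (is.null(x) || is.na(x) || x == "") NA_real_
                     else as.numeric(x)
  for (i in seq_len(nrow(assessments_df))) {
    r <- assessments_df[i, ]
    res <- tryCatch({
      args <- list(assessment_id = as.character(r$assessment_id),
                   assessment_date = as.character(r$assessment_date))
      for (f in .MEASURE_FIELDS) {
        args[[f]] <- if (f %in% names(r)) num(r[[f]]) else NA_real_
      }
      if ("age_at_assessment" %in% names(r)) {
        v <- num(r$age_at_assessment)
        args$age_at_assessment <- if (is.na(v)) NA_integer_ else as.integer(v)
      }
      do.call(assessment_record, args)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(where$assessments, " row ", i, ": ",
                                 conditionMessage(res)))
    } else {
      assessments[[length(assessments) + 1L]] <- res
    }
  }
  links <- if (nrow(links_df) > 0) {
    data.frame(person_id = as.character(links_df$person_id),
               assessment_id = as.character(links_df$assessment_id),
               stringsAsFactors = FALSE)
  } else {
    .empty_links()
  }
  if (length(errors) > 0) {
    stop("cohort validation failed:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  list(persons = persons, assessments = assessments, links = links)
}

#' Read a cohort from CSV files or a JSON document
#'
#' CSV format expects a directory containing `persons.csv`,
#' `assessments.csv` and `links.csv`; JSON expects a single file with
#' `persons`, `assessments` and `links` arrays. Every row is validated;
#' failures are reported together with their file and row number.
#'
#' @param path directory (csv) or file (json).
#' @param format `"csv"` or `"json"` (default: inferred from `path`).
#' @return list with elements `persons` (list of [person_record()]s),
#'   `assessments` (list of [assessment_record()]s) and `links`
#'   (data.frame).
#' @export
read_cohort <- function(path, format = if (grepl("\\.json$", path)) "json"
                                       else "csv") {
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    files <- file.path(path, .cohort_files)
    names(files) <- names(.cohort_files)
    for (f in files) {
      if (!file.exists(f)) stop("missing cohort file: ", f, call. = FALSE)
    }
    .build_cohort(
      utils::read.csv(files["persons"], stringsAsFactors = FALSE,
                      colClasses = "character"),
      utils::read.csv(files["assessments"], stringsAsFactors = FALSE,
                      colClasses = "character"),
      utils::read.csv(files["links"], stringsAsFactors = FALSE,
                      colClasses = "character"),
      where = list(persons = "persons.csv", assessments = "assessments.csv"))
  } else {
    doc <- jsonlite::read_json(path)
    to_df <- function(recs) {
      if (length(recs) == 0) return(data.frame())
      cols <- unique(unlist(lapply(recs, names)))
      as.data.frame(stats::setNames(lapply(cols, function(cn) {
        vapply(recs, function(r) {
          v <- r[[cn]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))
      }), cols), stringsAsFactors = FALSE)
    }
    .build_cohort(to_df(doc$persons), to_df(doc$assessments),
                  to_df(doc$links),
                  where = list(persons = "persons[]",
                               assessments = "assessments[]"))
  }
}

.persons_to_df <- function(persons) {
  if (length(persons) == 0) return(.empty_persons())
  do.call(rbind, lapply(persons, function(p) {
    data.frame(person_id = p$person_id, gender = p$gender,
               date_of_birth = format(p$date_of_birth),
               stringsAsFactors = FALSE)
  }))
}

.assessments_to_df <- function(assessments) {
  if (length(assessments) == 0) return(.empty_assessments())
  do.call(rbind, lapply(assessments, .assessment_to_row))
}

#' Write a cohort to CSV files or a JSON document
#' @param cohort list as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param path directory (csv; created if needed) or file (json).
#' @param format `"csv"` or `"json"` (default: inferred from `path`).
#' @return `path` invisibly.
#' @export
write_cohort <- function(cohort, path,
                         format = if (grepl("\\.json$", path)) "json"
                                  else "csv") {
  format <- match.arg(format, c("csv", "json"))
  pdf <- .persons_to_df(cohort$persons)
  adf <- .assessments_to_df(cohort$assessments)
  ldf <- cohort$links
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pdf, file.path(path, "persons.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(adf, file.path(path, "assessments.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(ldf, file.path(path, "links.csv"),
                     row.names = FALSE, na = "")
  } else {
    strip_na <- function(df) {
      lapply(seq_len(nrow(df)), function(i) {
        row <- as.list(df[i, , drop = FALSE])
        row[!vapply(row, function(v) is.na(v), logical(1))]
      })
    }
    jsonlite::write_json(list(persons = strip_na(pdf),
                              assessments = strip_na(adf),
                              links = strip_na(ldf)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load a cohort into a knowledge base
#' @param kb a [knowledge_base()].
#' @param cohort list as returned by [read_cohort()].
#' @return the updated `knowledge_base`.
#' @export
add_cohort <- function(kb, cohort) {
  for (p in cohort$persons) kb <- add_person(kb, p)
  for (a in cohort$assessments) kb <- add_assessment(kb, a)
  for (i in seq_len(nrow(cohort$links))) {
    kb <- link_assessment(kb, cohort$links$person_id[i],
                          cohort$links$assessment_id[i])
  }
  kb
}
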