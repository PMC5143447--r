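#' @title Reference-value tables
#' @description
#' Rule generation is table-driven: each rule family (body mass, fat
#' distribution, central obesity, adiposity) is produced from a table of
#' (gender, age band, class, bound) entries, so that updated cutoffs —
#' the part of the knowledge that changes as reference standards evolve —
#' never require touching code, only data.
#'
#' The shipped default cutoffs are a clearly-labelled WHO-2007-style
#' *fixture*: growth-reference-shaped but synthetic, not authoritative
#' values (the printed 0.85 female android waist-to-hip threshold and the
#' 13-17 age band are the exception). Units: BMI kg/m^2, circumferences
#' cm, ratios dimensionless, body fat percent.
#' @name reference_tables
NULL

.FAMILIES <- c("body_mass", "fat_distribution", "central_obesity", "adiposity")
.BOUND_KINDS <- c("lower_inclusive", "upper_exclusive", "interval")
.CRITERIA <- c(bmi = "isCharacterizedByBodyMassIndex",
               whr = "isCharacterizedByWaistToHipRatio",
               wc = "isCharacterizedByWaistCircumference",
               whtr = "isCharacterizedByWaistToHeightRatio",
               bfm = "isCharacterizedByBodyFatMass")
.FAMILY_CRITERIA <- list(body_mass = "bmi", fat_distribution = "whr",
                         central_obesity = c("whr", "wc", "whtr"),
                         adiposity = "bfm")

#' Construct a reference table
#'
#' @param family one of `"body_mass"`, `"fat_distribution"`,
#'   `"central_obesity"`, `"adiposity"`.
#' @param entries data.frame with columns `gender`, `age_min`, `age_max`
#'   (completed years, inclusive), `class` (consequent condition class),
#'   `criterion` (one of `bmi`, `whr`, `wc`, `whtr`, `bfm`), `bound_kind`
#'   (`lower_inclusive` / `upper_exclusive` / `interval`), `value_1`,
#'   `value_2` (`NA` unless `interval`).
#' @param citation free-text source annotation.
#' @return an object of class `reference_table`.
#' @export
reference_table <- function(family, entries, citation = "") {
  stopifnot(is.data.frame(entries))
  need <- c("gender", "age_min", "age_max", "class", "criterion",
            "bound_kind", "value_1", "value_2")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols) > 0) {
    stop("reference table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  entries$class <- canonical_class_name(as.character(entries$class))
  structure(list(family = family, entries = entries,
                 citation = as.character(citation)),
            class = "reference_table")
}

#' Validate a reference table
#'
#' Checks (violations are returned as data): known family/gender/
#' criterion/bound kind; strictly positive thresholds; for the body-mass
#' family, that per (gender, covered age) the class intervals partition
#' the positive BMI axis with no gaps or overlaps; non-overlapping age
#' bands within (gender, class, criterion); and growth-reference shape
#' (obesity-class lower bounds non-decreasing in age within gender).
#'
#' @param table a `reference_table`.
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_reference_table <- function(table) {
  out <- character(0)
  e <- table$entries
  if (!table$family %in% .FAMILIES) {
    return(paste0("unknown family: ", table$family))
  }
  if (!all(e$gender %in% c("Male", "Female"))) {
    out <- c(out, "gender must be Male or Female")
  }
  if (!all(e$criterion %in% .FAMILY_CRITERIA[[table$family]])) {
    out <- c(out, paste0("criterion not allowed for family ", table$family))
  }
  if (!all(e$bound_kind %in% .BOUND_KINDS)) {
    out <- c(out, "unknown bound_kind")
  }
  if (any(!is.finite(e$value_1) | e$value_1 <= 0)) {
    out <- c(out, "value_1 must be strictly positive")
  }
  iv <- e$bound_kind == "interval"
  if (any(iv & (!is.finite(e$value_2) | e$value_2 <= e$value_1))) {
    out <- c(out, "interval entries need value_2 > value_1")
  }
  if (any(e$age_min > e$age_max)) out <- c(out, "age_min > age_max")
  # non-overlapping age bands within (gender, class, criterion)
  key <- paste(e$gender, e$class, e$criterion)
  for (k in unique(key)) {
    sub <- e[key == k, , drop = FALSE]
    sub <- sub[order(sub$age_min), , drop = FALSE]
    if (nrow(sub) > 1 &&
        any(sub$age_min[-1] <= sub$age_max[-nrow(sub)])) {
      out <- c(out, paste0("overlapping age bands for ", k))
    }
  }
  if (table$family == "body_mass") {
    out <- c(out, .validate_bmi_partition(e))
  }
  # growth-reference shape: obesity-class lower bounds non-decreasing in age
  mono_class <- switch(table$family,
    body_mass = "ObeseCondition",
    central_obesity = "CentralObesityCondition",
    adiposity = "AdiposityCondition",
    NA_character_)
  if (!is.na(mono_class)) {
    sub <- e[e$class == mono_class &
               e$bound_kind %in% c("lower_inclusive", "interval"), ,
             drop = FALSE]
    for (k in unique(paste(sub$gender, sub$criterion))) {
      s2 <- sub[paste(sub$gender, sub$criterion) == k, , drop = FALSE]
      s2 <- s2[order(s2$age_min), , drop = FALSE]
      if (is.unsorted(s2$value_1)) {
        out <- c(out, paste0("lower bound decreasing in age for ", k))
      }
    }
  }
  unique(out)
}

.validate_bmi_partition <- function(e) {
  out <- character(0)
  for (g in unique(e$gender)) {
    sub <- e[e$gender == g, , drop = FALSE]
    for (age in seq(min(sub$age_min), max(sub$age_max))) {
      cov <- sub[sub$age_min <= age & age <= sub$age_max, , drop = FALSE]
      if (nrow(cov) == 0) next
      where <- paste0(g, " age ", age)
      if (sum(cov$bound_kind == "upper_exclusive") != 1 ||
          sum(cov$bound_kind == "lower_inclusive") != 1) {
        out <- c(out, paste0("BMI classes for ", where,
                             " need one open-below and one open-above entry"))
        next
      }
      lo <- ifelse(cov$bound_kind == "upper_exclusive", 0, cov$value_1)
      hi <- ifelse(cov$bound_kind == "lower_inclusive", Inf,
                   ifelse(cov$bound_kind == "upper_exclusive", cov$value_1,
                          cov$value_2))
      ord <- order(lo)
      if (any(abs(hi[ord][-length(ord)] - lo[ord][-1]) > 1e-9)) {
        out <- c(out, paste0("BMI intervals for ", where,
                             " do not partition the axis"))
      }
      if (anyDuplicated(cov$class)) {
        out <- c(out, paste0("duplicate BMI class for ", where))
      }
    }
  }
  out
}

#' The default (fixture) reference tables
#'
#' WHO-2007-style synthetic cutoffs covering ages 11-17 (body mass, one
#' year per band) and 10-19 (other families). The female android
#' waist-to-hip threshold 0.85 over ages 13-17 is the documented
#' reference value; the male android threshold 0.90 and all other
#' cutoffs are implementer-supplied fixtures.
#'
#' @return named list of `reference_table`s, one per family.
#' @export
default_reference_tables <- function() {
  ent <- function(gender, age_min, age_max, class, criterion, bound_kind,
                  value_1, value_2 = NA_real_) {
    data.frame(gender = gender, age_min = age_min, age_max = age_max,
               class = class, criterion = criterion, bound_kind = bound_kind,
               value_1 = value_1, value_2 = value_2, stringsAsFactors = FALSE)
  }
  ages <- 11:17
  # per-age cutoffs (thinness / overweight / obesity bounds), growth-shaped
  male_cut <- list(u = c(14.1, 14.5, 14.9, 15.5, 16.0, 16.5, 17.0),
                   n = c(19.2, 20.0, 20.8, 21.8, 22.7, 23.5, 24.3),
                   o = c(21.2, 22.1, 23.1, 24.0, 24.8, 25.6, 26.3))
  female_cut <- list(u = c(13.8, 14.2, 14.7, 15.2, 15.7, 16.1, 16.4),
                     n = c(19.9, 20.8, 21.8, 22.6, 23.3, 23.7, 23.9),
                     o = c(22.1, 23.4, 24.4, 25.2, 25.9, 26.4, 26.7))
  bm <- list()
  for (g in c("Male", "Female")) {
    cut <- if (g == "Male") male_cut else female_cut
    for (i in seq_along(ages)) {
      a <- ages[i]
      bm[[length(bm) + 1L]] <- rbind(
        ent(g, a, a, "UnderweightCondition", "bmi", "upper_exclusive",
            cut$u[i]),
        ent(g, a, a, "NormalWeightCondition", "bmi", "interval",
            cut$u[i], cut$n[i]),
        ent(g, a, a, "OverweightCondition", "bmi", "interval",
            cut$n[i], cut$o[i]),
        ent(g, a, a, "ObeseCondition", "bmi", "lower_inclusive", cut$o[i]))
    }
  }
  fd <- rbind(
    ent("Female", 13, 17, "AndroidCondition", "whr", "lower_inclusive", 0.85),
    ent("Female", 13, 17, "GynoidCondition", "whr", "upper_exclusive", 0.85),
    ent("Male", 13, 17, "AndroidCondition", "whr", "lower_inclusive", 0.90),
    ent("Male", 13, 17, "GynoidCondition", "whr", "upper_exclusive", 0.90))
  co <- rbind(
    ent("Female", 10, 19, "CentralObesityCondition", "whr",
        "lower_inclusive", 0.85),
    ent("Female", 10, 14, "CentralObesityCondition", "wc",
        "lower_inclusive", 75),
    ent("Female", 15, 19, "CentralObesityCondition", "wc",
        "lower_inclusive", 80),
    ent("Female", 10, 19, "CentralObesityCondition", "whtr",
        "lower_inclusive", 0.5),
    ent("Male", 10, 19, "CentralObesityCondition", "whr",
        "lower_inclusive", 0.90),
    ent("Male", 10, 14, "CentralObesityCondition", "wc",
        "lower_inclusive", 78),
    ent("Male", 15, 19, "CentralObesityCondition", "wc",
        "lower_inclusive", 84),
    ent("Male", 10, 19, "CentralObesityCondition", "whtr",
        "lower_inclusive", 0.5))
  ad <- rbind(
    ent("Female", 10, 12, "AdiposityCondition", "bfm", "lower_inclusive", 30),
    ent("Female", 13, 14, "AdiposityCondition", "bfm", "lower_inclusive", 30.5),
    ent("Female", 15, 16, "AdiposityCondition", "bfm", "lower_inclusive", 31),
    ent("Female", 17, 19, "AdiposityCondition", "bfm", "lower_inclusive", 31.5),
    ent("Male", 10, 12, "AdiposityCondition", "bfm", "lower_inclusive", 20),
    ent("Male", 13, 14, "AdiposityCondition", "bfm", "lower_inclusive", 20.5),
    ent("Male", 15, 16, "AdiposityCondition", "bfm", "lower_inclusive", 21),
    ent("Male", 17, 19, "AdiposityCondition", "bfm", "lower_inclusive", 21.5))
  cite <- "synthetic WHO-2007-style fixture; not authoritative reference data"
  list(
    body_mass = reference_table("body_mass", do.call(rbind, bm), cite),
    fat_distribution = reference_table(
      "fat_distribution", fd,
      paste("female android threshold 0.85, ages 13-17 (documented reference",
            "value); male threshold 0.90 implementer-supplied")),
    central_obesity = reference_table("central_obesity", co, cite),
    adiposity = reference_table("adiposity", ad, cite))
}

#' Write reference tables to a single CSV file
#' @param tables named list of `reference_table`s.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_reference_tables <- function(tables, path) {
  rows <- lapply(tables, function(tb) {
    e <- tb$entries
    e$family <- tb$family
    e$citation <- tb$citation
    e[, c("family", "gender", "age_min", "age_max", "class", "criterion",
          "bound_kind", "value_1", "value_2", "citation")]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read reference tables from CSV (or YAML)
#' @param path a CSV file as written by [write_reference_tables()], or a
#'   YAML file with `family`, `citation`, `entries` records.
#' @return named list of `reference_table`s keyed by family.
#' @export
read_reference_tables <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    docs <- yaml::read_yaml(path)
    out <- lapply(docs, function(d) {
      e <- do.call(rbind, lapply(d$entries, function(r) {
        data.frame(gender = r$gender, age_min = r$age_min,
                   age_max = r$age_max, class = r$class,
                   criterion = r$criterion, bound_kind = r$bound_kind,
                   value_1 = r$value_1,
                   value_2 = if (is.null(r$value_2)) NA_real_ else r$value_2,
                   stringsAsFactors = FALSE)
      }))
      reference_table(d$family, e,
                      if (is.null(d$citation)) "" else d$citation)
    })
    names(out) <- vapply(out, function(tb) tb$family, character(1))
    return(out)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value_2 <- suppressWarnings(as.numeric(df$value_2))
  out <- lapply(split(df, df$family), function(sub) {
    reference_table(sub$family[1],
                    sub[, c("gender", "age_min", "age_max", "class",
                            "criterion", "bound_kind", "value_1", "value_2")],
                    citation = sub$citation[1])
  })
  out[intersect(.FAMILIES, names(out))]
}

#' @export
print.reference_table <- function(x, ...) {
  cat("<reference_table>", x$family, "with", nrow(x$entries), "entries\n")
  invisible(x)
}
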