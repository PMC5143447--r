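#' @title Health-condition taxonomy
#' @description
#' The taxonomy is a rooted tree of health-condition classes. The root is
#' `HealthCondition`; domain families (physical constitution, physical
#' activity, physiology, nutrition) hang directly below it, and the
#' physical-constitution branch carries the assessable obesity-related
#' leaves. Each assessable leaf is annotated with the ids of the
#' classification criteria that can establish it:
#'
#' 1. body mass index (kg/m^2)
#' 2. waist-to-hip ratio (dimensionless)
#' 3. waist circumference (cm)
#' 4. waist-to-height ratio (dimensionless)
#' 5. body fat mass (percent of body mass)
#'
#' @name taxonomy
NULL

.KNOWN_MODULES <- c("Common", "PhysicalStatus", "PhysicalActivityBehaviour",
                    "PhysiologicalStatus", "NutritionalHabits",
                    "ApplicationContext")

#' Canonicalise a condition-class name
#'
#' Accepts the historical spelling `OverWeightCondition` as an alias for
#' the canonical `OverweightCondition`, so that data produced under either
#' spelling resolves to a single class.
#'
#' @param name character vector of class names.
#' @return character vector of canonical names.
#' @export
canonical_class_name <- function(name) {
  aliases <- c(OverWeightCondition = "OverweightCondition")
  out <- unname(ifelse(name %in% names(aliases), aliases[name], name))
  as.character(out)
}

#' Construct a condition taxonomy
#'
#' @param classes a data.frame with columns `name`, `parent` (NA for the
#'   root), `module`, and a list-column `criteria` of integer vectors
#'   (criterion ids in 1..5, possibly empty).
#' @return an object of class `condition_taxonomy`.
#' @export
condition_taxonomy <- function(classes) {
  stopifnot(is.data.frame(classes),
            all(c("name", "parent", "module", "criteria") %in% names(classes)))
  classes$name <- canonical_class_name(as.character(classes$name))
  classes$parent <- ifelse(is.na(classes$parent), NA_character_,
                           canonical_class_name(as.character(classes$parent)))
  structure(list(classes = classes), class = "condition_taxonomy")
}

#' The five classification-criterion properties
#'
#' Maps criterion ids 1..5 to the measured data property and its unit.
#'
#' @return a data.frame with columns `id`, `measure`, `property_name`, `unit`.
#' @export
criterion_properties <- function() {
  data.frame(
    id = 1:5,
    measure = c("BodyMassIndex", "WaistToHipRatio", "WaistCircumference",
                "WaistToHeightRatio", "BodyFatMass"),
    property_name = c("isCharacterizedByBodyMassIndex",
                      "isCharacterizedByWaistToHipRatio",
                      "isCharacterizedByWaistCircumference",
                      "isCharacterizedByWaistToHeightRatio",
                      "isCharacterizedByBodyFatMass"),
    unit = c("kg/m^2", "ratio", "cm", "ratio", "percent"),
    stringsAsFactors = FALSE
  )
}

#' Build the default health-condition taxonomy
#'
#' The tree ships the common root, the four domain families, the
#' physical-constitution branch with its assessable leaves (with criterion
#' annotations), and one illustrative stub leaf in each non-physical
#' family. Only assessable leaves in the PhysicalStatus module carry
#' criteria.
#'
#' @return a `condition_taxonomy`.
#' @examples
#' tax <- build_default_taxonomy()
#' is_subclass_of(tax, "ObeseCondition", "BodyMassCondition")
#' @export
build_default_taxonomy <- function() {
  row <- function(name, parent, module, criteria = integer(0)) {
    data.frame(name = name, parent = parent, module = module,
               criteria = I(list(as.integer(criteria))),
               stringsAsFactors = FALSE)
  }
  classes <- do.call(rbind, list(
    row("HealthCondition", NA, "Common"),
    row("PhysicalConstitutionCondition", "HealthCondition", "PhysicalStatus"),
    row("PhysicalActivityCondition", "HealthCondition", "PhysicalActivityBehaviour"),
    row("PhysiologicalCondition", "HealthCondition", "PhysiologicalStatus"),
    row("NutritionalCondition", "HealthCondition", "NutritionalHabits"),
    row("BodyMassCondition", "PhysicalConstitutionCondition", "PhysicalStatus"),
    row("BodyFatDistributionCondition", "PhysicalConstitutionCondition", "PhysicalStatus"),
    row("CentralObesityCondition", "PhysicalConstitutionCondition", "PhysicalStatus", c(2L, 3L, 4L)),
    row("AdiposityCondition", "PhysicalConstitutionCondition", "PhysicalStatus", 5L),
    row("ObeseCondition", "BodyMassCondition", "PhysicalStatus", 1L),
    row("OverweightCondition", "BodyMassCondition", "PhysicalStatus", 1L),
    row("NormalWeightCondition", "BodyMassCondition", "PhysicalStatus", 1L),
    row("UnderweightCondition", "BodyMassCondition", "PhysicalStatus", 1L),
    row("AndroidCondition", "BodyFatDistributionCondition", "PhysicalStatus", 2L),
    row("GynoidCondition", "BodyFatDistributionCondition", "PhysicalStatus", 2L),
    row("SedentaryCondition", "PhysicalActivityCondition", "PhysicalActivityBehaviour"),
    row("BreakfastSkipperCondition", "NutritionalCondition", "NutritionalHabits")
  ))
  condition_taxonomy(classes)
}

.tax_lookup <- function(taxonomy, name) {
  name <- canonical_class_name(name)
  idx <- match(name, taxonomy$classes$name)
  if (anyNA(idx)) {
    stop("unknown condition class: ",
         paste(name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Ancestor chain of a class (self first, root last)
#' @param taxonomy a `condition_taxonomy`.
#' @param name a class name.
#' @return character vector of class names.
#' @export
ancestors_of <- function(taxonomy, name) {
  cl <- taxonomy$classes
  cur <- cl$name[.tax_lookup(taxonomy, name)]
  chain <- character(0)
  seen <- character(0)
  while (!is.na(cur)) {
    if (cur %in% seen) stop("cycle in taxonomy at class ", cur, call. = FALSE)
    chain <- c(chain, cur)
    seen <- c(seen, cur)
    cur <- cl$parent[match(cur, cl$name)]
  }
  chain
}

#' Subsumption query
#'
#' `TRUE` iff `b` lies on the ancestor chain of `a` (reflexive: every
#' class subsumes itself).
#'
#' @param taxonomy a `condition_taxonomy`.
#' @param a,b class names.
#' @return logical scalar.
#' @export
is_subclass_of <- function(taxonomy, a, b) {
  b <- taxonomy$classes$name[.tax_lookup(taxonomy, b)]
  b %in% ancestors_of(taxonomy, a)
}

#' Criterion ids attached to a class
#' @inheritParams is_subclass_of
#' @param name a class name.
#' @return integer vector of criterion ids (possibly empty).
#' @export
criteria_of <- function(taxonomy, name) {
  taxonomy$classes$criteria[[.tax_lookup(taxonomy, name)]]
}

#' Validate a taxonomy against its structural invariants
#'
#' Checks: a single root named `HealthCondition`; parent links form a tree
#' (every parent exists, no cycles); known source modules; criteria only
#' on PhysicalStatus classes and drawn from 1..5. Violations are returned
#' as data, not raised.
#'
#' @param taxonomy a `condition_taxonomy`.
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_taxonomy <- function(taxonomy) {
  cl <- taxonomy$classes
  out <- character(0)
  if (anyDuplicated(cl$name)) {
    out <- c(out, paste0("duplicate class name: ",
                         paste(unique(cl$name[duplicated(cl$name)]), collapse = ", ")))
  }
  roots <- cl$name[is.na(cl$parent)]
  if (length(roots) == 0) out <- c(out, "no root class")
  if (length(roots) > 1) {
    out <- c(out, paste0("multiple roots: ", paste(roots, collapse = ", ")))
  }
  if (length(roots) >= 1 && !"HealthCondition" %in% roots) {
    out <- c(out, paste0("root is not HealthCondition: ", roots[1]))
  }
  dangling <- setdiff(stats::na.omit(cl$parent), cl$name)
  if (length(dangling) > 0) {
    out <- c(out, paste0("parent not in taxonomy: ", paste(dangling, collapse = ", ")))
  }
  # cycle detection by chain walking with a visit cap
  for (nm in cl$name) {
    cur <- nm
    steps <- 0
    while (!is.na(cur) && cur %in% cl$name) {
      cur <- cl$parent[match(cur, cl$name)]
      steps <- steps + 1
      if (steps > nrow(cl)) {
        out <- c(out, paste0("cycle through class ", nm))
        break
      }
    }
  }
  bad_mod <- cl$name[!cl$module %in% .KNOWN_MODULES]
  if (length(bad_mod) > 0) {
    out <- c(out, paste0("unknown source module for: ", paste(bad_mod, collapse = ", ")))
  }
  for (i in seq_len(nrow(cl))) {
    crit <- cl$criteria[[i]]
    if (length(crit) > 0) {
      if (!all(crit %in% 1:5)) {
        out <- c(out, paste0("criteria outside 1..5 for ", cl$name[i]))
      }
      if (cl$module[i] != "PhysicalStatus") {
        out <- c(out, paste0("criteria on non-PhysicalStatus class ", cl$name[i]))
      }
      if (cl$name[i] %in% stats::na.omit(cl$parent)) {
        out <- c(out, paste0("criteria on non-leaf class ", cl$name[i]))
      }
    }
  }
  unique(out)
}

#' Serialise a taxonomy to a plain list (YAML/JSON-ready)
#' @param taxonomy a `condition_taxonomy`.
#' @return a list of per-class records.
#' @export
taxonomy_to_list <- function(taxonomy) {
  cl <- taxonomy$classes
  lapply(seq_len(nrow(cl)), function(i) {
    rec <- list(name = cl$name[i], module = cl$module[i])
    if (!is.na(cl$parent[i])) rec$parent <- cl$parent[i]
    if (length(cl$criteria[[i]]) > 0) rec$criteria <- as.integer(cl$criteria[[i]])
    rec
  })
}

#' Read/write a taxonomy as a structured config file
#'
#' @param taxonomy a `condition_taxonomy`.
#' @param path file path; format inferred from extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `write_taxonomy` returns `path` invisibly; `read_taxonomy`
#'   returns a `condition_taxonomy`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  recs <- taxonomy_to_list(taxonomy)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  recs <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  rows <- lapply(recs, function(r) {
    data.frame(name = r$name,
               parent = if (is.null(r$parent)) NA_character_ else r$parent,
               module = r$module,
               criteria = I(list(as.integer(unlist(r$criteria)))),
               stringsAsFactors = FALSE)
  })
  condition_taxonomy(do.call(rbind, rows))
}

#' @export
print.condition_taxonomy <- function(x, ...) {
  cat("<condition_taxonomy>", nrow(x$classes), "classes\n")
  rec <- function(name, depth) {
    crit <- criteria_of(x, name)
    cat(strrep("  ", depth), name,
        if (length(crit)) paste0(" {", paste(crit, collapse = ","), "}") else "",
        "\n", sep = "")
    kids <- x$classes$name[!is.na(x$classes$parent) & x$classes$parent == name]
    for (k in kids) rec(k, depth + 1)
  }
  roots <- x$classes$name[is.na(x$classes$parent)]
  for (r in roots) rec(r, 0)
  invisible(x)
}
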