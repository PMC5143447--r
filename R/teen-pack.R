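#' @title The teenager physical-status rule pack
#' @description
#' Generates the age- and gender-specific classification rules for the
#' adolescent population from reference tables. With the default tables
#' the pack holds 76 classification rules — 56 body-mass (2 genders x 7
#' one-year age bands x 4 BMI classes), 4 fat-distribution, 8
#' central-obesity and 8 adiposity rules — plus the derived-parameter
#' rules (age at assessment, BMI, waist-to-hip and waist-to-height
#' ratios).
#'
#' Every generated rule follows one antecedent pattern: a gender class
#' atom on the person, the person-to-condition link, the age-at-
#' assessment bounds, and one measured-criterion comparison; the
#' consequent asserts the condition class on the health-condition
#' individual (never on the person). Lower bounds are inclusive
#' ("greater or equal"), upper bounds exclusive, so interval families
#' partition their axis.
#' @name teen_pack
NULL

.family_rule <- function(family, entry, seqno) {
  prop <- .CRITERIA[[entry$criterion]]
  body <- list(
    atom("class", entry$gender, "?p"),
    atom("object_property", "isInHealthCondition", c("?p", "?h")),
    atom("data_property", "isAssessedAtAge", c("?h", "?age")),
    atom("builtin", "greaterThanOrEqual", c("?age", fmt_num(entry$age_min))),
    atom("builtin", "lessThanOrEqual", c("?age", fmt_num(entry$age_max))),
    atom("data_property", prop, c("?h", "?v")))
  body <- c(body, switch(entry$bound_kind,
    lower_inclusive = list(
      atom("builtin", "greaterThanOrEqual", c("?v", fmt_num(entry$value_1)))),
    upper_exclusive = list(
      atom("builtin", "lessThan", c("?v", fmt_num(entry$value_1)))),
    interval = list(
      atom("builtin", "greaterThanOrEqual", c("?v", fmt_num(entry$value_1))),
      atom("builtin", "lessThan", c("?v", fmt_num(entry$value_2))))))
  rule(sprintf("R1_%s_%02d_%s_%s_age%s_%s", family, seqno, entry$gender,
               entry$criterion, paste0(entry$age_min, "_", entry$age_max),
               entry$class),
       body, atom("class", entry$class, "?h"),
       provenance = paste0("generated from ", family, " reference table"),
       family = family)
}

.build_family <- function(table, family) {
  if (!inherits(table, "reference_table") || table$family != family) {
    stop("expected a ", family, " reference table", call. = FALSE)
  }
  bad <- validate_reference_table(table)
  if (length(bad) > 0) {
    stop("invalid ", family, " table: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  e <- table$entries
  lapply(seq_len(nrow(e)), function(i) {
    .family_rule(family, as.list(e[i, , drop = FALSE]), i)
  })
}

#' Build the body-mass classification rules
#'
#' One rule per (gender, age band, BMI class) table entry; with the
#' default table, 56 rules.
#'
#' @param table a body-mass `reference_table`.
#' @return list of [rule()]s.
#' @export
build_body_mass_rules <- function(table) .build_family(table, "body_mass")

#' Build the fat-distribution (android/gynoid) rules
#'
#' With the default table, 4 rules (2 genders x {android, gynoid}); the
#' female android rule is waist-to-hip ratio >= 0.85 at ages 13-17.
#'
#' @param table a fat-distribution `reference_table`.
#' @return list of [rule()]s.
#' @export
build_fat_distribution_rules <- function(table) {
  .build_family(table, "fat_distribution")
}

#' Build the central-obesity rules
#'
#' Each rule tests exactly one of the three applicable criteria
#' (waist-to-hip ratio, waist circumference, waist-to-height ratio), so
#' any single present measurement above its cutoff suffices to infer
#' central obesity. With the default table, 8 rules.
#'
#' @param table a central-obesity `reference_table`.
#' @return list of [rule()]s.
#' @export
build_central_obesity_rules <- function(table) {
  .build_family(table, "central_obesity")
}

#' Build the adiposity rules
#'
#' Antecedents compare body fat mass (percent) against gender- and
#' age-specific bounds. With the default table, 8 rules.
#'
#' @param table an adiposity `reference_table`.
#' @return list of [rule()]s.
#' @export
build_adiposity_rules <- function(table) .build_family(table, "adiposity")

#' Derived-parameter rules (age, BMI, WHR, WHtR)
#'
#' Rules with data-property heads that compute age at assessment from the
#' date of birth and assessment date (completed calendar years), BMI from
#' mass and height, and the two waist ratios from their components, so
#' that classification can proceed from raw measurements alone.
#'
#' @return list of [rule()]s, family `"derived"`.
#' @export
derived_parameter_rules <- function() {
  list(
    rule("Ax0_age",
         list(atom("data_property", "hasDateOfBirth", c("?p", "?dob")),
              atom("object_property", "isInHealthCondition", c("?p", "?h")),
              atom("data_property", "isAssessedAtDate", c("?h", "?d")),
              atom("builtin", "ageInYears", c("?age", "?d", "?dob"))),
         atom("data_property", "isAssessedAtAge", c("?h", "?age")),
         provenance = "age at assessment in completed calendar years",
         family = "derived"),
    rule("derive_bmi",
         list(atom("data_property", "isCharacterizedByBodyMass",
                   c("?h", "?m")),
              atom("data_property", "isCharacterizedByHeight", c("?h", "?t")),
              atom("builtin", "multiply", c("?t2", "?t", "?t")),
              atom("builtin", "divide", c("?b", "?m", "?t2"))),
         atom("data_property", "isCharacterizedByBodyMassIndex",
              c("?h", "?b")),
         provenance = "BMI = mass / height^2", family = "derived"),
    rule("derive_whr",
         list(atom("data_property", "isCharacterizedByWaistCircumference",
                   c("?h", "?w")),
              atom("data_property", "isCharacterizedByHipCircumference",
                   c("?h", "?hip")),
              atom("builtin", "divide", c("?r", "?w", "?hip"))),
         atom("data_property", "isCharacterizedByWaistToHipRatio",
              c("?h", "?r")),
         provenance = "WHR = waist / hip", family = "derived"),
    rule("derive_whtr",
         list(atom("data_property", "isCharacterizedByWaistCircumference",
                   c("?h", "?w")),
              atom("data_property", "isCharacterizedByHeight", c("?h", "?t")),
              atom("builtin", "divide", c("?wm", "?w", "100")),
              atom("builtin", "divide", c("?r", "?wm", "?t"))),
         atom("data_property", "isCharacterizedByWaistToHeightRatio",
              c("?h", "?r")),
         provenance = "WHtR = waist (m) / height (m)", family = "derived"))
}

#' Assemble the teenager physical-status rule pack
#'
#' Concatenates the four classification-rule families built from their
#' reference tables, plus the derived-parameter rules. With the default
#' tables the pack holds 76 classification rules (56/4/8/8 across the
#' body-mass, fat-distribution, central-obesity and adiposity families).
#'
#' @param tables named list of `reference_table`s with elements
#'   `body_mass`, `fat_distribution`, `central_obesity`, `adiposity`
#'   (default: [default_reference_tables()]).
#' @param pack_id pack identifier.
#' @return a [rule_pack()] whose `family_counts` covers all families
#'   (including `"derived"`).
#' @export
assemble_teen_pack <- function(tables = default_reference_tables(),
                               pack_id = "teen_physical_status_R1") {
  missing_fam <- setdiff(.FAMILIES, names(tables))
  if (length(missing_fam) > 0) {
    stop("cannot assemble pack, missing famil",
         if (length(missing_fam) > 1) "ies: " else "y: ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  }
  rules <- c(build_body_mass_rules(tables$body_mass),
             build_fat_distribution_rules(tables$fat_distribution),
             build_central_obesity_rules(tables$central_obesity),
             build_adiposity_rules(tables$adiposity),
             derived_parameter_rules())
  rule_pack(pack_id, rules)
}

#' Number of classification rules in a pack
#'
#' Counts rules in the four classification families, excluding
#' derived-parameter helper rules and subsumption rules.
#'
#' @param pack a [rule_pack()].
#' @return integer.
#' @export
n_classification_rules <- function(pack) {
  sum(pack$family_counts[intersect(names(pack$family_counts), .FAMILIES)])
}
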