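#' @title Person and assessment records, derived anthropometric measures
#' @description
#' Units are fixed by the data dictionary: body mass in kg, height in m,
#' circumferences in cm, body fat mass in percent of body mass, dates as
#' ISO-8601. Ratios are dimensionless; the waist-to-height ratio converts
#' waist (cm) and height (m) to a common unit before dividing.
#' @name measures
NULL

.RATIO_TOL <- 0.005  # provided ratio vs recomputed-from-components

.check_id <- function(id, what) {
  if (!is.character(id) || length(id) != 1 || !grepl("^[A-Za-z0-9_.-]+$", id)) {
    stop(what, " must be a single URL-safe identifier, got: ",
         paste(id, collapse = ","), call. = FALSE)
  }
  id
}

.as_date <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1 || is.na(d)) stop("invalid ", what, ": ", x, call. = FALSE)
  d
}

#' Create a person record
#'
#' @param person_id opaque URL-safe identifier.
#' @param gender `"Male"` or `"Female"`.
#' @param date_of_birth a `Date` or ISO-8601 string.
#' @return an object of class `person_record`.
#' @export
person_record <- function(person_id, gender, date_of_birth) {
  .check_id(person_id, "person_id")
  gender <- as.character(gender)
  if (!gender %in% c("Male", "Female")) {
    stop("gender must be 'Male' or 'Female', got: ", gender, call. = FALSE)
  }
  structure(list(person_id = person_id, gender = gender,
                 date_of_birth = .as_date(date_of_birth, "date_of_birth")),
            class = "person_record")
}

.MEASURE_FIELDS <- c("body_mass", "height", "body_mass_index",
                     "waist_circumference", "hip_circumference",
                     "waist_to_hip_ratio", "waist_to_height_ratio",
                     "body_fat_mass")

#' Create a health-condition assessment record
#'
#' All measurements are optional; present values must be strictly
#' positive, ratios must lie in (0, 3), and a provided ratio must agree
#' with its components to within 0.005 when both are present.
#'
#' @param assessment_id opaque URL-safe identifier.
#' @param assessment_date a `Date` or ISO-8601 string.
#' @param body_mass kg. @param height m. @param body_mass_index kg/m^2.
#' @param waist_circumference cm. @param hip_circumference cm.
#' @param waist_to_hip_ratio dimensionless.
#' @param waist_to_height_ratio dimensionless.
#' @param body_fat_mass percent of body mass.
#' @param age_at_assessment completed years; normally filled by
#'   [enrich_assessment()].
#' @return an object of class `assessment_record`.
#' @export
assessment_record <- function(assessment_id, assessment_date,
                              body_mass = NA_real_, height = NA_real_,
                              body_mass_index = NA_real_,
                              waist_circumference = NA_real_,
                              hip_circumference = NA_real_,
                              waist_to_hip_ratio = NA_real_,
                              waist_to_height_ratio = NA_real_,
                              body_fat_mass = NA_real_,
                              age_at_assessment = NA_integer_) {
  .check_id(assessment_id, "assessment_id")
  rec <- structure(list(
    assessment_id = assessment_id,
    assessment_date = .as_date(assessment_date, "assessment_date"),
    body_mass = as.numeric(body_mass), height = as.numeric(height),
    body_mass_index = as.numeric(body_mass_index),
    waist_circumference = as.numeric(waist_circumference),
    hip_circumference = as.numeric(hip_circumference),
    waist_to_hip_ratio = as.numeric(waist_to_hip_ratio),
    waist_to_height_ratio = as.numeric(waist_to_height_ratio),
    body_fat_mass = as.numeric(body_fat_mass),
    age_at_assessment = if (is.na(age_at_assessment)) NA_integer_
                        else as.integer(age_at_assessment)
  ), class = "assessment_record")
  validate_assessment(rec)
  rec
}

#' Validate an assessment record's measurement invariants
#' @param rec an `assessment_record`.
#' @return `rec` invisibly; raises on violation.
#' @export
validate_assessment <- function(rec) {
  for (f in .MEASURE_FIELDS) {
    v <- rec[[f]]
    if (!is.na(v) && v <= 0) {
      stop("measurement ", f, " must be strictly positive (", v, ") in ",
           rec$assessment_id, call. = FALSE)
    }
  }
  for (f in c("waist_to_hip_ratio", "waist_to_height_ratio")) {
    v <- rec[[f]]
    if (!is.na(v) && (v <= 0 || v >= 3)) {
      stop("ratio ", f, " must lie in (0, 3): ", v, call. = FALSE)
    }
  }
  .check_ratio_consistency(rec)
  invisible(rec)
}

.check_ratio_consistency <- function(rec) {
  chk <- function(provided, computed, what) {
    if (!is.na(provided) && !is.na(computed) &&
        abs(provided - computed) > .RATIO_TOL) {
      stop("inconsistent ", what, " in ", rec$assessment_id, ": provided ",
           provided, " vs ", round(computed, 4), " from components",
           call. = FALSE)
    }
  }
  if (!is.na(rec$waist_circumference) && !is.na(rec$hip_circumference)) {
    chk(rec$waist_to_hip_ratio,
        compute_whr(rec$waist_circumference, rec$hip_circumference),
        "waist_to_hip_ratio")
  }
  if (!is.na(rec$waist_circumference) && !is.na(rec$height)) {
    chk(rec$waist_to_height_ratio,
        compute_whtr(rec$waist_circumference, rec$height),
        "waist_to_height_ratio")
  }
  if (!is.na(rec$body_mass) && !is.na(rec$height)) {
    chk(rec$body_mass_index, compute_bmi(rec$body_mass, rec$height),
        "body_mass_index")
  }
  invisible(rec)
}

#' Age in completed calendar years
#'
#' Birthday-anniversary semantics: the count increments on the anniversary
#' day itself. A February-29 birthday maps to March 1 in non-leap years.
#'
#' @param date_of_birth,assessment_date `Date`s or ISO-8601 strings.
#' @return non-negative integer, completed years.
#' @examples
#' compute_age("2000-10-15", "2014-11-20")  # 14
#' @export
compute_age <- function(date_of_birth, assessment_date) {
  dob <- .as_date(date_of_birth, "date_of_birth")
  at <- .as_date(assessment_date, "assessment_date")
  if (at < dob) {
    stop("assessment_date precedes date_of_birth (", at, " < ", dob, ")",
         call. = FALSE)
  }
  b <- as.POSIXlt(dob); a <- as.POSIXlt(at)
  age <- a$year - b$year
  # lexicographic (month, day) comparison; Feb 29 = (1,29) sorts before
  # Mar 1 = (2,1), giving the March-1 convention in non-leap years for free
  if (a$mon < b$mon || (a$mon == b$mon && a$mday < b$mday)) age <- age - 1L
  as.integer(age)
}

#' Body mass index
#' @param body_mass kg, strictly positive.
#' @param height m, strictly positive.
#' @return kg/m^2.
#' @export
compute_bmi <- function(body_mass, height) {
  if (!is.finite(body_mass) || body_mass <= 0) {
    stop("body_mass must be strictly positive: ", body_mass, call. = FALSE)
  }
  if (!is.finite(height) || height <= 0) {
    stop("height must be strictly positive: ", height, call. = FALSE)
  }
  body_mass / height^2
}

#' Waist-to-hip ratio
#' @param waist_circumference,hip_circumference cm, strictly positive.
#' @return dimensionless ratio.
#' @export
compute_whr <- function(waist_circumference, hip_circumference) {
  if (!is.finite(waist_circumference) || waist_circumference <= 0) {
    stop("waist_circumference must be strictly positive", call. = FALSE)
  }
  if (!is.finite(hip_circumference) || hip_circumference <= 0) {
    stop("hip_circumference must be strictly positive", call. = FALSE)
  }
  waist_circumference / hip_circumference
}

#' Waist-to-height ratio
#'
#' Waist is measured in cm and height in m; both are brought to metres
#' before dividing, so `compute_whtr(80, 1.60)` is 0.5.
#'
#' @param waist_circumference cm, strictly positive.
#' @param height m, strictly positive.
#' @return dimensionless ratio.
#' @export
compute_whtr <- function(waist_circumference, height) {
  if (!is.finite(waist_circumference) || waist_circumference <= 0) {
    stop("waist_circumference must be strictly positive", call. = FALSE)
  }
  if (!is.finite(height) || height <= 0) {
    stop("height must be strictly positive", call. = FALSE)
  }
  (waist_circumference / 100) / height
}

#' Enrich an assessment with derived measures
#'
#' Fills `age_at_assessment` from the person's date of birth, and any of
#' BMI, waist-to-hip ratio and waist-to-height ratio that are derivable
#' from present components. Explicitly provided values are never
#' overwritten; a provided value inconsistent with its components (beyond
#' the 0.005 tolerance) raises a validation error. Idempotent.
#'
#' @param person a `person_record`.
#' @param assessment an `assessment_record`.
#' @return the enriched `assessment_record`.
#' @export
enrich_assessment <- function(person, assessment) {
  stopifnot(inherits(person, "person_record"),
            inherits(assessment, "assessment_record"))
  .check_ratio_consistency(assessment)
  a <- assessment
  a$age_at_assessment <- if (!is.na(a$age_at_assessment)) a$age_at_assessment
    else compute_age(person$date_of_birth, a$assessment_date)
  if (is.na(a$body_mass_index) && !is.na(a$body_mass) && !is.na(a$height)) {
    a$body_mass_index <- compute_bmi(a$body_mass, a$height)
  }
  if (is.na(a$waist_to_hip_ratio) && !is.na(a$waist_circumference) &&
      !is.na(a$hip_circumference)) {
    a$waist_to_hip_ratio <- compute_whr(a$waist_circumference,
                                        a$hip_circumference)
  }
  if (is.na(a$waist_to_height_ratio) && !is.na(a$waist_circumference) &&
      !is.na(a$height)) {
    a$waist_to_height_ratio <- compute_whtr(a$waist_circumference, a$height)
  }
  a
}

#' @export
print.person_record <- function(x, ...) {
  cat("<person_record>", x$person_id, x$gender, "born",
      format(x$date_of_birth), "\n")
  invisible(x)
}

#' @export
print.assessment_record <- function(x, ...) {
  cat("<assessment_record>", x$assessment_id, "on", format(x$assessment_date))
  if (!is.na(x$age_at_assessment)) cat(" (age", x$age_at_assessment, ")")
  cat("\n")
  for (f in .MEASURE_FIELDS) {
    if (!is.na(x[[f]])) cat("  ", f, "=", signif(x[[f]], 6), "\n")
  }
  invisible(x)
}
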