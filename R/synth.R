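#' @title Synthetic teen cohorts
#' @description
#' A seeded generator for offline testing: persons aged 10-19 with
#' gender- and age-indexed normally distributed height and body mass
#' (growth-chart-shaped fixture means, not epidemiological claims), plus
#' waist/hip circumferences and body fat with configurable per-field
#' missingness. BMI is left to be derived from sampled height and mass.
#' All randomness flows from the single spec seed.
#' @name synth
NULL

#' Default gender- and age-indexed normal models
#'
#' Height in metres, mass in kg; one (mean, sd) row per gender and
#' completed-years age 8-25 (ages outside 10-19 extend the boundary
#' values so longitudinal follow-ups stay defined).
#'
#' @return data.frame with columns `gender`, `age`, `mean`, `sd`.
#' @export
default_height_model <- function() {
  ages <- 10:19
  m <- c(1.38, 1.43, 1.49, 1.56, 1.63, 1.69, 1.73, 1.75, 1.76, 1.77)
  f <- c(1.38, 1.44, 1.51, 1.57, 1.60, 1.62, 1.63, 1.63, 1.63, 1.63)
  .extend_model(rbind(
    data.frame(gender = "Male", age = ages, mean = m, sd = 0.07),
    data.frame(gender = "Female", age = ages, mean = f, sd = 0.06)))
}

#' @rdname default_height_model
#' @export
default_mass_model <- function() {
  ages <- 10:19
  m <- c(32, 36, 40, 45, 51, 56, 61, 64, 66, 67)
  f <- c(33, 37, 42, 46, 50, 52, 54, 55, 56, 57)
  .extend_model(rbind(
    data.frame(gender = "Male", age = ages, mean = m, sd = 8),
    data.frame(gender = "Female", age = ages, mean = f, sd = 7)))
}

.extend_model <- function(df) {
  out <- df
  for (g in unique(df$gender)) {
    sub <- df[df$gender == g, ]
    lo <- sub[which.min(sub$age), ]
    hi <- sub[which.max(sub$age), ]
    for (a in 8:(min(sub$age) - 1)) {
      out <- rbind(out, transform(lo, age = a))
    }
    for (a in (max(sub$age) + 1):25) {
      out <- rbind(out, transform(hi, age = a))
    }
  }
  rownames(out) <- NULL
  out
}

.model_lookup <- function(model, gender, age) {
  age <- max(min(age, max(model$age)), min(model$age))
  row <- model[model$gender == gender & model$age == age, ]
  if (nrow(row) == 0) stop("model has no entry for ", gender, " age ", age,
                           call. = FALSE)
  row[1, ]
}

#' Specify a synthetic cohort
#'
#' @param n_persons number of persons.
#' @param seed integer seed; the only entropy source.
#' @param age_range integer vector `c(min, max)` of completed years at the
#'   first assessment (default 10-19).
#' @param gender_ratio proportion of females in `[0, 1]`.
#' @param height_model,mass_model gender/age-indexed normal models (see
#'   [default_height_model()]).
#' @param measurement_missingness named per-field missingness
#'   probabilities in `[0, 1]` (fields `waist_circumference`,
#'   `hip_circumference`, `body_fat_mass`).
#' @param n_assessments assessments per person at yearly spacing
#'   (2 or more exercises longitudinal reclassification).
#' @param baseline_date date of the first assessment wave.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_persons, seed, age_range = c(10L, 19L),
                        gender_ratio = 0.5,
                        height_model = default_height_model(),
                        mass_model = default_mass_model(),
                        measurement_missingness = c(
                          waist_circumference = 0.3,
                          hip_circumference = 0.3,
                          body_fat_mass = 0.7),
                        n_assessments = 1L,
                        baseline_date = as.Date("2015-06-01")) {
  stopifnot(n_persons >= 0, length(age_range) == 2,
            age_range[1] <= age_range[2],
            gender_ratio >= 0, gender_ratio <= 1,
            all(measurement_missingness >= 0),
            all(measurement_missingness <= 1),
            all(height_model$sd > 0), all(mass_model$sd > 0),
            n_assessments >= 1)
  structure(list(n_persons = as.integer(n_persons), seed = as.integer(seed),
                 age_range = as.integer(age_range),
                 gender_ratio = gender_ratio, height_model = height_model,
                 mass_model = mass_model,
                 measurement_missingness = measurement_missingness,
                 n_assessments = as.integer(n_assessments),
                 baseline_date = as.Date(baseline_date)),
            class = "cohort_spec")
}

# shift a date by whole years; Feb 29 lands on Mar 1 in non-leap years
.add_years <- function(d, n) {
  lt <- as.POSIXlt(d)
  lt$year <- lt$year + n
  as.Date(lt)
}

.rnorm_pos <- function(n, mean, sd, floor = mean / 10) {
  pmax(stats::rnorm(n, mean, sd), floor)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the spec seed: the same spec yields the identical
#' cohort. Dates of birth are placed so each person's completed age at
#' the baseline assessment equals the sampled age; follow-up assessments
#' (when `n_assessments > 1`) are spaced exactly one year apart with
#' freshly sampled measurements at the then-current age.
#'
#' @param spec a [cohort_spec()].
#' @return list of `persons`, `assessments`, `links` as in
#'   [read_cohort()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    persons <- list()
    assessments <- list()
    links <- .empty_links()
    miss <- spec$measurement_missingness
    for (i in seq_len(spec$n_persons)) {
      pid <- sprintf("p%05d", i)
      gender <- if (stats::runif(1) < spec$gender_ratio) "Female" else "Male"
      age0 <- sample(seq(spec$age_range[1], spec$age_range[2]), 1)
      offset <- sample(0:364, 1)
      dob <- .add_years(spec$baseline_date - offset, -age0)
      persons[[i]] <- person_record(pid, gender, dob)
      for (k in seq_len(spec$n_assessments)) {
        aid <- sprintf("a%05d-%d", i, k)
        date <- .add_years(spec$baseline_date, k - 1L)
        age <- age0 + (k - 1L)
        hm <- .model_lookup(spec$height_model, gender, age)
        mm <- .model_lookup(spec$mass_model, gender, age)
        height <- .rnorm_pos(1, hm$mean, hm$sd)
        mass <- .rnorm_pos(1, mm$mean, mm$sd)
        waist <- .rnorm_pos(1, 45 * height, 5)
        hip <- .rnorm_pos(1, 53 * height, 5)
        bfm <- min(max(stats::rnorm(1, if (gender == "Female") 25 else 18, 5),
                       2), 45)
        args <- list(assessment_id = aid, assessment_date = date,
                     body_mass = round(mass, 1), height = round(height, 3))
        if (stats::runif(1) >= miss[["waist_circumference"]]) {
          args$waist_circumference <- round(waist, 1)
        }
        if (stats::runif(1) >= miss[["hip_circumference"]]) {
          args$hip_circumference <- round(hip, 1)
        }
        if (stats::runif(1) >= miss[["body_fat_mass"]]) {
          args$body_fat_mass <- round(bfm, 1)
        }
        assessments[[length(assessments) + 1L]] <-
          do.call(assessment_record, args)
        links <- rbind(links, data.frame(person_id = pid,
                                         assessment_id = aid,
                                         stringsAsFactors = FALSE))
      }
    }
    list(persons = persons, assessments = assessments, links = links)
  })
}

#' Read a cohort spec from a YAML file
#' @param path YAML file with any of the [cohort_spec()] fields
#'   (`n_persons` and `seed` required).
#' @return a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$n_persons) || is.null(doc$seed)) {
    stop("cohort spec needs n_persons and seed", call. = FALSE)
  }
  args <- list(n_persons = doc$n_persons, seed = doc$seed)
  if (!is.null(doc$age_range)) args$age_range <- unlist(doc$age_range)
  if (!is.null(doc$gender_ratio)) args$gender_ratio <- doc$gender_ratio
  if (!is.null(doc$n_assessments)) args$n_assessments <- doc$n_assessments
  if (!is.null(doc$baseline_date)) args$baseline_date <- doc$baseline_date
  if (!is.null(doc$measurement_missingness)) {
    args$measurement_missingness <- unlist(doc$measurement_missingness)
  }
  do.call(cohort_spec, args)
}
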