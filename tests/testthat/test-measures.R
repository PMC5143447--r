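test_that("age is counted in completed years with anniversary semantics", {
  expect_identical(compute_age("2000-10-15", "2014-11-20"), 14L)
  expect_identical(compute_age("2000-11-30", "2014-11-01"), 13L)
  expect_identical(compute_age("2000-05-05", "2000-05-05"), 0L)
  # the count increments on the anniversary day itself
  expect_identical(compute_age("2000-10-15", "2014-10-14"), 13L)
  expect_identical(compute_age("2000-10-15", "2014-10-15"), 14L)
  # Feb-29 birthdays roll to March 1 in non-leap years
  expect_identical(compute_age("2000-02-29", "2001-02-28"), 0L)
  expect_identical(compute_age("2000-02-29", "2001-03-01"), 1L)
  expect_identical(compute_age("2000-02-29", "2004-02-29"), 4L)
  expect_error(compute_age("2010-01-01", "2009-12-31"), "precedes")
})

test_that("age satisfies exact-anniversary and monotonicity properties", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      dob <- as.Date("1995-01-01") + sample(0:5000, 1)
      n <- sample(0:30, 1)
      lt <- as.POSIXlt(dob)
      lt$year <- lt$year + n
      expect_identical(compute_age(dob, as.Date(lt)), as.integer(n))
    }
    # monotone non-decreasing, steps of at most 1 across consecutive days
    dob <- as.Date("2002-06-17")
    days <- seq(dob, by = "day", length.out = 800)
    ages <- vapply(days, function(d) compute_age(dob, d), integer(1))
    expect_true(all(diff(ages) %in% c(0L, 1L)))
  })
})

test_that("BMI and the waist ratios follow their formulas and domains", {
  expect_equal(compute_bmi(80, 2.0), 20.0)
  expect_equal(compute_bmi(50, 1.60), 19.53, tolerance = 0.005 / 19.53)
  expect_error(compute_bmi(70, 0), "strictly positive")
  expect_error(compute_bmi(-1, 1.7), "strictly positive")

  expect_equal(compute_whr(68, 80), 0.85)
  expect_equal(compute_whtr(80, 1.60), 0.50)
  expect_error(compute_whr(68, 0), "strictly positive")
  expect_error(compute_whtr(0, 1.6), "strictly positive")

  # scale invariance of the hip ratio
  withr::with_seed(11, {
    for (rep in 1:25) {
      w <- runif(1, 50, 110); h <- runif(1, 60, 130); k <- runif(1, 0.1, 10)
      expect_equal(compute_whr(k * w, k * h), compute_whr(w, h),
                   tolerance = 1e-9)
    }
  })
})

test_that("record constructors enforce the data dictionary", {
  expect_error(person_record("p1", "X", "2001-01-01"), "gender")
  expect_error(person_record("p one", "Male", "2001-01-01"), "identifier")
  expect_error(person_record("p1", "Male", "not-a-date"), "invalid")
  expect_error(assessment_record("a1", "2015-01-01", body_mass = -3),
               "strictly positive")
  expect_error(assessment_record("a1", "2015-01-01",
                                 waist_to_hip_ratio = 3.5), "\\(0, 3\\)")
  expect_error(assessment_record("a1", "2015-01-01",
                                 waist_circumference = 68,
                                 hip_circumference = 80,
                                 waist_to_hip_ratio = 0.99),
               "inconsistent waist_to_hip_ratio")
  # agreement within 0.005 is accepted
  ok <- assessment_record("a1", "2015-01-01", waist_circumference = 68,
                          hip_circumference = 80,
                          waist_to_hip_ratio = 0.853)
  expect_s3_class(ok, "assessment_record")
})

test_that("enrichment fills derived values, never overwrites, idempotent", {
  p <- person_record("p1", "Male", "2000-10-15")
  a <- assessment_record("a1", "2015-11-20", body_mass = 60, height = 1.70)
  e <- enrich_assessment(p, a)
  expect_identical(e$age_at_assessment, 15L)
  expect_equal(e$body_mass_index, 20.76, tolerance = 0.005 / 20.76)

  provided <- assessment_record("a2", "2015-11-20", body_mass_index = 19)
  e2 <- enrich_assessment(p, provided)
  expect_equal(e2$body_mass_index, 19)

  full <- assessment_record("a3", "2015-11-20", body_mass = 60,
                            height = 1.70, waist_circumference = 70,
                            hip_circumference = 90)
  once <- enrich_assessment(p, full)
  twice <- enrich_assessment(p, once)
  expect_equal(once, twice)
  expect_equal(once$waist_to_hip_ratio, 70 / 90)
  expect_equal(once$waist_to_height_ratio, 0.70 / 1.70)

  expect_error(enrich_assessment(p, assessment_record("a4", "1999-01-01")),
               "precedes")
})
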