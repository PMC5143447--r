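test_that("the default tables yield the 56/4/8/8 rule inventory", {
  tables <- default_reference_tables()
  expect_length(build_body_mass_rules(tables$body_mass), 56)
  expect_length(build_fat_distribution_rules(tables$fat_distribution), 4)
  expect_length(build_central_obesity_rules(tables$central_obesity), 8)
  expect_length(build_adiposity_rules(tables$adiposity), 8)

  pack <- assemble_teen_pack(tables)
  expect_equal(n_classification_rules(pack), 76)
  expect_equal(pack$family_counts[["body_mass"]], 56L)
  expect_equal(pack$family_counts[["fat_distribution"]], 4L)
  expect_equal(pack$family_counts[["central_obesity"]], 8L)
  expect_equal(pack$family_counts[["adiposity"]], 8L)
})

test_that("one gender, one age, four classes yields four rules", {
  expect_length(build_body_mass_rules(tiny_bmi_table()), 4)
})

test_that("pack assembly requires all four families", {
  tables <- default_reference_tables()
  tables$adiposity <- NULL
  expect_error(assemble_teen_pack(tables), "missing family: adiposity")
  expect_error(build_body_mass_rules(tables$fat_distribution),
               "expected a body_mass")
})

test_that("gender-specific rules reference exactly their gender class", {
  pack <- assemble_teen_pack()
  cls_rules <- Filter(function(r) r$family %in% c(
    "body_mass", "fat_distribution", "central_obesity", "adiposity"),
    pack$rules)
  for (r in cls_rules) {
    gatoms <- Filter(function(a) a$kind == "class" &&
                       a$predicate %in% c("Male", "Female"), r$antecedent)
    expect_length(gatoms, 1)
    expect_true(grepl(gatoms[[1]]$predicate, r$rule_id))
  }
})

test_that("BMI classification partitions the axis at every boundary", {
  tables <- default_reference_tables()
  rules <- build_body_mass_rules(tables$body_mass)
  e <- tables$body_mass$entries
  for (g in c("Male", "Female")) {
    for (age in c(11, 14, 17)) {
      cuts <- sort(unique(e$value_1[e$gender == g & e$age_min == age]))
      probe <- unique(c(cuts - 0.005, cuts, cuts + 0.005,
                        cuts[-1] - diff(cuts) / 2, 10, 45))
      for (bmi in probe) {
        hits <- intersect(classify_single(rules, g, age,
                                          "isCharacterizedByBodyMassIndex",
                                          bmi), bmi_leaves)
        expect_length(hits, 1)
      }
    }
  }
})

test_that("the partition property holds for randomised valid tables too", {
  withr::with_seed(303, {
    for (rep in 1:5) {
      tab <- random_rising_bmi_table(ages = 12:15)
      expect_length(validate_reference_table(tab), 0)
      rules <- build_body_mass_rules(tab)
      cuts <- sort(unique(tab$entries$value_1[
        tab$entries$gender == "Female" & tab$entries$age_min == 13]))
      for (bmi in unique(c(cuts - 0.01, cuts, cuts + 0.01, 5, 60))) {
        hits <- intersect(classify_single(rules, "Female", 13,
                                          "isCharacterizedByBodyMassIndex",
                                          bmi), bmi_leaves)
        expect_length(hits, 1)
      }
    }
  })
})

test_that("the android threshold and age band behave as specified", {
  rules <- build_fat_distribution_rules(
    default_reference_tables()$fat_distribution)
  got <- classify_single(rules, "Female", 15,
                         "isCharacterizedByWaistToHipRatio", 0.85)
  expect_true("AndroidCondition" %in% got)
  expect_false("GynoidCondition" %in% got)

  below <- classify_single(rules, "Female", 15,
                           "isCharacterizedByWaistToHipRatio", 0.84)
  expect_true("GynoidCondition" %in% below)
  expect_false("AndroidCondition" %in% below)
})

test_that("any single central-obesity criterion suffices; none infers nothing", {
  rules <- build_central_obesity_rules(
    default_reference_tables()$central_obesity)
  only_whtr <- classify_single(rules, "Male", 14,
                               "isCharacterizedByWaistToHeightRatio", 0.55)
  expect_true("CentralObesityCondition" %in% only_whtr)
  only_wc <- classify_single(rules, "Female", 16,
                             "isCharacterizedByWaistCircumference", 85)
  expect_true("CentralObesityCondition" %in% only_wc)

  none <- classify_single(rules, "Male", 14,
                          "isCharacterizedByBodyMassIndex", 30)
  expect_false("CentralObesityCondition" %in% none)
})

test_that("adiposity flips exactly at its bound and needs body fat", {
  tables <- default_reference_tables()
  rules <- build_adiposity_rules(tables$adiposity)
  e <- tables$adiposity$entries
  for (i in seq_len(nrow(e))) {
    g <- e$gender[i]; age <- e$age_min[i]; bound <- e$value_1[i]
    above <- classify_single(rules, g, age, "isCharacterizedByBodyFatMass",
                             bound)
    at_minus <- classify_single(rules, g, age,
                                "isCharacterizedByBodyFatMass",
                                bound - 0.01)
    expect_true("AdiposityCondition" %in% above)
    expect_false("AdiposityCondition" %in% at_minus)
  }
  no_bfm <- classify_single(rules, "Male", 12,
                            "isCharacterizedByWaistCircumference", 90)
  expect_false("AdiposityCondition" %in% no_bfm)
})

test_that("a rising obese bound reclassifies a constant BMI a year later", {
  withr::with_seed(404, {
    for (rep in 1:8) {
      a <- sample(12:15, 1)
      tab <- random_rising_bmi_table(ages = c(a, a + 1))
      e <- tab$entries
      g <- sample(c("Male", "Female"), 1)
      obese_a <- e$value_1[e$gender == g & e$age_min == a &
                             e$class == "ObeseCondition"]
      obese_a1 <- e$value_1[e$gender == g & e$age_min == a + 1 &
                              e$class == "ObeseCondition"]
      over_a1 <- e$value_1[e$gender == g & e$age_min == a + 1 &
                             e$class == "OverweightCondition"]
      expect_gt(obese_a1, obese_a)
      lo <- max(obese_a, over_a1)
      bmi <- (lo + obese_a1) / 2
      rules <- build_body_mass_rules(tab)
      first <- classify_single(rules, g, a,
                               "isCharacterizedByBodyMassIndex", bmi)
      second <- classify_single(rules, g, a + 1,
                                "isCharacterizedByBodyMassIndex", bmi)
      expect_true("ObeseCondition" %in% first)
      expect_true("OverweightCondition" %in% second)
      expect_false("ObeseCondition" %in% second)
    }
  })
})

test_that("reference-table validation catches broken tables", {
  # gap in the partition
  broken <- tiny_bmi_table()
  broken$entries$value_1[broken$entries$class == "ObeseCondition"] <- 25
  expect_true(any(grepl("do not partition",
                        validate_reference_table(broken))))
  expect_error(build_body_mass_rules(broken), "invalid body_mass table")

  # negative threshold
  neg <- tiny_bmi_table()
  neg$entries$value_1[1] <- -1
  expect_true(any(grepl("strictly positive",
                        validate_reference_table(neg))))

  # overlapping age bands within gender/class/criterion
  tab <- default_reference_tables()$adiposity
  tab$entries$age_max[1] <- 14
  expect_true(any(grepl("overlapping age bands",
                        validate_reference_table(tab))))

  # obese lower bound decreasing with age
  dec <- rbind(tiny_bmi_table(age = 12)$entries,
               tiny_bmi_table(age = 13, u = 15, n = 21, o = 23.5)$entries)
  dec_tab <- reference_table("body_mass", dec)
  expect_true(any(grepl("decreasing in age",
                        validate_reference_table(dec_tab))))
})

test_that("reference tables round-trip through CSV", {
  tables <- default_reference_tables()
  path <- file.path(tempdir(), "tables.csv")
  write_reference_tables(tables, path)
  back <- read_reference_tables(path)
  expect_setequal(names(back), names(tables))
  for (fam in names(tables)) {
    a <- tables[[fam]]$entries
    b <- back[[fam]]$entries
    a <- a[order(a$gender, a$age_min, a$class, a$criterion), ]
    b <- b[order(b$gender, b$age_min, b$class, b$criterion), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a)
  }
  pack <- assemble_teen_pack(back)
  expect_equal(n_classification_rules(pack), 76)
  unlink(path)
})
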