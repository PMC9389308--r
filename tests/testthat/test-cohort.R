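write_cohort_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("cohort loading derives BMI, collects row errors, keeps valid rows", {
  path <- write_cohort_file(c(
    "id,sex,age_years,weight_kg,height_cm,l_thyroxine",
    "a,F,4,20,100,1",
    "b,M,6,22,115,0",
    "c,M,2,12,0,1",      # non-positive height -> rejected
    "d,F,10,31,134,"
  ))
  cohort <- load_cohort(path)
  expect_s3_class(cohort, "cohort")
  expect_equal(nrow(cohort), 3)
  expect_equal(cohort$bmi[1], 20)  # 20 kg at 1.00 m
  expect_equal(cohort$l_thyroxine[1:2], c(TRUE, FALSE))
  problems <- attr(cohort, "validation")
  expect_equal(nrow(problems), 1)
  expect_equal(problems$row, 3)
  expect_match(problems$message, "non-positive height")
})

test_that("decimal age comes from ISO dates when no age column is given", {
  path <- write_cohort_file(c(
    "id,sex,birth_date,exam_date,weight_kg,height_cm",
    "a,M,2015-03-01,2020-03-01,18,110"
  ))
  cohort <- load_cohort(path)
  expect_equal(cohort$age_years, as.numeric(as.Date("2020-03-01") -
                                              as.Date("2015-03-01")) / 365.25)
})

test_that("loading fails only when no valid rows remain", {
  path <- write_cohort_file(c("id,sex,age_years,weight_kg,height_cm",
                              "a,F,4,0,100", "b,X,6,22,115"))
  expect_error(load_cohort(path), "no valid rows")
  no_col <- write_cohort_file(c("id,sex,age_years,weight_kg", "a,F,4,20"))
  expect_error(load_cohort(no_col), "missing column: height_cm")
})

test_that("cohorts round-trip through write_cohort", {
  sim <- simulate_cohort(simulate_config(n = 25, seed = 9), default_pair())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(sim$cohort, path)
  back <- load_cohort(path)
  expect_equal(nrow(back), 25)
  expect_equal(back$age_years, sim$cohort$age_years, tolerance = 1e-9)
  expect_equal(back$bmi, sim$cohort$bmi, tolerance = 1e-9)
  expect_equal(back$l_thyroxine, sim$cohort$l_thyroxine)
})

test_that("adult exclusion keeps age < 18 and reports the excluded fraction", {
  cohort <- structure(data.frame(id = letters[1:4], sex = "female",
                                 age_years = c(4, 17.9, 18.0, 25),
                                 weight_kg = 30, height_cm = 120,
                                 bmi = bmi(30, 1.2)),
                      class = c("cohort", "data.frame"))
  kept <- suppressMessages(exclude_adults(cohort))
  expect_equal(kept$age_years, c(4, 17.9))
  expect_equal(attr(kept, "adult_exclusion"),
               list(excluded = 2L, fraction = 0.5))
  all_kids <- suppressMessages(exclude_adults(kept))
  expect_equal(nrow(all_kids), 2)
  empty <- suppressMessages(exclude_adults(cohort[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("standardization recovers the simulated z against the truth chart", {
  pair <- default_pair()
  sim <- simulate_cohort(simulate_config(n = 200, seed = 31), pair)
  std <- standardize_cohort(sim$cohort, pair$standard, pair$specialized)
  spec <- std[std$reference == "specialized", ]
  for (m in c("height", "weight", "bmi")) {
    col <- paste0("z_", m)
    got <- spec$z[spec$measure == m][match(sim$truth$id,
                                           spec$id[spec$measure == m])]
    expect_equal(got, sim$truth[[col]], tolerance = 1e-9)
  }
  # centile consistent with z through the normal CDF
  expect_equal(std$centile, 100 * pnorm(std$z), tolerance = 1e-9)
})

test_that("children at the chart median score zero on both references", {
  pair <- make_reference_pair(make_base_reference(), delta = 0, sd_ratio = 1)
  set <- pair$standard
  ages <- c(2, 9.5)
  h <- interpolate_lms(ref_for(set, "height", "male"), ages)$M
  w <- interpolate_lms(ref_for(set, "weight", "male"), ages)$M
  cohort <- structure(data.frame(id = c("m1", "m2"), sex = "male",
                                 age_years = ages, weight_kg = w,
                                 height_cm = h, bmi = bmi(w, cm_to_m(h))),
                      class = c("cohort", "data.frame"))
  std <- standardize_cohort(cohort, pair$standard, pair$specialized)
  expect_equal(std$z[std$measure != "bmi"], rep(0, 8), tolerance = 1e-9)
})

test_that("children outside a reference span are flagged, never dropped", {
  narrow <- lms_reference_set(lapply(make_base_reference(), function(r) {
    lms_reference(r$age[r$age <= 10], r$L[r$age <= 10], r$M[r$age <= 10],
                  r$S[r$age <= 10], attr(r, "measure"), attr(r, "sex"),
                  "narrow")
  }))
  pair <- default_pair()
  cohort <- structure(data.frame(id = c("in", "out"), sex = "female",
                                 age_years = c(5, 15), weight_kg = c(18, 50),
                                 height_cm = c(105, 160),
                                 bmi = bmi(c(18, 50), cm_to_m(c(105, 160)))),
                      class = c("cohort", "data.frame"))
  std <- standardize_cohort(cohort, narrow, pair$specialized)
  flagged <- std[std$reference == "standard" & std$id == "out", ]
  expect_equal(nrow(flagged), 3)
  expect_false(any(flagged$in_range))
  expect_true(all(is.na(flagged$z)))
  expect_true(all(std$in_range[std$reference == "specialized"]))
  # flagged records stay out of the tallies
  tab <- band_table(std)
  expect_equal(unname(tab$totals["standard", ]), rep(1, 3))
  expect_equal(unname(tab$totals["specialized", ]), rep(2, 3))
})
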