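test_that("reader echoes a valid table and enforces each invariant distinctly", {
  path <- write_ref_file(c("sex,age,L,M,S", "M,1.0,1,10,0.1", "M,2.0,1,12,0.1"))
  ref <- read_lms_reference(path, measure = "weight", sex = "male")
  expect_s3_class(ref, "lms_reference")
  expect_equal(nrow(ref), 2)
  expect_equal(range(ref$age), c(1, 2))
  expect_equal(ref$M, c(10, 12))

  bad_order <- write_ref_file(c("sex,age,L,M,S", "M,2.0,1,12,0.1", "M,1.0,1,10,0.1"))
  expect_error(read_lms_reference(bad_order, "weight", "male"),
               "non-increasing age")
  bad_s <- write_ref_file(c("sex,age,L,M,S", "M,1.0,1,10,0.1", "M,2.0,1,12,0"))
  expect_error(read_lms_reference(bad_s, "weight", "male"), "S <= 0 at row 2")
  bad_m <- write_ref_file(c("sex,age,L,M,S", "M,1.0,1,-3,0.1", "M,2.0,1,12,0.1"))
  expect_error(read_lms_reference(bad_m, "weight", "male"), "M <= 0 at row 1")
  bad_cell <- write_ref_file(c("sex,age,L,M,S", "M,1.0,1,ten,0.1", "M,2.0,1,12,0.1"))
  expect_error(read_lms_reference(bad_cell, "weight", "male"),
               "non-numeric cell in column 'M' at row 1")
  no_col <- write_ref_file(c("sex,age,L,M", "M,1.0,1,10", "M,2.0,1,12"))
  expect_error(read_lms_reference(no_col, "weight", "male"), "missing column")
})

test_that("reader supports sex filters, numeric sex codes and age-in-months", {
  path <- write_ref_file(c("sex\tage\tL\tM\tS", "1\t12\t1\t10\t0.1",
                           "1\t24\t1\t12\t0.1", "2\t12\t1\t9\t0.1",
                           "2\t24\t1\t11\t0.1"))
  m <- read_lms_reference(path, "weight", "male", age_in_months = TRUE)
  f <- read_lms_reference(path, "weight", "female", age_in_months = TRUE)
  expect_equal(m$age, c(1, 2))
  expect_equal(m$M, c(10, 12))
  expect_equal(f$M, c(9, 11))

  remap <- write_ref_file(c("Age.yr,lambda,median,cv", "1,1,10,0.1", "2,1,12,0.1"))
  ref <- read_lms_reference(remap, "weight", "male",
                            col_map = c(age = "Age.yr", l = "lambda",
                                        m = "median", s = "cv"))
  expect_equal(ref$M, c(10, 12))
})

test_that("write -> read round trip reproduces numeric content exactly", {
  ref <- lms_reference(c(0.5, 1.25, 7), c(-1.37, 0, 2.2),
                       c(8.123456789, 10.987654321, 33.3),
                       c(0.0811111, 0.12345, 0.2), "bmi", "female", "ds")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lms_reference(ref, path)
  back <- read_lms_reference(path, "bmi", "female", label = "ds")
  expect_equal(back$age, ref$age)
  expect_equal(back$L, ref$L)
  expect_equal(back$M, ref$M)
  expect_equal(back$S, ref$S)

  set <- make_base_reference()
  prefix <- file.path(withr::local_tempdir(), "std")
  write_lms_reference_set(set, prefix)
  back_set <- read_lms_reference_set(prefix)
  for (key in names(set)) {
    expect_equal(back_set[[key]]$M, set[[key]]$M, tolerance = 1e-12)
    expect_equal(back_set[[key]]$S, set[[key]]$S, tolerance = 1e-12)
  }
})

test_that("interpolation is linear between knots, exact at knots, span-guarded", {
  ref <- tiny_ref()
  mid <- interpolate_lms(ref, 1.5)
  expect_equal(unlist(mid[c("L", "M", "S")]), c(L = 1, M = 11, S = 0.1))
  knot <- interpolate_lms(ref, 1.0)
  expect_equal(unlist(knot[c("L", "M", "S")]), c(L = 1, M = 10, S = 0.1))
  expect_error(interpolate_lms(ref, 2.5), "outside tabulated span")
  expect_error(interpolate_lms(ref, 0.99), "outside tabulated span")

  # interpolated M, S stay positive anywhere in span for valid references
  set.seed(11)
  for (rep in 1:20) {
    ages <- sort(runif(5, 0, 18)); ages <- ages + seq_along(ages) * 1e-3
    r <- lms_reference(ages, rnorm(5), runif(5, 0.5, 50), runif(5, 0.01, 0.3),
                       "weight", "female")
    q <- interpolate_lms(r, runif(20, min(ages), max(ages)))
    expect_true(all(q$M > 0 & q$S > 0))
  }
})

test_that("centile curves hit the inverse-LMS values and are monotone in p", {
  ref <- tiny_ref()
  expect_equal(centile_curve_from_lms(ref, 50)$value, ref$M)
  # L=1, M=10, S=0.1, p=3: value = 10 * (1 + 0.1 * qnorm(0.03)) = 8.1192
  expect_equal(centile_curve_from_lms(ref, 3)$value[1],
               10 * (1 + 0.1 * qnorm(0.03)))
  expect_equal(round(centile_curve_from_lms(ref, 3)$value[1], 3), 8.119)
  expect_error(centile_curve_from_lms(ref, 0), "strictly inside")
  expect_error(centile_curve_from_lms(ref, 100), "strictly inside")

  ps <- c(1, 3, 10, 25, 50, 75, 90, 97, 99)
  for (L in c(-1.5, 0, 1)) {
    r <- lms_reference(c(1, 2), L, c(10, 12), 0.1, "weight", "male")
    vals <- vapply(ps, function(p) centile_curve_from_lms(r, p)$value[1], 0)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("centile-curve references support the approximate scorer", {
  ref <- tiny_ref()
  curves <- centile_curve_reference(ref)
  expect_true(all(curves$P3 < curves$P50))
  expect_equal(approx_sds_at_age(curves, x = 11, age = 1.5), 0)  # P50(1.5) = 11
  expect_equal(approx_sds_at_age(curves, curves$P3[1], 1.0), -2)
  expect_error(approx_sds_at_age(curves, 10, age = 5), "outside")
})

test_that("reference sets key members by measure and sex under one label", {
  set <- make_base_reference()
  expect_length(set, 6)
  expect_s3_class(ref_for(set, "bmi", "female"), "lms_reference")
  expect_error(ref_for(set, "weight", "unknown"), "no entry")
  mixed <- list(tiny_ref(label = "a"), tiny_ref(sex = "female", label = "b"))
  expect_error(lms_reference_set(mixed), "share one label")
})
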