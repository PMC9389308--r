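test_that("reference pairs shift the median by delta SDS per measure", {
  base <- lms_reference(c(1, 2), 1, c(100, 110), 0.04, "height", "male")
  pair <- make_reference_pair(base, delta = -2)
  expect_equal(pair$specialized[[1]]$M, c(92, 101.2))  # 100 * (1 + 0.04 * -2)
  expect_equal(pair$specialized[[1]]$S, base$S)
  # identity when delta = 0, sd_ratio = 1
  null_pair <- make_reference_pair(make_base_reference(), delta = 0)
  for (key in names(null_pair$standard)) {
    expect_equal(null_pair$specialized[[key]]$M, null_pair$standard[[key]]$M)
    expect_equal(null_pair$specialized[[key]]$S, null_pair$standard[[key]]$S)
  }
  # infeasible delta names the offending age
  wide <- lms_reference(c(3, 4), -2, c(10, 10), 0.3, "weight", "male")
  expect_error(make_reference_pair(wide, delta = 2), "age 3")
  # sd_ratio scales S
  scaled <- make_reference_pair(base, delta = 0, sd_ratio = 1.5)
  expect_equal(scaled$specialized[[1]]$S, base$S * 1.5)
})

test_that("specialized BMI is derived consistently from shifted weight and height", {
  pair <- default_pair()
  for (sex in c("male", "female")) {
    w <- ref_for(pair$specialized, "weight", sex)
    h <- ref_for(pair$specialized, "height", sex)
    b <- ref_for(pair$specialized, "bmi", sex)
    expect_equal(b$M, w$M / (h$M / 100)^2, tolerance = 1e-12)
  }
  # consequence: a child's derived BMI is standard normal on the truth chart
  sim <- simulate_cohort(simulate_config(n = 4000, seed = 21), pair)
  expect_lt(abs(mean(sim$truth$z_bmi)), 3 / sqrt(4000))
  expect_lt(abs(sd(sim$truth$z_bmi) - 1), 3 / sqrt(2 * 4000))
})

test_that("simulation is seed-deterministic down to written bytes", {
  pair <- default_pair()
  cfg <- simulate_config(n = 1, seed = 123)
  one <- simulate_cohort(cfg, pair)
  expect_equal(nrow(one$cohort), 1)
  two <- simulate_cohort(cfg, pair)
  expect_identical(one$cohort, two$cohort)
  expect_identical(one$truth, two$truth)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_cohort(simulate_cohort(simulate_config(n = 50, seed = 8), pair)$cohort, p1)
  write_cohort(simulate_cohort(simulate_config(n = 50, seed = 8), pair)$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(
    simulate_cohort(simulate_config(n = 50, seed = 9), pair)$cohort$height_cm,
    simulate_cohort(simulate_config(n = 50, seed = 8), pair)$cohort$height_cm))
})

test_that("config invariants are enforced", {
  expect_error(simulate_config(n = 0), "n >= 1")
  expect_error(simulate_config(male_fraction = 1.2), "probabilities")
  expect_error(simulate_config(rho = 1), "rho")
  expect_error(simulate_config(gestation_sd = 0), "positive")
  expect_error(simulate_config(lt_height_sd = c(treated = 0.8)), "untreated")
  expect_error(simulate_config(age = list(dist = "beta", min = 1, max = 2)),
               "unknown age distribution")
  expect_error(simulate_config(age = list(dist = "uniform", min = 5, max = 2)),
               "min")
})

test_that("simulated marginals recover the configured parameters", {
  pair <- default_pair()
  n <- 10000
  sim <- simulate_cohort(simulate_config(n = n, seed = 101), pair)
  truth <- sim$truth
  se_mean <- 1 / sqrt(n); se_sd <- 1 / sqrt(2 * n)
  for (col in c("z_height", "z_weight")) {
    expect_lt(abs(mean(truth[[col]])), 3 * se_mean)
    expect_lt(abs(sd(truth[[col]]) - 1), 3 * se_sd)
  }
  expect_equal(cor(truth$z_height, truth$z_weight), 0.7, tolerance = 0.03)
  expect_lt(abs(mean(sim$cohort$sex == "male") - 0.54),
            3 * sqrt(0.54 * 0.46 / n))
  expect_equal(median(sim$cohort$age_years), 4.85, tolerance = 0.35)
  expect_lt(abs(mean(sim$cohort$birth_weight_g) - 2898), 3 * 513 / sqrt(n))
  expect_lt(abs(mean(sim$cohort$l_thyroxine) - 0.64),
            3 * sqrt(0.64 * 0.36 / n))
  expect_lt(abs(mean(sim$cohort$breastfed) - 0.78),
            3 * sqrt(0.78 * 0.22 / n))
  expect_true(all(sim$cohort$gestational_age_wk >= 22 &
                    sim$cohort$gestational_age_wk <= 43))
  expect_true(all(sim$cohort$birth_weight_g > 0))
})

test_that("classification against the truth chart yields the nominal 3% tail", {
  pair <- default_pair()
  sim <- simulate_cohort(simulate_config(n = 10000, seed = 55), pair)
  std <- standardize_cohort(sim$cohort, pair$standard, pair$specialized)
  tab <- band_table(std)
  for (m in c("height", "weight", "bmi")) {
    expect_equal(tab$percentages["under", "specialized", m],
                 100 * pnorm(-1.88), tolerance = 0.5 / (100 * pnorm(-1.88)))
  }
})

test_that("a delta = -1 chart shift moves the standard-chart under-tail to Phi(-0.88)", {
  pair <- make_reference_pair(make_base_reference(),
                              delta = c(weight = -1, height = -1, bmi = NA))
  sim <- simulate_cohort(simulate_config(n = 10000, seed = 56,
                                         delta = c(weight = -1, height = -1,
                                                   bmi = NA)), pair)
  std <- standardize_cohort(sim$cohort, pair$standard, pair$specialized)
  tab <- band_table(std)
  for (m in c("height", "weight")) {
    expect_equal(tab$percentages["under", "standard", m] / 100,
                 pnorm(-0.88), tolerance = 0.012 / pnorm(-0.88))
  }
})

test_that("discordance sign: delta = -1 raises the standard-chart under share in every replicate", {
  pair <- make_reference_pair(make_base_reference(),
                              delta = c(weight = -1, height = -1, bmi = NA))
  for (rep in 1:50) {
    sim <- simulate_cohort(simulate_config(n = 1000, seed = 900 + rep,
                                           delta = c(weight = -1, height = -1,
                                                     bmi = NA)), pair)
    std <- standardize_cohort(sim$cohort, pair$standard, pair$specialized)
    tab <- band_table(std)
    expect_gt(tab$percentages["under", "standard", "height"],
              tab$percentages["under", "specialized", "height"])
  }
})
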