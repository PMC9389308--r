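# Synthetic growth references and cohorts.
#
# No copyrighted reference tables are shipped; the base reference is a
# smooth synthetic chart with log-normal age slices (L = 0). The key
# property of that choice: when the specialized chart is built by shifting
# the median by delta SDS with unchanged S, a child at specialized-chart
# z-score z_true sits at standard-chart z-score exactly z_true + delta, so
# chart-discordance proportions have a normal-theory closed form the
# recovery tests can check against.

#' Synthetic base growth reference set
#'
#' A smooth synthetic growth chart for weight, height and BMI, both sexes,
#' tabulated from birth to 18 years at 0.1-year knots. Median curves are
#' monotone splines through realistic pediatric anchor values (birth length
#' ~50 cm, adult height ~176/163 cm; birth weight ~3.5 kg, adult weight
#' ~67/55 kg); age slices are log-normal (`L = 0`) with constant
#' coefficients of variation (height 0.04, weight 0.12). The BMI median is
#' derived from the weight and height medians, `M_w / (M_h/100)^2`, and its
#' S is `sqrt(S_w^2 + 4 S_h^2 - 4 rho S_w S_h)` so that the BMI of a child
#' simulated with latent z-correlation `rho` is itself standard normal on
#' the chart.
#'
#' @param ages tabulated knot ages in decimal years.
#' @param s_height,s_weight coefficients of variation.
#' @param rho latent weight-height z correlation the BMI S is matched to;
#'   use the same value as in [simulate_config()].
#' @param label chart label.
#' @return an [lms_reference_set()] with six members.
#' @export
make_base_reference <- function(ages = seq(0, 18, by = 0.1),
                                s_height = 0.04, s_weight = 0.12,
                                rho = 0.7, label = "standard") {
  anchor_age <- c(0, 1, 2, 4, 7, 10, 13, 16, 18)
  anchors <- list(
    male = list(height = c(50, 75, 87, 103, 122, 138, 156, 173, 176),
                weight = c(3.5, 10, 12.5, 16, 23, 32, 45, 61, 67)),
    female = list(height = c(49.5, 74, 86, 102, 121, 138, 157, 162, 163),
                  weight = c(3.4, 9.5, 12, 15.5, 22, 32, 45, 53, 55))
  )
  s_bmi <- sqrt(s_weight^2 + 4 * s_height^2 - 4 * rho * s_weight * s_height)
  refs <- list()
  for (sex in .SEXES) {
    m_h <- stats::splinefun(anchor_age, anchors[[sex]]$height,
                            method = "hyman")(ages)
    m_w <- stats::splinefun(anchor_age, anchors[[sex]]$weight,
                            method = "hyman")(ages)
    refs[[paste0("height.", sex)]] <-
      lms_reference(ages, 0, m_h, s_height, "height", sex, label)
    refs[[paste0("weight.", sex)]] <-
      lms_reference(ages, 0, m_w, s_weight, "weight", sex, label)
    refs[[paste0("bmi.", sex)]] <-
      lms_reference(ages, 0, m_w / (m_h / 100)^2, s_bmi, "bmi", sex, label)
  }
  lms_reference_set(refs)
}

#' Build a standard / specialized reference pair
#'
#' The standard chart is the base set unchanged. The specialized chart has,
#' at every tabulated age, its median moved to the base chart's value at
#' z-score `delta[measure]` — `M_spec = lms_value(delta, L, M, S)` — and
#' its coefficient of variation scaled by `sd_ratio[measure]` (L
#' unchanged). A measurement at specialized-chart z 0 therefore sits at
#' standard-chart z `delta` exactly when `sd_ratio = 1`.
#'
#' A negative `delta` emulates a condition-specific chart for a population
#' that is lighter and shorter than the general one, as for Down syndrome.
#' If `delta` carries no (or an `NA`) BMI entry while weight and height are
#' present, the specialized BMI median is derived from the shifted weight
#' and height medians (`M_w_spec / (M_h_spec/100)^2`), keeping the three
#' specialized curves mutually consistent for simulated children whose BMI
#' is computed from their simulated weight and height.
#'
#' @param base an [lms_reference_set()] (or single [lms_reference()]).
#' @param delta named SDS offsets per measure (e.g. `c(weight = -1,
#'   height = -1.2)`); a scalar is recycled to every measure.
#' @param sd_ratio named positive S multipliers per measure; scalar
#'   recycled.
#' @param label label for the specialized set.
#' @return list of class `lms_reference_pair` with members `standard` and
#'   `specialized`.
#' @export
make_reference_pair <- function(base, delta, sd_ratio = 1,
                                label = "specialized") {
  single <- inherits(base, "lms_reference")
  if (single) base <- lms_reference_set(list(base))
  stopifnot(inherits(base, "lms_reference_set"))
  measures <- unique(vapply(base, attr, "", "measure"))
  if (is.null(names(delta))) delta <- stats::setNames(rep_len(delta, length(measures)), measures)
  if (is.null(names(sd_ratio))) sd_ratio <- stats::setNames(rep_len(sd_ratio, length(measures)), measures)
  if (any(sd_ratio <= 0, na.rm = TRUE)) stop("sd_ratio must be positive")

  shift_one <- function(ref, d, sr) {
    arg_ok <- abs(ref$L) < .L_EPS | (1 + ref$L * ref$S * d) > 0
    if (!all(arg_ok)) {
      stop(sprintf("delta %g infeasible at age %g: 1 + L*S*delta <= 0",
                   d, ref$age[which(!arg_ok)[1]]))
    }
    lms_reference(ref$age, ref$L,
                  lms_value(d, ref$L, ref$M, ref$S), ref$S * sr,
                  attr(ref, "measure"), attr(ref, "sex"), label)
  }

  spec <- list()
  for (key in names(base)) {
    ref <- base[[key]]
    m <- attr(ref, "measure")
    d <- if (m %in% names(delta)) delta[[m]] else NA_real_
    sr <- if (m %in% names(sd_ratio)) sd_ratio[[m]] else 1
    if (m == "bmi" && is.na(d)) next  # derived below
    if (is.na(d)) stop("no delta given for measure '", m, "'")
    spec[[key]] <- shift_one(ref, d, sr)
  }
  # derive specialized BMI from shifted weight and height when unspecified
  for (key in names(base)) {
    ref <- base[[key]]
    if (attr(ref, "measure") != "bmi" || !is.null(spec[[key]])) next
    sex <- attr(ref, "sex")
    w <- spec[[paste0("weight.", sex)]]; h <- spec[[paste0("height.", sex)]]
    if (is.null(w) || is.null(h)) {
      stop("cannot derive specialized BMI without weight and height references")
    }
    sr <- if ("bmi" %in% names(sd_ratio)) sd_ratio[["bmi"]] else 1
    spec[[key]] <- lms_reference(ref$age, ref$L, w$M / (h$M / 100)^2,
                                 ref$S * sr, "bmi", sex, label)
  }
  structure(list(standard = base,
                 specialized = lms_reference_set(spec[names(base)])),
            class = "lms_reference_pair")
}

#' Simulation configuration
#'
#' Defaults emulate the marginals of a national Down-syndrome cohort:
#' 54% boys; ages young-skewed with median 4.85 years (truncated
#' log-normal on [0.1, 18]); birth weight 2898 +/- 513 g (truncated at 0);
#' gestational age 37.7 +/- 2.17 weeks (truncated to [22, 43]); 78%
#' breastfed; 64% on L-thyroxine. Growth is shifted relative to the
#' standard chart by `delta` SDS per measure (weight -1, height -1.2 by
#' default; the specialized BMI curve is derived from those unless a BMI
#' delta is supplied).
#'
#' `lt_height_sd`, when non-`NULL`, couples the L-thyroxine flag to height
#' dispersion: treated / untreated children get height-z standard
#' deviations `lt_height_sd["treated"]` / `["untreated"]` instead of 1.
#' It is `NULL` by default so that emitted truth z-scores are exactly
#' standard normal; set it (e.g. `c(treated = 0.8, untreated = 1.2)`) for
#' subgroup-effect scenarios.
#'
#' @param n number of children (>= 1).
#' @param seed integer random seed (mandatory; echoed in outputs).
#' @param male_fraction probability a child is male.
#' @param age list describing the age distribution: `dist` one of
#'   `"lognormal"` (`meanlog`, `sdlog`, truncated to `[min, max]`),
#'   `"loguniform"` or `"uniform"` (`min`, `max`).
#' @param delta named SDS offset of the specialized chart per measure.
#' @param sd_ratio named S multiplier of the specialized chart per measure.
#' @param rho latent weight-height z-score correlation, |rho| < 1.
#' @param truth which chart the cohort actually follows (`"specialized"`
#'   for a condition cohort, `"standard"` for a null scenario).
#' @param birth_weight_mean,birth_weight_sd grams.
#' @param gestation_mean,gestation_sd weeks, truncated to [22, 43].
#' @param breastfed_prob,l_thyroxine_prob probabilities.
#' @param lt_height_sd `NULL`, or named vector `c(treated=, untreated=)`.
#' @return validated list of class `sim_config`.
#' @export
simulate_config <- function(n = 386, seed = 20220805,
                            male_fraction = 0.54,
                            age = list(dist = "lognormal", meanlog = 1.734928,
                                       sdlog = 1, min = 0.1, max = 18),
                            delta = c(weight = -1, height = -1.2, bmi = NA),
                            sd_ratio = c(weight = 1, height = 1, bmi = 1),
                            rho = 0.7,
                            truth = c("specialized", "standard"),
                            birth_weight_mean = 2898, birth_weight_sd = 513,
                            gestation_mean = 37.7, gestation_sd = 2.17,
                            breastfed_prob = 0.78, l_thyroxine_prob = 0.64,
                            lt_height_sd = NULL) {
  truth <- match.arg(truth)
  stopifnot(n >= 1, n == round(n))
  if (is.null(seed) || !is.finite(seed)) stop("a finite integer seed is required")
  for (p in c(male_fraction, breastfed_prob, l_thyroxine_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (birth_weight_sd <= 0 || gestation_sd <= 0) stop("SDs must be positive")
  if (!is.null(lt_height_sd)) {
    if (!all(c("treated", "untreated") %in% names(lt_height_sd)) ||
        any(lt_height_sd <= 0)) {
      stop("lt_height_sd must be c(treated = , untreated = ), both positive")
    }
  }
  if (!age$dist %in% c("lognormal", "loguniform", "uniform")) {
    stop("unknown age distribution: ", age$dist)
  }
  if (age$min <= 0 || age$max <= age$min) stop("need 0 < age$min < age$max")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 male_fraction = male_fraction, age = age, delta = delta,
                 sd_ratio = sd_ratio, rho = rho, truth = truth,
                 birth_weight_mean = birth_weight_mean,
                 birth_weight_sd = birth_weight_sd,
                 gestation_mean = gestation_mean,
                 gestation_sd = gestation_sd,
                 breastfed_prob = breastfed_prob,
                 l_thyroxine_prob = l_thyroxine_prob,
                 lt_height_sd = lt_height_sd),
            class = "sim_config")
}

.draw_ages <- function(age, n) {
  switch(age$dist,
    lognormal = {
      lo <- stats::plnorm(age$min, age$meanlog, age$sdlog)
      hi <- stats::plnorm(age$max, age$meanlog, age$sdlog)
      stats::qlnorm(stats::runif(n, lo, hi), age$meanlog, age$sdlog)
    },
    loguniform = exp(stats::runif(n, log(age$min), log(age$max))),
    uniform = stats::runif(n, age$min, age$max)
  )
}

.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort with the structure the dual-chart analysis assumes: per
#' child, sex ~ Bernoulli(`male_fraction`); age from the configured
#' distribution; latent `(z_height, z_weight)` bivariate standard normal
#' with correlation `rho`; height and weight realized through the inverse
#' LMS transform of the *truth* chart at the child's sex and age; BMI
#' derived from the simulated weight and height; covariates from truncated
#' normal / Bernoulli marginals. The true z-scores (including the BMI z
#' against the truth chart) are emitted alongside for parameter-recovery
#' tests. Fully determined by `config$seed`.
#'
#' @param config a [simulate_config()].
#' @param refs an `lms_reference_pair` from [make_reference_pair()] (or a
#'   list with members `standard` and `specialized`).
#' @return list with `cohort` (a `cohort` data frame), `truth` (data frame
#'   of true z-scores per child) and `config`.
#' @export
simulate_cohort <- function(config, refs) {
  stopifnot(inherits(config, "sim_config"))
  truth_set <- refs[[config$truth]]
  stopifnot(inherits(truth_set, "lms_reference_set"))
  set.seed(config$seed)
  n <- config$n
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  span <- range(truth_set[[1]]$age)
  age <- pmin(pmax(.draw_ages(config$age, n), span[1]), span[2])

  # latent z: bivariate standard normal, corr rho
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  z_h <- z1
  z_w <- config$rho * z1 + sqrt(1 - config$rho^2) * z2

  l_thy <- stats::runif(n) < config$l_thyroxine_prob
  if (!is.null(config$lt_height_sd)) {
    z_h <- z_h * ifelse(l_thy, config$lt_height_sd[["treated"]],
                        config$lt_height_sd[["untreated"]])
  }

  height <- weight <- numeric(n)
  for (s in .SEXES) {
    idx <- which(sex == s)
    if (!length(idx)) next
    lh <- interpolate_lms(ref_for(truth_set, "height", s), age[idx])
    lw <- interpolate_lms(ref_for(truth_set, "weight", s), age[idx])
    height[idx] <- lms_value(z_h[idx], lh$L, lh$M, lh$S)
    weight[idx] <- lms_value(z_w[idx], lw$L, lw$M, lw$S)
  }
  bmi_val <- bmi(weight, cm_to_m(height))
  z_b <- numeric(n)
  for (s in .SEXES) {
    idx <- which(sex == s)
    if (!length(idx)) next
    lb <- interpolate_lms(ref_for(truth_set, "bmi", s), age[idx])
    z_b[idx] <- lms_z(bmi_val[idx], lb$L, lb$M, lb$S)
  }

  breastfed <- stats::runif(n) < config$breastfed_prob
  cohort <- data.frame(
    id = sprintf("sim%05d", seq_len(n)),
    sex = sex,
    age_years = age,
    weight_kg = weight,
    height_cm = height,
    bmi = bmi_val,
    birth_weight_g = .rnorm_trunc(n, config$birth_weight_mean,
                                  config$birth_weight_sd, 0, Inf),
    gestational_age_wk = .rnorm_trunc(n, config$gestation_mean,
                                      config$gestation_sd, 22, 43),
    breastfed = breastfed,
    breastfed_months = ifelse(breastfed,
                              round(stats::qlnorm(stats::runif(n),
                                                  log(9), 0.8), 1), NA),
    l_thyroxine = l_thy,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cohort", "data.frame")
  attr(cohort, "validation") <- data.frame(row = integer(), field = character(),
                                           message = character())
  truth <- data.frame(id = cohort$id, z_height = z_h, z_weight = z_w,
                      z_bmi = z_b, truth_reference = config$truth,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth, config = config)
}
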