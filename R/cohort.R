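# Cohort I/O, validation, adult exclusion, and dual-reference
# standardization.

.COHORT_NUMERIC <- c("age_years", "weight_kg", "height_cm", "birth_weight_g",
                     "gestational_age_wk", "breastfed_months")
.COHORT_FLAGS <- c("breastfed", "l_thyroxine")

.parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "f", "no", "n")] <- FALSE
  out
}

#' Load a cohort table from delimited text
#'
#' Reads a comma- or tab-delimited file (auto-detected), one child per row.
#' Recognized columns (case-insensitive): `id`, `sex` (F/M or female/male),
#' either `age_years` or the pair `birth_date`/`exam_date` (ISO 8601; the
#' decimal age is then `(exam_date - birth_date) / 365.25`), `weight_kg`,
#' `height_cm`, and the optional covariates `birth_weight_g`,
#' `gestational_age_wk`, `breastfed`, `breastfed_months`, `l_thyroxine`.
#' BMI is derived as `weight_kg / (height_cm/100)^2`.
#'
#' Malformed rows (non-positive weight or height, missing or negative age,
#' unknown sex) are dropped and collected into a validation report attached
#' as `attr(, "validation")`, a data frame with the 1-based data row number,
#' field and message. Loading fails only when no valid rows remain.
#'
#' @param path file path.
#' @return a data frame of class `cohort` with columns `id`, `sex`,
#'   `age_years`, `weight_kg`, `height_cm`, `bmi`, and any covariates
#'   present; validation report in `attr(, "validation")`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.table(path, sep = .detect_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (!"id" %in% names(df)) df$id <- as.character(seq_len(nrow(df)))
  if (!"sex" %in% names(df)) stop("missing column: sex")
  if (!any(c("age_years", "birth_date") %in% names(df))) {
    stop("missing column: age_years (or birth_date + exam_date)")
  }
  for (col in c("weight_kg", "height_cm")) {
    if (!col %in% names(df)) stop("missing column: ", col)
  }

  problems <- data.frame(row = integer(), field = character(),
                         message = character(), stringsAsFactors = FALSE)
  note <- function(row, field, msg) {
    problems[nrow(problems) + 1L, ] <<- list(row, field, msg)
  }

  n <- nrow(df)
  sex <- rep(NA_character_, n)
  known <- c(f = "female", m = "male", female = "female", male = "male",
             "1" = "male", "2" = "female")
  key <- tolower(trimws(df$sex))
  sex[key %in% names(known)] <- unname(known[key[key %in% names(known)]])
  for (i in which(is.na(sex))) note(i, "sex", paste0("unrecognized sex '", df$sex[i], "'"))

  num <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, n))
    v <- suppressWarnings(as.numeric(df[[col]]))
    for (i in which(is.na(v) & nzchar(df[[col]]) & !is.na(df[[col]]))) {
      note(i, col, paste0("non-numeric value '", df[[col]][i], "'"))
    }
    v
  }

  if ("age_years" %in% names(df)) {
    age <- num("age_years")
  } else {
    if (!"exam_date" %in% names(df)) stop("missing column: exam_date")
    bd <- as.Date(df$birth_date, format = "%Y-%m-%d")
    ed <- as.Date(df$exam_date, format = "%Y-%m-%d")
    for (i in which(is.na(bd))) note(i, "birth_date", "unparseable date")
    for (i in which(is.na(ed))) note(i, "exam_date", "unparseable date")
    age <- as.numeric(ed - bd) / 365.25
  }
  weight <- num("weight_kg")
  height <- num("height_cm")

  valid <- !is.na(sex) & is.finite(age) & is.finite(weight) & is.finite(height)
  for (i in which(is.finite(age) & age < 0)) note(i, "age_years", "negative age")
  for (i in which(is.finite(weight) & weight <= 0)) note(i, "weight_kg", "non-positive weight")
  for (i in which(is.finite(height) & height <= 0)) note(i, "height_cm", "non-positive height")
  valid <- valid & age >= 0 & weight > 0 & height > 0
  for (i in which(!valid & !(seq_len(n) %in% problems$row))) {
    note(i, "row", "missing required value")
  }

  out <- data.frame(id = df$id, sex = sex, age_years = age,
                    weight_kg = weight, height_cm = height,
                    stringsAsFactors = FALSE)[valid, , drop = FALSE]
  if (!nrow(out)) {
    stop("no valid rows in ", path, " (", nrow(problems), " rows rejected)")
  }
  out$bmi <- bmi(out$weight_kg, cm_to_m(out$height_cm))
  for (col in setdiff(.COHORT_NUMERIC, c("age_years", "weight_kg", "height_cm"))) {
    if (col %in% names(df)) out[[col]] <- num(col)[valid]
  }
  for (col in .COHORT_FLAGS) {
    if (col %in% names(df)) out[[col]] <- .parse_flag(df[[col]])[valid]
  }
  rownames(out) <- NULL
  attr(out, "validation") <- problems
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort table as tab-delimited text
#'
#' Emits the format [load_cohort()] reads.
#'
#' @param cohort a `cohort` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$bmi <- NULL  # derived; recomputed on load
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exclude adults from a cohort
#'
#' Pediatric growth references end at 18 years, so records with
#' `age_years >= 18` are removed; the count and fraction excluded are
#' reported via `message()` and stored in `attr(, "adult_exclusion")`.
#'
#' @param cohort a `cohort` data frame.
#' @return the cohort restricted to `age_years < 18`.
#' @export
exclude_adults <- function(cohort) {
  keep <- cohort$age_years < 18
  n_excl <- sum(!keep)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- attr(cohort, "validation")
  attr(out, "adult_exclusion") <- list(
    excluded = n_excl,
    fraction = if (nrow(cohort)) n_excl / nrow(cohort) else 0
  )
  class(out) <- c("cohort", "data.frame")
  if (n_excl > 0) {
    message(sprintf("excluded %d adult record(s) (%.1f%% of cohort)",
                    n_excl, 100 * n_excl / nrow(cohort)))
  }
  out
}

#' Standardize a cohort against two growth references
#'
#' For every child, measure (weight, height, BMI) and reference chart, the
#' reference's (L, M, S) are interpolated to the child's age and sex and
#' the measurement is converted to a z-score ([lms_z()]) and centile.
#' Children whose age falls outside a reference's tabulated span are
#' flagged (`in_range = FALSE`, z and centile `NA`) and excluded from that
#' reference's tallies downstream — never silently dropped.
#'
#' @param cohort a `cohort` data frame.
#' @param ref_std the standard (general-population) [lms_reference_set()].
#' @param ref_spec the specialized (condition-specific) reference set.
#' @return a data frame of class `standardized_cohort`, one row per child x
#'   measure x reference, with columns `id`, `sex`, `age_years`, `measure`,
#'   `reference`, `x`, `z`, `centile`, `in_range`.
#' @export
standardize_cohort <- function(cohort, ref_std, ref_spec) {
  stopifnot(inherits(ref_std, "lms_reference_set"),
            inherits(ref_spec, "lms_reference_set"))
  sets <- list(standard = ref_std, specialized = ref_spec)
  values <- list(weight = cohort$weight_kg, height = cohort$height_cm,
                 bmi = cohort$bmi)
  pieces <- list()
  for (ref_name in names(sets)) {
    for (measure in .MEASURES) {
      for (sex in .SEXES) {
        idx <- which(cohort$sex == sex)
        if (!length(idx)) next
        ref <- ref_for(sets[[ref_name]], measure, sex)
        age <- cohort$age_years[idx]
        ok <- in_reference_span(ref, age)
        z <- rep(NA_real_, length(idx))
        if (any(ok)) {
          lms <- interpolate_lms(ref, age[ok])
          z[ok] <- lms_z(values[[measure]][idx][ok], lms$L, lms$M, lms$S)
        }
        pieces[[length(pieces) + 1L]] <- data.frame(
          id = cohort$id[idx], sex = sex, age_years = age,
          measure = measure, reference = ref_name,
          x = values[[measure]][idx], z = z,
          centile = ifelse(is.na(z), NA_real_, 100 * stats::pnorm(z)),
          in_range = ok, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$measure, out$reference, match(out$id, cohort$id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- c(standard = attr(ref_std, "label"),
                           specialized = attr(ref_spec, "label"))
  class(out) <- c("standardized_cohort", "data.frame")
  out
}
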