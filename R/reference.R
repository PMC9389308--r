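# LMS reference tables: construction, validation, file I/O, age
# interpolation, and centile-curve extraction.

.MEASURES <- c("weight", "height", "bmi")
.SEXES <- c("female", "male")

#' Construct an LMS growth reference
#'
#' An `lms_reference` is a validated table of `(age, L, M, S)` rows for one
#' measure and one sex: ages in decimal years, `L` the Box-Cox power, `M`
#' the median in measure units (kg, cm or kg/m^2), `S` the coefficient of
#' variation. Ages must be strictly increasing, `M` and `S` strictly
#' positive, and at least two rows are required so the table spans an age
#' interval.
#'
#' @param age,L,M,S numeric vectors of equal length (>= 2 rows).
#' @param measure one of `"weight"`, `"height"`, `"bmi"`.
#' @param sex one of `"female"`, `"male"`.
#' @param label free-text chart label, e.g. `"standard"` or `"ds"`.
#' @return an object of class `lms_reference` (a data frame with columns
#'   `age`, `L`, `M`, `S` and attributes `measure`, `sex`, `label`).
#' @seealso [read_lms_reference()], [interpolate_lms()]
#' @export
lms_reference <- function(age, L, M, S, measure, sex, label = "standard") {
  measure <- match.arg(measure, .MEASURES)
  sex <- match.arg(sex, .SEXES)
  ref <- data.frame(age = as.numeric(age), L = as.numeric(L),
                    M = as.numeric(M), S = as.numeric(S))
  ref <- ref[order(ref$age), , drop = FALSE]
  rownames(ref) <- NULL
  attr(ref, "measure") <- measure
  attr(ref, "sex") <- sex
  attr(ref, "label") <- as.character(label)
  class(ref) <- c("lms_reference", "data.frame")
  validate_lms_reference(ref)
  ref
}

#' @rdname lms_reference
#' @param ref an `lms_reference` to validate.
#' @return `validate_lms_reference()` returns `ref` invisibly, or raises a
#'   validation error naming the offending row and column.
#' @export
validate_lms_reference <- function(ref) {
  stopifnot(inherits(ref, "lms_reference"))
  for (col in c("age", "L", "M", "S")) {
    bad <- which(!is.finite(ref[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric cell in column '%s' at row %d", col, bad[1]))
    }
  }
  if (nrow(ref) < 2) stop("reference needs at least 2 rows, got ", nrow(ref))
  if (any(diff(ref$age) <= 0)) {
    i <- which(diff(ref$age) <= 0)[1]
    stop(sprintf("non-increasing age at row %d (age %g follows %g)",
                 i + 1, ref$age[i + 1], ref$age[i]))
  }
  if (any(ref$M <= 0)) {
    stop(sprintf("M <= 0 at row %d", which(ref$M <= 0)[1]))
  }
  if (any(ref$S <= 0)) {
    stop(sprintf("S <= 0 at row %d", which(ref$S <= 0)[1]))
  }
  invisible(ref)
}

#' @export
print.lms_reference <- function(x, ...) {
  cat(sprintf("<lms_reference> %s, %s, label '%s': %d rows, ages %g-%g y\n",
              attr(x, "measure"), attr(x, "sex"), attr(x, "label"),
              nrow(x), min(x$age), max(x$age)))
  invisible(x)
}

# Detect comma vs tab delimiter from the header line.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

# Map configurable / case-insensitive header names onto canonical ones.
.map_columns <- function(df, col_map, required) {
  names(df) <- tolower(names(df))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      have <- tolower(col_map[[canon]])
      if (have %in% names(df)) names(df)[names(df) == have] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

# Decode a sex column given a codes mapping like c(F = "female", M = "male").
.decode_sex <- function(x, sex_codes) {
  x <- trimws(as.character(x))
  out <- unname(sex_codes[toupper(x)])
  out[tolower(x) %in% .SEXES] <- tolower(x)[tolower(x) %in% .SEXES]
  bad <- which(is.na(out) | !(out %in% .SEXES))
  if (length(bad)) {
    stop(sprintf("unrecognized sex code '%s' at row %d", x[bad[1]], bad[1]))
  }
  out
}

#' Read an LMS reference table from delimited text
#'
#' Reads a comma- or tab-delimited file (auto-detected) with a header and
#' columns `sex, age, L, M, S` (case-insensitive; remappable through
#' `col_map`). A file may hold both sexes; `sex` selects one. Ages may be
#' tabulated in months (`age_in_months = TRUE` divides by 12).
#'
#' @param path file path.
#' @param measure measure the table describes: `"weight"`, `"height"`, `"bmi"`.
#' @param sex which sex to extract (`"female"` or `"male"`). If the file has
#'   no `sex` column, all rows are taken to belong to `sex`.
#' @param label chart label stored on the result.
#' @param col_map optional named character vector mapping canonical names to
#'   the file's header names, e.g. `c(age = "Age.yr", M = "median")`.
#' @param sex_codes named character vector decoding the file's sex codes;
#'   default accepts `F`/`M` and `1`/`2` (1 = male, 2 = female, the common
#'   anthropometric coding).
#' @param age_in_months set `TRUE` if the age column is in months.
#' @return a validated [lms_reference()], rows sorted by age.
#' @export
read_lms_reference <- function(path, measure, sex, label = "standard",
                               col_map = NULL,
                               sex_codes = c(F = "female", M = "male",
                                             "1" = "male", "2" = "female"),
                               age_in_months = FALSE) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  sex <- match.arg(sex, .SEXES)
  df <- utils::read.table(path, sep = .detect_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character")
  df <- .map_columns(df, col_map, required = c("age", "l", "m", "s"))
  names(df)[names(df) == "l"] <- "L"
  names(df)[names(df) == "m"] <- "M"
  names(df)[names(df) == "s"] <- "S"
  if ("sex" %in% names(df)) {
    df <- df[.decode_sex(df$sex, sex_codes) == sex, , drop = FALSE]
    if (!nrow(df)) stop("no rows for sex '", sex, "' in ", path)
  }
  for (col in c("age", "L", "M", "S")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric cell in column '%s' at row %d: '%s'",
                   col, bad[1], df[[col]][bad[1]]))
    }
    df[[col]] <- v
  }
  age <- if (age_in_months) df$age / 12 else df$age
  # construct without re-sorting first so genuinely non-increasing input is
  # reported rather than silently repaired
  if (any(diff(age) <= 0) && !identical(order(age), seq_along(age))) {
    i <- which(diff(age) <= 0)[1]
    stop(sprintf("non-increasing age at row %d (age %g follows %g)",
                 i + 1, age[i + 1], age[i]))
  }
  lms_reference(age, df$L, df$M, df$S, measure = measure, sex = sex,
                label = label)
}

#' Write an LMS reference to tab-delimited text
#'
#' Emits the same format [read_lms_reference()] consumes (columns
#' `sex, age, L, M, S`), so read-write-read round trips reproduce the
#' numeric content exactly.
#'
#' @param ref an [lms_reference()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lms_reference <- function(ref, path) {
  stopifnot(inherits(ref, "lms_reference"))
  out <- data.frame(sex = toupper(substr(attr(ref, "sex"), 1, 1)),
                    age = ref$age, L = ref$L, M = ref$M, S = ref$S)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolate L, M, S at arbitrary ages
#'
#' Piecewise-linear interpolation in age, applied independently to each of
#' L, M and S between the bracketing tabulated rows; exact at the knots.
#' No extrapolation: ages outside the tabulated span raise an error, since
#' silent extrapolation would corrupt downstream classifications.
#'
#' @param ref an [lms_reference()].
#' @param age decimal ages, all within the tabulated span.
#' @return a data frame with columns `age`, `L`, `M`, `S`.
#' @export
interpolate_lms <- function(ref, age) {
  stopifnot(inherits(ref, "lms_reference"))
  if (any(!is.finite(age))) stop("`age` must be finite")
  lo <- min(ref$age); hi <- max(ref$age)
  if (any(age < lo | age > hi)) {
    bad <- age[age < lo | age > hi][1]
    stop(sprintf("age %g outside tabulated span [%g, %g]; no extrapolation",
                 bad, lo, hi))
  }
  data.frame(
    age = age,
    L = stats::approx(ref$age, ref$L, xout = age)$y,
    M = stats::approx(ref$age, ref$M, xout = age)$y,
    S = stats::approx(ref$age, ref$S, xout = age)$y
  )
}

#' Is an age inside a reference's tabulated span?
#'
#' @param ref an [lms_reference()].
#' @param age decimal ages.
#' @return logical vector.
#' @export
in_reference_span <- function(ref, age) {
  age >= min(ref$age) & age <= max(ref$age)
}

#' Extract a centile curve from an LMS reference
#'
#' Evaluates the measurement value at centile `p` for every tabulated age:
#' `lms_value(qnorm(p/100), L, M, S)`. The 50th centile curve equals the M
#' column exactly.
#'
#' @param ref an [lms_reference()].
#' @param p centile in percent, strictly inside (0, 100).
#' @return a data frame with columns `age`, `value`.
#' @export
centile_curve_from_lms <- function(ref, p) {
  stopifnot(inherits(ref, "lms_reference"), length(p) == 1L)
  z <- centile_to_z(p)
  data.frame(age = ref$age, value = lms_value(z, ref$L, ref$M, ref$S))
}

#' Build a P3/P50 centile-curve reference
#'
#' A reduced reference holding only the 3rd and 50th centile curves, the
#' inputs of the approximate scorer [approx_sds()]. The invariant
#' `P3 < P50` at every age follows from monotonicity of the LMS quantile
#' function.
#'
#' @param ref an [lms_reference()].
#' @return an object of class `centile_curve_reference` (data frame with
#'   columns `age`, `P3`, `P50`; attributes `measure`, `sex`, `label`).
#' @export
centile_curve_reference <- function(ref) {
  stopifnot(inherits(ref, "lms_reference"))
  out <- data.frame(age = ref$age,
                    P3 = centile_curve_from_lms(ref, 3)$value,
                    P50 = centile_curve_from_lms(ref, 50)$value)
  if (any(out$P3 >= out$P50)) {
    stop("invalid curves: P3 must lie below P50 at every age")
  }
  attr(out, "measure") <- attr(ref, "measure")
  attr(out, "sex") <- attr(ref, "sex")
  attr(out, "label") <- attr(ref, "label")
  class(out) <- c("centile_curve_reference", "data.frame")
  out
}

#' Approximate SDS of a measurement against a centile-curve reference
#'
#' Interpolates the P3 and P50 curves linearly to the child's age and
#' applies [approx_sds()].
#'
#' @param curve_ref a [centile_curve_reference()].
#' @param x measurement.
#' @param age decimal age within the curve's span.
#' @return approximate SDS.
#' @export
approx_sds_at_age <- function(curve_ref, x, age) {
  stopifnot(inherits(curve_ref, "centile_curve_reference"))
  lo <- min(curve_ref$age); hi <- max(curve_ref$age)
  if (any(age < lo | age > hi)) {
    stop(sprintf("age outside tabulated span [%g, %g]", lo, hi))
  }
  p3 <- stats::approx(curve_ref$age, curve_ref$P3, xout = age)$y
  p50 <- stats::approx(curve_ref$age, curve_ref$P50, xout = age)$y
  approx_sds(x, p50, p3)
}

#' A set of LMS references covering measures and sexes
#'
#' Analyses standardize three measures for both sexes, so references travel
#' as a set: a named list keyed `"<measure>.<sex>"`. All members must share
#' one chart label.
#'
#' @param ... `lms_reference` objects (or a single list of them).
#' @return an object of class `lms_reference_set`.
#' @export
lms_reference_set <- function(...) {
  refs <- list(...)
  if (length(refs) == 1L && !inherits(refs[[1]], "lms_reference")) {
    refs <- refs[[1]]
  }
  stopifnot(length(refs) >= 1, all(vapply(refs, inherits, TRUE, "lms_reference")))
  labels <- unique(vapply(refs, attr, "", "label"))
  if (length(labels) != 1L) {
    stop("all references in a set must share one label, got: ",
         paste(labels, collapse = ", "))
  }
  names(refs) <- vapply(refs, function(r) {
    paste(attr(r, "measure"), attr(r, "sex"), sep = ".")
  }, "")
  if (anyDuplicated(names(refs))) stop("duplicate (measure, sex) in set")
  structure(refs, class = "lms_reference_set", label = labels)
}

#' @rdname lms_reference_set
#' @param set an `lms_reference_set`.
#' @param measure,sex the member to extract.
#' @return `ref_for()`: the matching [lms_reference()].
#' @export
ref_for <- function(set, measure, sex) {
  stopifnot(inherits(set, "lms_reference_set"))
  key <- paste(measure, sex, sep = ".")
  if (is.null(set[[key]])) {
    stop("reference set '", attr(set, "label"), "' has no entry for ", key)
  }
  set[[key]]
}

#' @export
print.lms_reference_set <- function(x, ...) {
  cat(sprintf("<lms_reference_set> label '%s' with %d references: %s\n",
              attr(x, "label"), length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Write every member of a reference set
#'
#' One tab-delimited file per measure, both sexes per file, named
#' `<prefix>_<measure>.tsv`.
#'
#' @param set an [lms_reference_set()].
#' @param prefix path prefix for the output files.
#' @return named character vector of written paths, invisibly.
#' @export
write_lms_reference_set <- function(set, prefix) {
  stopifnot(inherits(set, "lms_reference_set"))
  measures <- unique(vapply(set, attr, "", "measure"))
  paths <- character(0)
  for (m in measures) {
    members <- set[vapply(set, function(r) attr(r, "measure") == m, TRUE)]
    rows <- do.call(rbind, lapply(members, function(r) {
      data.frame(sex = toupper(substr(attr(r, "sex"), 1, 1)),
                 age = r$age, L = r$L, M = r$M, S = r$S)
    }))
    path <- paste0(prefix, "_", m, ".tsv")
    utils::write.table(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[m] <- path
  }
  invisible(paths)
}

#' Read a reference set written by [write_lms_reference_set()]
#'
#' @param prefix the path prefix used when writing.
#' @param measures measures to read.
#' @param label chart label for the set.
#' @return an [lms_reference_set()].
#' @export
read_lms_reference_set <- function(prefix, measures = .MEASURES,
                                   label = "standard") {
  refs <- list()
  for (m in measures) {
    path <- paste0(prefix, "_", m, ".tsv")
    for (s in .SEXES) {
      refs[[paste(m, s, sep = ".")]] <-
        read_lms_reference(path, measure = m, sex = s, label = label)
    }
  }
  lms_reference_set(refs)
}
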