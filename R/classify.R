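# Percentile-band classification of z-scores.
#
# The five-band scheme follows the published cutoff table verbatim: bands at
# SDS -1.88, -1.66, 1.66, 1.88 nominally corresponding to the 3rd, 10th,
# 90th and 97th percentile. Note that +/-1.66 SDS is *not* the normal
# quantile of the 10th/90th percentile (that would be +/-1.2816); the scheme
# is defined in SDS terms and we classify as printed. `cutoff_mode =
# "quantile"` swaps in the exact normal quantiles for sensitivity checks.

.FIVE_LABELS <- list(
  weight = c("Underweight", "Normal", "Normal", "Overweight", "Obesity"),
  height = c("Growth deficiency", "Normal", "Normal", "Normal", "High growth"),
  bmi    = c("Underweight", "Normal", "Normal", "Overweight", "Obesity")
)
.THREE_LABELS <- c("under", "norm", "over")

#' Band classification scheme
#'
#' Bundles the SDS cutoffs and labels used to classify z-scores into
#' percentile bands. Two schemes are provided: `"three_band"` (below the
#' 3rd centile / the wide norm 3rd-97th / above the 97th) used for the
#' headline dual-chart comparison, and `"five_band"` which additionally
#' flags the 3rd-10th and 90th-97th centile bands (overweight flagging at
#' the 90th).
#'
#' Cutoffs default to the published SDS values (-1.88, -1.66, 1.66, 1.88);
#' `cutoff_mode = "quantile"` uses the exact standard-normal quantiles of
#' the 3rd/10th/90th/97th percentiles instead.
#'
#' @param name `"three_band"` or `"five_band"`.
#' @param cutoff_mode `"printed"` (SDS cutoffs as published) or
#'   `"quantile"` (exact normal quantiles).
#' @return an object of class `band_scheme`: list with `name`, `cutoff_mode`,
#'   `cutoffs` (ordered SDS thresholds), and `labels`.
#' @export
band_scheme <- function(name = c("three_band", "five_band"),
                        cutoff_mode = c("printed", "quantile")) {
  name <- match.arg(name)
  cutoff_mode <- match.arg(cutoff_mode)
  cuts5 <- switch(cutoff_mode,
    printed  = c(-1.88, -1.66, 1.66, 1.88),
    quantile = stats::qnorm(c(0.03, 0.10, 0.90, 0.97))
  )
  cutoffs <- if (name == "three_band") cuts5[c(1, 4)] else cuts5
  structure(list(name = name, cutoff_mode = cutoff_mode, cutoffs = cutoffs,
                 labels = if (name == "three_band") .THREE_LABELS
                          else .FIVE_LABELS),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> %s (%s cutoffs): %s\n", x$name, x$cutoff_mode,
              paste(format(x$cutoffs, digits = 5), collapse = ", ")))
  invisible(x)
}

# Five-band index with the published boundary inclusivities:
#   1: z <  c1         (< 3rd)
#   2: c1 <= z < c2    (3rd-10th)
#   3: c2 <= z <= c3   (10th-90th)
#   4: c3 <  z <= c4   (90th-97th)
#   5: z >  c4         (> 97th)
# Mutually exclusive and exhaustive over the reals.
.band_index5 <- function(z, cuts) {
  ifelse(z < cuts[1], 1L,
  ifelse(z < cuts[2], 2L,
  ifelse(z <= cuts[3], 3L,
  ifelse(z <= cuts[4], 4L, 5L))))
}

#' Five-band classification of a z-score
#'
#' Maps a z-score to one of five percentile bands and returns the
#' measure-specific label: for weight and BMI the bands read Underweight /
#' Normal / Normal / Overweight / Obesity; for height Growth deficiency /
#' Normal / Normal / Normal / High growth. Boundary inclusivity follows the
#' published table: z = -1.88 falls in the 3rd-10th band (Normal),
#' z = 1.88 in the 90th-97th band.
#'
#' @param z finite z-scores.
#' @param measure `"weight"`, `"height"` or `"bmi"`.
#' @param scheme a five-band [band_scheme()].
#' @return factor of band labels, levels in band order.
#' @export
classify_five <- function(z, measure, scheme = band_scheme("five_band")) {
  measure <- match.arg(measure, .MEASURES)
  stopifnot(inherits(scheme, "band_scheme"), scheme$name == "five_band")
  if (any(!is.finite(z))) stop("`z` must be finite")
  labels <- scheme$labels[[measure]]
  factor(labels[.band_index5(z, scheme$cutoffs)], levels = unique(labels))
}

#' @rdname classify_five
#' @return `band_index_five()`: integer band index 1-5 (1 = below 3rd
#'   centile, 5 = above 97th), non-decreasing in `z`.
#' @export
band_index_five <- function(z, scheme = band_scheme("five_band")) {
  stopifnot(inherits(scheme, "band_scheme"), scheme$name == "five_band")
  if (any(!is.finite(z))) stop("`z` must be finite")
  .band_index5(z, scheme$cutoffs)
}

#' Three-band classification of a z-score
#'
#' The wide-norm scheme used for the dual-chart comparison: `under` if
#' z < -1.88 (below the 3rd centile), `norm` if -1.88 <= z <= 1.88 (the
#' wide range of the norm, 3rd-97th), `over` if z > 1.88 (above the 97th).
#' Both boundaries are included in the norm, consistent with the five-band
#' table's inclusivities.
#'
#' @param z finite z-scores.
#' @param scheme a three-band [band_scheme()].
#' @return ordered factor with levels `under < norm < over`.
#' @export
classify_three <- function(z, scheme = band_scheme("three_band")) {
  stopifnot(inherits(scheme, "band_scheme"), scheme$name == "three_band")
  if (any(!is.finite(z))) stop("`z` must be finite")
  idx <- ifelse(z < scheme$cutoffs[1], 1L, ifelse(z <= scheme$cutoffs[2], 2L, 3L))
  factor(.THREE_LABELS[idx], levels = .THREE_LABELS, ordered = TRUE)
}

#' Serialize / restore a band scheme
#'
#' Schemes round-trip through a small JSON config so alternative cutoff
#' sets can be stored alongside results.
#'
#' @param scheme a [band_scheme()].
#' @param path optional file to write; if `NULL`, the JSON string is
#'   returned.
#' @return `scheme_to_json()`: the JSON string (invisibly when written to
#'   `path`); `scheme_from_json()`: a `band_scheme`.
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "band_scheme"))
  json <- jsonlite::toJSON(unclass(scheme), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname scheme_to_json
#' @param json a JSON string or path to a JSON file.
#' @export
scheme_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  scheme <- band_scheme(x$name, x$cutoff_mode)
  # custom cutoffs survive the round trip even if they match neither mode
  scheme$cutoffs <- as.numeric(x$cutoffs)
  scheme
}
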