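# Band contingency tables and the dual-chart comparison statistics.

#' Three-band contingency table across two references
#'
#' Tallies the three-band classification (under / norm / over the wide
#' 3rd-97th centile norm) of a standardized cohort for every measure and
#' both references. Percentages are computed as `100 * count / column
#' total` at full precision; a display copy is rounded half-up to integers.
#' Only records within the reference's age span enter a column's tally, so
#' column totals can differ between references and measures.
#'
#' @param standardized a `standardized_cohort` from [standardize_cohort()].
#' @param scheme a three-band [band_scheme()].
#' @return an object of class `band_table`: list with `counts` (3 bands x
#'   2 references x 3 measures array), `totals`, `percentages` (full
#'   precision), `display` (rounded half-up), and `scheme`.
#' @export
band_table <- function(standardized, scheme = band_scheme("three_band")) {
  stopifnot(inherits(standardized, "standardized_cohort"))
  s <- standardized[standardized$in_range, , drop = FALSE]
  bands <- classify_three(s$z, scheme)
  measures <- intersect(.MEASURES, unique(s$measure))
  refs <- c("standard", "specialized")
  counts <- array(0L, dim = c(3, 2, length(measures)),
                  dimnames = list(band = .THREE_LABELS, reference = refs,
                                  measure = measures))
  for (m in measures) {
    for (r in refs) {
      sel <- s$measure == m & s$reference == r
      counts[, r, m] <- as.integer(table(bands[sel]))
    }
  }
  .band_table_from_array(counts, scheme)
}

.band_table_from_array <- function(counts, scheme) {
  totals <- apply(counts, c(2, 3), sum)
  pct <- sweep(counts, c(2, 3), pmax(totals, 1L), "/") * 100
  for (b in seq_len(dim(pct)[1])) pct[b, , ][totals == 0] <- NA_real_
  structure(list(counts = counts, totals = totals, percentages = pct,
                 display = round_half_up(pct), scheme = scheme),
            class = "band_table")
}

#' Build a band table from published counts
#'
#' Constructs the same `band_table` object directly from per-band counts —
#' e.g. the counts printed in a publication — so percentage and comparison
#' arithmetic can be reproduced without child-level data.
#'
#' @param ... one named matrix per measure (`weight =`, `height =`,
#'   `bmi =`), each 3 bands (under, norm, over — rows) x 2 references
#'   (standard, specialized — columns).
#' @param scheme a three-band [band_scheme()].
#' @return a `band_table`.
#' @examples
#' band_table_from_counts(
#'   weight = cbind(standard = c(108, 280, 13), specialized = c(23, 350, 19))
#' )
#' @export
band_table_from_counts <- function(..., scheme = band_scheme("three_band")) {
  mats <- list(...)
  stopifnot(length(mats) >= 1, all(names(mats) %in% .MEASURES))
  counts <- array(0L, dim = c(3, 2, length(mats)),
                  dimnames = list(band = .THREE_LABELS,
                                  reference = c("standard", "specialized"),
                                  measure = names(mats)))
  for (m in names(mats)) {
    mat <- as.matrix(mats[[m]])
    stopifnot(nrow(mat) == 3, ncol(mat) == 2)
    counts[, , m] <- as.integer(mat)
  }
  .band_table_from_array(counts, scheme)
}

#' @export
print.band_table <- function(x, ...) {
  cat("<band_table> counts (display %):\n")
  for (m in dimnames(x$counts)$measure) {
    cat("  ", m, ":\n", sep = "")
    for (b in dimnames(x$counts)$band) {
      cat(sprintf("    %-6s standard %4d (%2.0f)   specialized %4d (%2.0f)\n",
                  b, x$counts[b, "standard", m], x$display[b, "standard", m],
                  x$counts[b, "specialized", m], x$display[b, "specialized", m]))
    }
  }
  invisible(x)
}

#' Compare the two references for one measure and band
#'
#' Reports the percentage of children falling in `band` under each
#' reference, the percentage-point difference (standard minus specialized),
#' and a Pearson chi-squared test (1 df, no continuity correction by
#' default) on the 2x2 table in-band / out-of-band x standard /
#' specialized chart. When a margin of that table is zero the test is
#' skipped with a warning and the difference is still reported.
#'
#' An independence test on the two columns mirrors common published
#' practice even though the two classifications concern the same children;
#' [compare_references_paired()] provides the statistically preferable
#' McNemar paired test when child-level data are available.
#'
#' @param table a [band_table()].
#' @param measure `"weight"`, `"height"` or `"bmi"`.
#' @param band `"under"`, `"norm"` or `"over"`.
#' @param correct apply Yates' continuity correction.
#' @return an object of class `comparison_result`: list with `measure`,
#'   `band`, `pct_standard`, `pct_specialized`, `pp_difference`
#'   (= pct_standard - pct_specialized, full precision) and `test`
#'   (`statistic`, `df`, `p_value`, or `NULL` if skipped).
#' @export
compare_references <- function(table, measure, band, correct = FALSE) {
  stopifnot(inherits(table, "band_table"))
  measure <- match.arg(measure, dimnames(table$counts)$measure)
  band <- match.arg(band, .THREE_LABELS)
  n_in <- table$counts[band, , measure]
  tot <- table$totals[, measure]
  if (any(tot == 0)) stop("both reference columns must be non-empty")
  m22 <- rbind(in_band = n_in, out_band = tot - n_in)
  test <- NULL
  if (any(rowSums(m22) == 0)) {
    warning("degenerate 2x2 table (zero margin): chi-squared test skipped")
  } else {
    t <- chi_square_test(m22, correct = correct)
    test <- list(statistic = t$statistic, df = t$df, p_value = t$p_value)
  }
  pct <- table$percentages[band, , measure]
  structure(list(measure = measure, band = band,
                 pct_standard = unname(pct["standard"]),
                 pct_specialized = unname(pct["specialized"]),
                 pp_difference = unname(pct["standard"] - pct["specialized"]),
                 test = test),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s, band '%s': %.1f%% vs %.1f%% (%+.2f p.p.)",
              x$measure, x$band, x$pct_standard, x$pct_specialized,
              x$pp_difference))
  if (!is.null(x$test)) {
    cat(sprintf("; chi-sq = %.4g, df = %d, p = %.3g",
                x$test$statistic, x$test$df, x$test$p_value))
  }
  cat("\n")
  invisible(x)
}

#' Paired (McNemar) comparison of the two references
#'
#' Both classifications concern the same children, so the paired design is
#' the statistically preferable view: McNemar's test on the 2x2 table of
#' in-band membership under the standard vs the specialized chart, using
#' only children in range of both references for the measure.
#'
#' @param standardized a `standardized_cohort`.
#' @param measure,band as in [compare_references()].
#' @param scheme a three-band [band_scheme()].
#' @return list with the paired 2x2 `table`, `statistic`, `df`, `p_value`.
#' @export
compare_references_paired <- function(standardized, measure, band,
                                      scheme = band_scheme("three_band")) {
  stopifnot(inherits(standardized, "standardized_cohort"))
  s <- standardized[standardized$measure == measure & standardized$in_range, ]
  std <- s[s$reference == "standard", ]
  spc <- s[s$reference == "specialized", ]
  ids <- intersect(std$id, spc$id)
  in_std <- classify_three(std$z[match(ids, std$id)], scheme) == band
  in_spc <- classify_three(spc$z[match(ids, spc$id)], scheme) == band
  tab <- table(standard = factor(in_std, c(FALSE, TRUE)),
               specialized = factor(in_spc, c(FALSE, TRUE)))
  res <- stats::mcnemar.test(tab)
  list(table = tab, statistic = unname(res$statistic),
       df = unname(res$parameter), p_value = unname(res$p.value))
}

#' L-thyroxine subgroup comparison on height classification
#'
#' Compares the proportion of height classifications falling in the wide
#' norm band (3rd-97th centile) between children on L-thyroxine and those
#' not, using the specified reference chart, with a Pearson chi-squared
#' test on the 2x2 norm / out-of-norm x treated / untreated table.
#'
#' @param standardized a `standardized_cohort`.
#' @param cohort the matching `cohort` with an `l_thyroxine` flag column.
#' @param reference which chart's classification to use.
#' @param scheme a three-band [band_scheme()].
#' @return list with `n_treated`, `n_untreated`, `pct_norm_treated`,
#'   `pct_norm_untreated`, `pp_difference` (treated minus untreated) and
#'   `test`; `NULL` (with a warning) if either subgroup is empty.
#' @export
lthyroxine_subgroup <- function(standardized, cohort,
                                reference = c("standard", "specialized"),
                                scheme = band_scheme("three_band")) {
  reference <- match.arg(reference)
  if (is.null(cohort$l_thyroxine)) stop("cohort has no l_thyroxine column")
  s <- standardized[standardized$measure == "height" &
                      standardized$reference == reference &
                      standardized$in_range, ]
  treated_ids <- cohort$id[which(cohort$l_thyroxine)]
  untreated_ids <- cohort$id[which(!cohort$l_thyroxine)]
  in_norm <- classify_three(s$z, scheme) == "norm"
  grp <- ifelse(s$id %in% treated_ids, "treated",
                ifelse(s$id %in% untreated_ids, "untreated", NA))
  ok <- !is.na(grp)
  if (!any(grp[ok] == "treated") || !any(grp[ok] == "untreated")) {
    warning("empty L-thyroxine subgroup: comparison skipped")
    return(NULL)
  }
  n_t <- sum(grp[ok] == "treated"); n_u <- sum(grp[ok] == "untreated")
  p_t <- 100 * mean(in_norm[ok][grp[ok] == "treated"])
  p_u <- 100 * mean(in_norm[ok][grp[ok] == "untreated"])
  m22 <- rbind(norm = c(treated = sum(in_norm[ok] & grp[ok] == "treated"),
                        untreated = sum(in_norm[ok] & grp[ok] == "untreated")),
               out = c(n_t - sum(in_norm[ok] & grp[ok] == "treated"),
                       n_u - sum(in_norm[ok] & grp[ok] == "untreated")))
  test <- if (any(rowSums(m22) == 0)) {
    warning("degenerate subgroup table: chi-squared test skipped")
    NULL
  } else {
    t <- chi_square_test(m22)
    list(statistic = t$statistic, df = t$df, p_value = t$p_value)
  }
  list(n_treated = n_t, n_untreated = n_u,
       pct_norm_treated = p_t, pct_norm_untreated = p_u,
       pp_difference = p_t - p_u, test = test)
}
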