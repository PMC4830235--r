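# Directional 2x2 chi-square tests of seasonal movement.

#' Build a focal-vs-other 2x2 contingency table
#'
#' Rows are the focal species versus all other reference specimens (the
#' reference set minus the focal species' records -- the two rows are
#' disjoint, unlike the abundance-index denominator). Columns are two
#' disjoint record strata, e.g. two regions or two elevation classes.
#' Records matching neither stratum, or outside the month filter, are
#' excluded.
#'
#' @param focal,reference Cleaned record tibbles (reference may include the
#'   focal species' rows; they are removed from the "other" row by
#'   scientific name).
#' @param months Integer months to include (`NULL` = all).
#' @param stratum_a,stratum_b Predicate functions taking a record tibble
#'   and returning a logical vector; must be disjoint.
#' @param labels Length-2 character stratum labels (A first).
#' @return A `contingency_2x2`: 2x2 integer matrix (rows focal/other) with
#'   a `valid` attribute, `FALSE` when any margin is zero.
#' @export
build_table <- function(focal, reference, months = NULL,
                        stratum_a, stratum_b, labels = c("A", "B")) {
  focal_names <- unique(focal$scientific_name)
  other <- reference[!(reference$scientific_name %in% focal_names), , drop = FALSE]
  in_months <- function(x) if (is.null(months)) rep(TRUE, nrow(x)) else x$month %in% months
  cnt <- function(x, pred) {
    sel <- in_months(x) & pred(x)
    sum(sel, na.rm = TRUE)
  }
  fa <- cnt(focal, stratum_a)
  fb <- cnt(focal, stratum_b)
  oa <- cnt(other, stratum_a)
  ob <- cnt(other, stratum_b)
  tab <- matrix(c(fa, oa, fb, ob), nrow = 2,
                dimnames = list(group = c("focal", "other"), stratum = labels))
  valid <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  structure(tab, valid = valid, class = c("contingency_2x2", "matrix", "array"))
}

# Expected counts from the margins of a 2x2 table.
expected_counts <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Standard Pearson test of independence with 1 degree of freedom, with or
#' without the Yates continuity correction; both statistics are always
#' reported. The direction flag says whether the observed odds ratio
#' (focal enrichment in stratum A relative to stratum B) exceeds 1, i.e.
#' whether the table leans the way a directional prediction with A as the
#' predicted-high stratum would expect.
#'
#' @param tab A [build_table()] result or plain 2x2 matrix.
#' @param correct Apply the Yates continuity correction for the headline
#'   `statistic`/`p_value` (default `TRUE`, the conventional default for
#'   2x2 tables). The other setting is reported alongside either way.
#' @return A `movement_test` object; see [tidy.movement_test()].
#' @export
chisq_2x2 <- function(tab, correct = TRUE) {
  valid <- attr(tab, "valid") %||% (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
  m <- unclass(tab)
  attr(m, "valid") <- NULL
  res <- list(table = m, df = 1L, continuity_correction = correct, valid = valid)
  if (!valid) {
    res[c("statistic", "p_value", "statistic_pearson", "p_pearson",
          "statistic_yates", "p_yates", "odds_ratio", "direction_consistent")] <-
      list(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
           NA_real_, NA)
    class(res) <- "movement_test"
    return(res)
  }
  pear <- suppressWarnings(chisq.test(m, correct = FALSE))
  yate <- suppressWarnings(chisq.test(m, correct = TRUE))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  res$statistic_pearson <- unname(pear$statistic)
  res$p_pearson <- pear$p.value
  res$statistic_yates <- unname(yate$statistic)
  res$p_yates <- yate$p.value
  res$statistic <- if (correct) res$statistic_yates else res$statistic_pearson
  res$p_value <- if (correct) res$p_yates else res$p_pearson
  res$odds_ratio <- or
  res$direction_consistent <- is.finite(or) && or > 1 ||
    (is.infinite(or) && m[1, 1] > 0)
  class(res) <- "movement_test"
  res
}

#' @export
print.movement_test <- function(x, ...) {
  cat("2x2 movement test\n")
  print(x$table)
  if (x$valid) {
    cat(sprintf("X-squared = %.4f (Pearson %.4f / Yates %.4f), df = 1, p = %.4g\n",
                x$statistic, x$statistic_pearson, x$statistic_yates, x$p_value))
    cat(sprintf("odds ratio = %.3f; direction consistent: %s\n",
                x$odds_ratio, x$direction_consistent))
  } else {
    cat("invalid table (empty margin); no test run\n")
  }
  invisible(x)
}

#' @describeIn chisq_2x2 One-row tibble of the test result.
#' @param x A `movement_test`.
#' @param ... Unused.
#' @export
tidy.movement_test <- function(x, ...) {
  tibble(
    focal_a = x$table[1, 1], focal_b = x$table[1, 2],
    other_a = x$table[2, 1], other_b = x$table[2, 2],
    statistic = x$statistic, p_value = x$p_value, df = x$df,
    statistic_pearson = x$statistic_pearson, p_pearson = x$p_pearson,
    statistic_yates = x$statistic_yates, p_yates = x$p_yates,
    odds_ratio = x$odds_ratio,
    direction_consistent = x$direction_consistent,
    continuity_correction = x$continuity_correction,
    valid = x$valid
  )
}

#' Run the four directional movement tests
#'
#' The battery asks, always relative to the "other" reference specimens:
#' Q1 -- is the focal species enriched in NW over NE during molt-stopover?
#' Q2 -- enriched in S over NW in winter (reported both with and without
#' records east of the isthmus exclusion meridian, to guard against an
#' unrelated population wintering on the eastern peninsula)? Q3 -- enriched
#' in NE over NW during spring migration? Q4 -- enriched in lowlands
#' (below the elevation threshold) over uplands, all months pooled,
#' elevation-known records only. The predicted-high stratum is always
#' stratum A, so `direction_consistent = TRUE` means the table leans the
#' predicted way.
#'
#' @param focal,reference Cleaned record tibbles.
#' @param part A [region_partition()].
#' @param periods A [seasonal_periods()].
#' @param correct Continuity-correction setting passed to [chisq_2x2()].
#' @return A `movement_battery` object: a list of `movement_test`s with a
#'   [tidy()] method giving one row per question (five rows: Q2 appears
#'   with and without the isthmus exclusion). No multiplicity adjustment is
#'   applied; the family size (4 questions) is recorded in the output.
#' @export
run_movement_battery <- function(focal, reference, part = region_partition(),
                                 periods = seasonal_periods(), correct = TRUE) {
  reg <- function(x) assign_region(x$latitude, x$longitude, part)
  in_nw <- function(x) reg(x) == "NW"
  in_ne <- function(x) reg(x) == "NE"
  in_s <- function(x) reg(x) == "S"
  lowland <- function(x) classify_elevation(x$elevation_m, part) == "lowland"
  upland <- function(x) classify_elevation(x$elevation_m, part) == "upland"
  west_of_isthmus <- function(x) x |> filter(.data$longitude <= part$tehuantepec_lon)

  specs <- list(
    q1_molt_nw_vs_ne = list(months = periods$molt, a = in_nw, b = in_ne,
                            labels = c("NW", "NE"), exclude_east = FALSE),
    q2_winter_s_vs_nw = list(months = periods$winter, a = in_s, b = in_nw,
                             labels = c("S", "NW"), exclude_east = FALSE),
    q2_winter_s_vs_nw_excl_isthmus = list(months = periods$winter, a = in_s,
                                          b = in_nw, labels = c("S", "NW"),
                                          exclude_east = TRUE),
    q3_spring_ne_vs_nw = list(months = periods$spring, a = in_ne, b = in_nw,
                              labels = c("NE", "NW"), exclude_east = FALSE),
    q4_lowland_vs_upland = list(months = NULL, a = lowland, b = upland,
                                labels = c("lowland", "upland"),
                                exclude_east = FALSE)
  )
  question_ids <- c(1L, 2L, 2L, 3L, 4L)
  tests <- purrr::imap(specs, function(sp, nm) {
    f <- focal
    r <- reference
    if (sp$exclude_east) {
      f <- west_of_isthmus(f)
      r <- west_of_isthmus(r)
    }
    tab <- build_table(f, r, months = sp$months, stratum_a = sp$a,
                       stratum_b = sp$b, labels = sp$labels)
    chisq_2x2(tab, correct = correct)
  })
  structure(list(tests = tests, question_id = question_ids, n_questions = 4L),
            class = "movement_battery")
}

#' @describeIn run_movement_battery One row per test in the battery.
#' @param x A `movement_battery`.
#' @param ... Unused.
#' @export
tidy.movement_battery <- function(x, ...) {
  purrr::imap(x$tests, function(t, nm) mutate(tidy(t), test = nm, .before = 1)) |>
    bind_rows() |>
    mutate(question_id = x$question_id, .after = "test")
}

#' @describeIn run_movement_battery One-row battery summary.
#' @export
glance.movement_battery <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_questions = x$n_questions,
    n_tests = nrow(td),
    n_valid = sum(td$valid),
    n_direction_consistent = sum(td$direction_consistent, na.rm = TRUE),
    min_p = suppressWarnings(min(td$p_value, na.rm = TRUE))
  )
}

#' @export
print.movement_battery <- function(x, ...) {
  print(tidy(x) |>
          select("test", "question_id", "statistic", "p_value",
                 "direction_consistent", "valid"))
  invisible(x)
}
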