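#' Classify an observed hit count against the chance thresholds
#'
#' Compares an observed hit count with the upper and lower chance thresholds
#' of its design. Hit rates strictly above U are significantly better than
#' chance; rates strictly below L (when a lower threshold exists) are
#' significantly worse than chance, raising the malingering / systematic-error
#' flag; everything else -- including results exactly at a threshold -- is
#' consistent with random guessing. Comparisons are made on integer hit
#' counts, so threshold boundaries are exact.
#'
#' @param hits Observed hit count, a single integer in [0, trials].
#' @param design A \code{\link{test_design}}.
#' @inheritParams chance_thresholds
#' @return An object of class \code{"outcome_classification"}: a list with the
#'   observed count and rate, \code{point_probability} (P(hits) under
#'   guessing), \code{category} (one of \code{"significantly_above"},
#'   \code{"chance_consistent"}, \code{"significantly_below"}),
#'   \code{malingering_flag}, and the \code{\link{chance_thresholds}} used.
#' @examples
#' d <- test_design(3, 30)
#' classify_hit_count(14, d)  # above U = 0.433
#' classify_hit_count(6, d)   # below L = 0.233: malingering flag
#' @export
classify_hit_count <- function(hits, design, sided = c("one_sided", "two_sided"),
                               round_pmf = FALSE) {
  design <- as_test_design(design)
  sided <- match.arg(sided)
  if (length(hits) != 1) stop("`hits` must be a single hit count", call. = FALSE)
  hits <- check_hits(hits, design)

  th <- chance_thresholds(design, sided, round_pmf = round_pmf)
  if (th$degenerate) {
    stop(sprintf(
      "point-probability rule undefined for this design (a=%d, n=%d, %s): no hit count is chance-consistent",
      design$alternatives, design$trials, sided), call. = FALSE)
  }

  category <- if (hits > th$upper_hits) {
    "significantly_above"
  } else if (th$lower_exists && hits < th$lower_hits) {
    "significantly_below"
  } else {
    "chance_consistent"
  }

  structure(
    list(design = design, sided = sided,
         observed_hits = hits, observed_rate = hits / design$trials,
         point_probability = binom_pmf(hits, design),
         category = category,
         malingering_flag = category == "significantly_below",
         thresholds = th),
    class = "outcome_classification"
  )
}

#' @export
print.outcome_classification <- function(x, ...) {
  cat(sprintf("Observed %d/%d hits (rate %.3f, P(k) = %.4f): %s\n",
              x$observed_hits, x$design$trials,
              round_half_up(x$observed_rate), x$point_probability,
              gsub("_", " ", x$category)))
  if (x$malingering_flag) {
    cat("  Significantly below chance: malingering or systematic error suspected.\n")
  }
  if (!x$thresholds$lower_exists) {
    cat("  (No lower threshold for this design; below-chance detection unavailable.)\n")
  }
  invisible(x)
}

#' Conventional 1/a above-chance rule
#'
#' The traditional criterion that treats any hit rate strictly above the
#' single-trial guessing probability \code{1/alternatives} as better than
#' chance, regardless of the number of trials. Provided for comparison with
#' the binomial rule, which it systematically over-calls: every hit count the
#' binomial rule flags as above chance also exceeds 1/a, but not conversely.
#' A rate exactly equal to 1/a is not counted as above chance.
#'
#' @param hits Observed hit count(s).
#' @param design A \code{\link{test_design}}.
#' @return Logical, \code{TRUE} where \code{hits/trials > 1/alternatives}
#'   (evaluated in exact integer arithmetic).
#' @export
conventional_above_chance <- function(hits, design) {
  design <- as_test_design(design)
  hits <- check_hits(hits, design)
  # k/n > 1/a  <=>  k * a > n, exact in integers
  as.numeric(hits) * design$alternatives > design$trials
}

#' Summarize a cohort of hit counts under both chance rules
#'
#' Counts how many subjects in a cohort score significantly above, within, and
#' below the binomial chance interval [L, U], side by side with the number
#' scoring above the conventional 1/a criterion. The comparison shows how many
#' apparent above-chance results under the conventional rule are still
#' chance-consistent once the scatter of guessing across trials is modelled.
#'
#' @param hits Integer vector of per-subject hit counts, all in [0, trials].
#' @param design A \code{\link{test_design}} shared by all subjects.
#' @inheritParams chance_thresholds
#' @return An object of class \code{"cohort_summary"}: counts
#'   \code{n_above_binomial}, \code{n_within_binomial}, \code{n_below_binomial},
#'   \code{n_above_conventional}, \code{total}, plus the thresholds and the
#'   per-subject categories.
#' @examples
#' d <- test_design(3, 30)
#' cohort_summary(c(14, 15, 10, 6, 20), d)
#' @export
cohort_summary <- function(hits, design, sided = c("one_sided", "two_sided"),
                           round_pmf = FALSE) {
  design <- as_test_design(design)
  sided <- match.arg(sided)
  if (length(hits) == 0) stop("empty cohort: no hit counts supplied", call. = FALSE)
  hits <- check_hits(hits, design)

  th <- chance_thresholds(design, sided, round_pmf = round_pmf)
  if (th$degenerate) {
    stop("point-probability rule undefined for this design (degenerate)",
         call. = FALSE)
  }

  above <- hits > th$upper_hits
  below <- th$lower_exists & hits < th$lower_hits
  category <- ifelse(above, "significantly_above",
                     ifelse(below, "significantly_below", "chance_consistent"))

  structure(
    list(design = design, sided = sided, thresholds = th,
         hits = hits, category = category,
         n_above_binomial = sum(above),
         n_below_binomial = sum(below),
         n_within_binomial = sum(!above & !below),
         n_above_conventional = sum(conventional_above_chance(hits, design)),
         total = length(hits)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d subjects (a=%d, n=%d, %s)\n",
              x$total, x$design$alternatives, x$design$trials,
              gsub("_", "-", x$sided)))
  cat(sprintf("  binomial rule:     %d above U, %d within [L, U], %d below L\n",
              x$n_above_binomial, x$n_within_binomial, x$n_below_binomial))
  cat(sprintf("  conventional 1/a:  %d above %0.3f\n",
              x$n_above_conventional,
              round_half_up(1 / x$design$alternatives)))
  invisible(x)
}
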