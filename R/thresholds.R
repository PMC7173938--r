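#' Upper and lower chance thresholds for hit rates
#'
#' Computes the interval of hit rates consistent with pure random guessing in
#' a closed-set, forced-choice test, using the binomial point probability
#' rule: a hit count k is chance-consistent when its point probability
#' P(k) under guessing exceeds the criterion (0.05 for one-sided testing,
#' 0.025 per threshold for two-sided testing). The upper threshold U is the
#' largest chance-consistent hit rate and the lower threshold L the smallest.
#' Observed hit rates strictly above U are significantly better than chance;
#' rates strictly below L (when L > 0) are significantly worse than chance,
#' which flags malingering, misunderstood instructions, or technical error.
#'
#' A lower threshold above zero only exists for sufficiently few alternatives
#' and sufficiently many trials; \code{lower_exists} reports whether
#' below-chance detection is available for the design. Conversely, for very
#' large trial counts the mode of the binomial pmf itself drops to or below
#' the criterion and \emph{no} hit count is chance-consistent; the rule is
#' then inapplicable and the result is returned with \code{degenerate = TRUE}
#' and \code{NA} thresholds rather than an empty interval.
#'
#' @param design A \code{\link{test_design}}.
#' @param sided \code{"one_sided"} (criterion 0.05) or \code{"two_sided"}
#'   (criterion 0.025 on each threshold).
#' @param round_pmf If \code{TRUE}, round each point probability to 3 decimals
#'   before comparing with the criterion. Published threshold tables are
#'   sometimes produced this way, which moves a handful of boundary cells
#'   where P(k) lies within 0.0005 of the criterion (for example
#'   P(12; 25, 1/3) = 0.0503 is treated as 0.050 and hence significant).
#'   The default \code{FALSE} applies the criterion to the full-precision
#'   probability.
#'
#' @return An object of class \code{"chance_thresholds"}: a list with
#'   \code{design}, \code{sided}, \code{criterion}, \code{lower}/\code{upper}
#'   (hit-rate thresholds L and U), \code{lower_hits}/\code{upper_hits} (the
#'   same thresholds as integer hit counts, used for exact comparisons),
#'   \code{lower_exists} (TRUE iff L > 0) and \code{degenerate}.
#'
#' @examples
#' chance_thresholds(test_design(4, 20), "one_sided")   # L = 0.10, U = 0.40
#' chance_thresholds(test_design(3, 30), "one_sided")   # L = 0.233, U = 0.433
#' chance_thresholds(test_design(2, 1000), "one_sided") # degenerate
#' @export
chance_thresholds <- function(design, sided = c("one_sided", "two_sided"),
                              round_pmf = FALSE) {
  design <- as_test_design(design)
  sided <- match.arg(sided)
  criterion <- if (sided == "one_sided") 0.05 else 0.025

  n <- design$trials
  pmf <- binom_pmf(0:n, design)
  if (isTRUE(round_pmf)) pmf <- round_half_up(pmf, 3)
  keep <- (pmf - criterion) > PMF_TOL

  if (!any(keep)) {
    out <- structure(
      list(design = design, sided = sided, criterion = criterion,
           lower = NA_real_, upper = NA_real_,
           lower_hits = NA_integer_, upper_hits = NA_integer_,
           lower_exists = FALSE, degenerate = TRUE, round_pmf = round_pmf),
      class = "chance_thresholds"
    )
    verbose_message(sprintf(
      "chance_thresholds: a=%d n=%d %s -> degenerate (max P(k) <= %.3f)",
      design$alternatives, n, sided, criterion))
    return(out)
  }

  kk <- which(keep) - 1L
  # The binomial pmf is unimodal, so the chance-consistent hit counts must
  # form one contiguous run; anything else indicates a numerical fault.
  if (any(diff(kk) != 1L)) {
    stop("internal error: chance-consistent hit counts are not contiguous")
  }
  lower_hits <- min(kk)
  upper_hits <- max(kk)

  out <- structure(
    list(design = design, sided = sided, criterion = criterion,
         lower = lower_hits / n, upper = upper_hits / n,
         lower_hits = lower_hits, upper_hits = upper_hits,
         lower_exists = lower_hits > 0L, degenerate = FALSE,
         round_pmf = round_pmf),
    class = "chance_thresholds"
  )
  verbose_message(sprintf(
    "chance_thresholds: a=%d n=%d %s -> L=%.3f U=%.3f (lower_exists=%s)",
    design$alternatives, n, sided, out$lower, out$upper, out$lower_exists))
  out
}

#' @export
print.chance_thresholds <- function(x, ...) {
  cat(sprintf("Chance thresholds (%s, criterion P(k) > %.3f)\n",
              gsub("_", "-", x$sided), x$criterion))
  cat(sprintf("  design: %d alternatives, %d trials\n",
              x$design$alternatives, x$design$trials))
  if (x$degenerate) {
    cat("  degenerate: no hit count has P(k) above the criterion;\n")
    cat("  the point-probability rule is inapplicable at this trial count.\n")
  } else {
    cat(sprintf("  L = %.3f (%d hits)   U = %.3f (%d hits)\n",
                round_half_up(x$lower), x$lower_hits,
                round_half_up(x$upper), x$upper_hits))
    if (!x$lower_exists) {
      cat("  L = 0: below-chance (malingering) detection unavailable.\n")
    }
  }
  invisible(x)
}

#' Threshold table over a grid of alternatives and trial counts
#'
#' Builds the printable table of lower/upper chance thresholds (L, U) for
#' every combination of alternatives and trial counts, one row per trial
#' count and one L/U column pair per alternative count, rounded to 3 decimals.
#' Degenerate cells (no chance-consistent hit count) are \code{NA}.
#'
#' @param alternatives Integer vector of alternative counts (each >= 2).
#' @param trials Integer vector of trial counts (each >= 1).
#' @inheritParams chance_thresholds
#' @return A data frame of class \code{"threshold_table"} with column \code{n}
#'   followed by columns \code{L_a<a>}, \code{U_a<a>}. The \code{sided} and
#'   \code{round_pmf} settings are attached as attributes.
#' @examples
#' threshold_table(alternatives = 2:5, trials = c(10, 20, 50), sided = "one_sided")
#' @export
threshold_table <- function(alternatives = 2:10,
                            trials = c(2, 4, 6, 8, 10, 15, 20, 25, 30, 40, 50, 100),
                            sided = c("one_sided", "two_sided"),
                            round_pmf = FALSE) {
  sided <- match.arg(sided)
  alternatives <- vapply(alternatives, check_count, integer(1),
                         name = "alternatives", min = 2)
  trials <- vapply(trials, check_count, integer(1), name = "trials", min = 1)

  tab <- data.frame(n = trials)
  for (a in alternatives) {
    L <- U <- rep(NA_real_, length(trials))
    for (i in seq_along(trials)) {
      th <- chance_thresholds(test_design(a, trials[i]), sided,
                              round_pmf = round_pmf)
      if (!th$degenerate) {
        L[i] <- round_half_up(th$lower)
        U[i] <- round_half_up(th$upper)
      }
    }
    tab[[paste0("L_a", a)]] <- L
    tab[[paste0("U_a", a)]] <- U
  }
  attr(tab, "sided") <- sided
  attr(tab, "round_pmf") <- round_pmf
  class(tab) <- c("threshold_table", "data.frame")
  tab
}
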