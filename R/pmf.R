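#' Point probability of a hit count under random guessing
#'
#' The binomial probability mass function evaluated at \code{hits} for a
#' session of \code{trials} independent guesses, each correct with probability
#' \code{1/alternatives}:
#' \deqn{P(k) = \binom{n}{k} p^k (1-p)^{n-k}, \quad p = 1/a.}
#' This point probability -- not a cumulative tail -- is what the threshold
#' rule in \code{\link{chance_thresholds}} compares against the significance
#' criterion.
#'
#' @param hits Hit count(s) between 0 and \code{design$trials}.
#' @param design A \code{\link{test_design}}.
#' @return Probabilities in [0, 1], one per element of \code{hits}.
#' @examples
#' d <- test_design(4, 20)
#' binom_pmf(0:20, d)
#' @export
binom_pmf <- function(hits, design) {
  design <- as_test_design(design)
  hits <- check_hits(hits, design)
  stats::dbinom(hits, design$trials, 1 / design$alternatives)
}

#' Probability grid of all possible hit counts
#'
#' Tabulates, for every possible hit count k = 0..n, the hit rate k/n, the
#' point probability P(k) of reaching exactly k hits by guessing alone, and
#' whether that probability falls at or below the one-sided (0.05) and
#' two-sided (0.025 per threshold) significance criteria.
#'
#' @param design A \code{\link{test_design}}.
#' @return A data frame with columns \code{hits}, \code{hit_rate},
#'   \code{probability}, \code{significant_one_sided},
#'   \code{significant_two_sided}. Probabilities sum to 1.
#' @examples
#' probability_grid(test_design(4, 20))
#' @export
probability_grid <- function(design) {
  design <- as_test_design(design)
  k <- 0:design$trials
  pmf <- binom_pmf(k, design)
  data.frame(
    hits = k,
    hit_rate = k / design$trials,
    probability = pmf,
    significant_one_sided = !((pmf - 0.05) > PMF_TOL),
    significant_two_sided = !((pmf - 0.025) > PMF_TOL)
  )
}
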