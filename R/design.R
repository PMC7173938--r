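#' Define a closed-set, forced-choice test design
#'
#' A design is the pair of test parameters every other computation in the
#' package depends on: the number of response alternatives offered on each
#' trial and the number of trials in the session. Under pure random guessing
#' the per-trial probability of a hit is \code{1/alternatives}, so the number
#' of hits in a session is binomially distributed.
#'
#' @param alternatives Number of response alternatives per trial (integer,
#'   at least 2).
#' @param trials Number of trials in the session (integer, at least 1).
#'
#' @return An object of class \code{"test_design"}: a list with elements
#'   \code{alternatives} and \code{trials}.
#'
#' @examples
#' d <- test_design(alternatives = 4, trials = 20)
#' chance_prob(d)
#' expected_hits(d)
#' @export
test_design <- function(alternatives, trials) {
  alternatives <- check_count(alternatives, "alternatives", min = 2)
  trials <- check_count(trials, "trials", min = 1)
  structure(
    list(alternatives = alternatives, trials = trials),
    class = "test_design"
  )
}

#' @export
print.test_design <- function(x, ...) {
  cat(sprintf(
    "Closed-set forced-choice design: %d alternatives, %d trials (p = 1/%d = %.4g)\n",
    x$alternatives, x$trials, x$alternatives, 1 / x$alternatives
  ))
  invisible(x)
}

as_test_design <- function(design) {
  if (!inherits(design, "test_design")) {
    stop("`design` must be created with test_design()", call. = FALSE)
  }
  design
}

#' Per-trial probability of a hit by chance
#'
#' The probability of guessing the correct response on a single trial,
#' \code{1/alternatives}. This single-trial value is also the mean hit rate
#' of the binomial guessing distribution, and is what the conventional
#' "1/a" chance criterion uses as a constant threshold.
#'
#' @param design A \code{\link{test_design}}.
#' @return A number in (0, 0.5].
#' @export
chance_prob <- function(design) {
  design <- as_test_design(design)
  1 / design$alternatives
}

#' Hit rate of an observed hit count
#'
#' @param hits Observed number of hits, between 0 and \code{design$trials}.
#'   May be a vector.
#' @param design A \code{\link{test_design}}.
#' @return \code{hits / trials}.
#' @export
hit_rate <- function(hits, design) {
  design <- as_test_design(design)
  hits <- check_hits(hits, design)
  hits / design$trials
}

#' Expected hits and hit rate under random guessing
#'
#' The mean of the binomial guessing distribution: \code{trials/alternatives}
#' hits, i.e. a mean hit rate of \code{1/alternatives}. Observed sessions
#' scatter around this mean; the scatter is what \code{\link{chance_thresholds}}
#' quantifies.
#'
#' @param design A \code{\link{test_design}}.
#' @return A list with elements \code{hits} (mean hit count, \code{n * p}) and
#'   \code{rate} (mean hit rate, \code{p}).
#' @export
expected_hits <- function(design) {
  design <- as_test_design(design)
  p <- 1 / design$alternatives
  list(hits = design$trials * p, rate = p)
}
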