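#' Synthetic responder model for forced-choice sessions
#'
#' A minimal generative model of a test subject, used to study the operating
#' characteristics of the chance-threshold decision rule without clinical
#' data. On each trial the subject knows the correct answer with probability
#' \code{knowledge_prob} (q). A \code{"listener"} answers correctly whenever
#' the answer is known and guesses otherwise; a \code{"malingerer"}
#' deliberately answers among the wrong alternatives with probability
#' \code{avoidance_prob} (v) when the answer is known; a \code{"guesser"}
#' never knows the answer (q = 0). Trials are independent and identically
#' distributed (no learning or fatigue), so the per-trial hit probability has
#' the closed form
#' \deqn{P(hit) = q (1 - v) + (1 - q) / a,}
#' and session hit counts are binomial -- every simulation result has an
#' analytic oracle.
#'
#' @param mode One of \code{"guesser"}, \code{"listener"}, \code{"malingerer"}.
#' @param knowledge_prob Probability q in [0, 1] that the correct answer is
#'   known on a trial. Forced to 0 for a guesser.
#' @param avoidance_prob Probability v in [0, 1] that a malingerer deliberately
#'   answers wrongly when the answer is known. Forced to 0 for guessers and
#'   listeners.
#' @return An object of class \code{"responder_model"}.
#' @examples
#' responder_model("guesser")
#' responder_model("listener", knowledge_prob = 0.9)
#' responder_model("malingerer", knowledge_prob = 1, avoidance_prob = 1)
#' @export
responder_model <- function(mode = c("guesser", "listener", "malingerer"),
                            knowledge_prob = 0, avoidance_prob = 0) {
  mode <- match.arg(mode)
  check_prob <- function(x, name) {
    if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x < 0 || x > 1) {
      stop(sprintf("`%s` must be a single probability in [0, 1]", name),
           call. = FALSE)
    }
    as.numeric(x)
  }
  knowledge_prob <- check_prob(knowledge_prob, "knowledge_prob")
  avoidance_prob <- check_prob(avoidance_prob, "avoidance_prob")
  if (mode == "guesser" && knowledge_prob != 0) {
    stop("a guesser has knowledge_prob = 0", call. = FALSE)
  }
  if (mode != "malingerer" && avoidance_prob != 0) {
    stop("avoidance_prob applies only to malingerers", call. = FALSE)
  }
  structure(
    list(mode = mode, knowledge_prob = knowledge_prob,
         avoidance_prob = avoidance_prob),
    class = "responder_model"
  )
}

#' @export
print.responder_model <- function(x, ...) {
  cat(sprintf("Responder model: %s (q = %g, v = %g)\n",
              x$mode, x$knowledge_prob, x$avoidance_prob))
  invisible(x)
}

#' Per-trial hit probability of a responder model
#'
#' @param model A \code{\link{responder_model}}.
#' @param design A \code{\link{test_design}}.
#' @return \code{q * (1 - v) + (1 - q) / a}.
#' @export
hit_probability <- function(model, design) {
  if (!inherits(model, "responder_model")) {
    stop("`model` must be created with responder_model()", call. = FALSE)
  }
  design <- as_test_design(design)
  q <- model$knowledge_prob
  v <- model$avoidance_prob
  q * (1 - v) + (1 - q) / design$alternatives
}

#' Simulate session hit counts under a responder model
#'
#' Draws the number of hits in \code{trials} independent trials for each of
#' \code{sessions} simulated sessions, using the model's closed-form per-trial
#' hit probability. Uses the global RNG (\code{set.seed} for reproducibility).
#'
#' @param design A \code{\link{test_design}}.
#' @param model A \code{\link{responder_model}}.
#' @param sessions Number of sessions to simulate.
#' @return Integer vector of hit counts, one per session.
#' @export
simulate_hit_counts <- function(design, model, sessions = 1) {
  design <- as_test_design(design)
  sessions <- check_count(sessions, "sessions", min = 1)
  stats::rbinom(sessions, design$trials, hit_probability(model, design))
}

#' Operating characteristics of the chance-threshold rule
#'
#' Simulates many sessions under a responder model and reports the fraction
#' classified significantly above, within, and below the chance interval of
#' the design. For a pure guesser these fractions converge to the exact
#' binomial pmf sums over the corresponding hit-count sets; for a malingerer
#' the below-L fraction is the detection rate of the malingering flag.
#'
#' @param design A \code{\link{test_design}} (must not be degenerate).
#' @param model A \code{\link{responder_model}}.
#' @param sessions Number of simulated sessions.
#' @inheritParams chance_thresholds
#' @param seed Optional integer seed.
#' @return An object of class \code{"operating_characteristics"}: fractions
#'   \code{above}, \code{within}, \code{below}, the matching counts, the
#'   thresholds and the model.
#' @examples
#' oc <- operating_characteristics(test_design(4, 20),
#'                                 responder_model("guesser"),
#'                                 sessions = 10000, seed = 1)
#' oc$above + oc$below   # rate of false significance under pure guessing
#' @export
operating_characteristics <- function(design, model, sessions = 10000,
                                      sided = c("one_sided", "two_sided"),
                                      round_pmf = FALSE, seed = NULL) {
  design <- as_test_design(design)
  sided <- match.arg(sided)
  sessions <- check_count(sessions, "sessions", min = 1)
  th <- chance_thresholds(design, sided, round_pmf = round_pmf)
  if (th$degenerate) {
    stop("operating characteristics undefined: design is degenerate",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  k <- simulate_hit_counts(design, model, sessions)
  n_above <- sum(k > th$upper_hits)
  n_below <- sum(th$lower_exists & k < th$lower_hits)
  structure(
    list(design = design, model = model, sided = sided, thresholds = th,
         sessions = sessions,
         n_above = n_above, n_below = n_below,
         n_within = sessions - n_above - n_below,
         above = n_above / sessions,
         below = n_below / sessions,
         within = (sessions - n_above - n_below) / sessions),
    class = "operating_characteristics"
  )
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d sessions (%s, a=%d, n=%d)\n",
              x$sessions, x$model$mode, x$design$alternatives,
              x$design$trials))
  cat(sprintf("  above U: %.4f   within [L, U]: %.4f   below L: %.4f\n",
              x$above, x$within, x$below))
  invisible(x)
}
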