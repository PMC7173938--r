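#' Loudspeaker array for a localization task
#'
#' Describes a line array of loudspeakers by azimuth. Either give explicit
#' \code{azimuths} (strictly increasing, degrees) or a \code{count} and total
#' \code{span}, in which case speakers are placed equally spaced from 0 to
#' \code{span} degrees. Angular errors are absolute azimuth differences on the
#' line; no circular wrap-around is applied, which is unambiguous for the
#' spans of at most 180 degrees typical of clinical arrays.
#'
#' @param count Number of speakers (>= 2); ignored when \code{azimuths} is given.
#' @param span Angle in degrees between the outermost speakers (> 0); ignored
#'   when \code{azimuths} is given.
#' @param azimuths Optional explicit speaker azimuths in degrees.
#' @return An object of class \code{"speaker_array"}: list with
#'   \code{azimuths}, \code{count}, \code{span} and \code{separation} (the
#'   common spacing, or \code{NA} for irregular explicit arrays).
#' @examples
#' speaker_array(3, 180)                 # 0, 90, 180
#' speaker_array(azimuths = c(0, 30, 90))
#' @export
speaker_array <- function(count = NULL, span = NULL, azimuths = NULL) {
  if (is.null(azimuths)) {
    count <- check_count(count, "count", min = 2)
    if (length(span) != 1 || !is.numeric(span) || !is.finite(span) || span <= 0) {
      stop("`span` must be a single positive angle in degrees", call. = FALSE)
    }
    azimuths <- seq(0, span, length.out = count)
  } else {
    if (length(azimuths) < 2 || !is.numeric(azimuths) || anyNA(azimuths)) {
      stop("`azimuths` must be at least two finite angles", call. = FALSE)
    }
    if (any(diff(azimuths) <= 0)) {
      stop("`azimuths` must be strictly increasing", call. = FALSE)
    }
  }
  azimuths <- as.numeric(azimuths)
  seps <- diff(azimuths)
  structure(
    list(azimuths = azimuths,
         count = length(azimuths),
         span = max(azimuths) - min(azimuths),
         separation = if (all(abs(seps - seps[1]) < 1e-9)) seps[1] else NA_real_),
    class = "speaker_array"
  )
}

#' @export
print.speaker_array <- function(x, ...) {
  cat(sprintf("Speaker array: %d speakers, span %g deg%s\n", x$count, x$span,
              if (is.na(x$separation)) "" else
                sprintf(", separation %g deg", x$separation)))
  cat("  azimuths:", paste(x$azimuths, collapse = ", "), "\n")
  invisible(x)
}

#' Localization test design
#'
#' Combines a speaker array with the number of repetitions per target. Each
#' speaker serves as target \code{repetitions} times, so a session has
#' \code{count * repetitions} trials.
#'
#' @param array A \code{\link{speaker_array}}.
#' @param repetitions Repetitions per target speaker (>= 1).
#' @return An object of class \code{"localization_design"}.
#' @export
localization_design <- function(array, repetitions) {
  if (!inherits(array, "speaker_array")) {
    stop("`array` must be created with speaker_array()", call. = FALSE)
  }
  repetitions <- check_count(repetitions, "repetitions", min = 1)
  structure(
    list(array = array, repetitions = repetitions,
         trials = array$count * repetitions),
    class = "localization_design"
  )
}

#' @export
print.localization_design <- function(x, ...) {
  cat(sprintf(
    "Localization design: %d speakers x %d repetitions = %d trials\n",
    x$array$count, x$repetitions, x$trials))
  invisible(x)
}

#' RMS angular error of one session
#'
#' Root-mean-square azimuth difference between target and response speakers
#' over the trials of a session. Correct responses contribute an error of
#' zero; the mean square is taken over \emph{all} trials.
#'
#' @param targets,responses Integer speaker indices (1-based into
#'   \code{array$azimuths}), one per trial.
#' @param array A \code{\link{speaker_array}}.
#' @return RMS error in degrees.
#' @examples
#' arr <- speaker_array(3, 180)
#' session_rms(c(1, 2, 3), c(3, 1, 2), arr)  # sqrt((180^2+90^2+90^2)/3)
#' @export
session_rms <- function(targets, responses, array) {
  if (!inherits(array, "speaker_array")) {
    stop("`array` must be created with speaker_array()", call. = FALSE)
  }
  if (length(targets) != length(responses) || length(targets) == 0) {
    stop("`targets` and `responses` must be non-empty and the same length",
         call. = FALSE)
  }
  idx_ok <- function(i) all(i >= 1 & i <= array$count & i == as.integer(i))
  if (!idx_ok(targets) || !idx_ok(responses)) {
    stop("speaker indices must be integers in 1..count", call. = FALSE)
  }
  err <- array$azimuths[responses] - array$azimuths[targets]
  sqrt(mean(err^2))
}

# Simulate session RMS errors for `nsub` guessing subjects (one value each).
# Per trial: with probability 1/a the response is the target (zero error),
# otherwise a uniformly chosen different speaker. Uses the global RNG.
sim_rms_sessions <- function(array, repetitions, nsub) {
  a <- array$count
  az <- array$azimuths
  n <- a * repetitions
  tg <- matrix(rep(rep(seq_len(a), times = repetitions), each = nsub),
               nrow = nsub)
  hit <- matrix(stats::runif(nsub * n) < 1 / a, nrow = nsub)
  wrong <- matrix(sample.int(a - 1L, nsub * n, replace = TRUE), nrow = nsub)
  resp <- wrong + (wrong >= tg)            # skip the target slot
  err2 <- (az[resp] - az[tg])^2
  dim(err2) <- dim(tg)
  err2[hit] <- 0
  sqrt(rowMeans(err2))
}

#' Simulate the RMS angular error of a single guessing session
#'
#' Draws one session under the guessing model: every speaker is set as target
#' \code{repetitions} times; on each trial the simulated subject hits the
#' target with probability \code{1/count} (error 0) and otherwise picks one of
#' the remaining speakers uniformly, contributing the absolute azimuth
#' difference as error. Uses the global RNG (\code{set.seed} for
#' reproducibility).
#'
#' @param design A \code{\link{localization_design}}.
#' @return RMS error of the simulated session, in degrees.
#' @export
simulate_session_rms <- function(design) {
  if (!inherits(design, "localization_design")) {
    stop("`design` must be created with localization_design()", call. = FALSE)
  }
  sim_rms_sessions(design$array, design$repetitions, 1L)
}

#' Infinite-trial RMS error under guessing (closed form)
#'
#' The RMS angular error a guessing subject converges to as the number of
#' trials grows. Per trial with target t, each of the other speakers is chosen
#' with probability 1/a and the target (zero error) with probability 1/a, so
#' \deqn{RMS_\infty = \sqrt{\frac{1}{a^2} \sum_t \sum_{r \ne t} (\theta_r - \theta_t)^2}.}
#' Finite sessions have a mean RMS slightly \emph{below} this asymptote
#' (Jensen's inequality for the square root of a sample mean), converging to
#' it as repetitions grow. Serves as the analytic oracle for
#' \code{\link{mc_rms_distribution}}.
#'
#' @param array A \code{\link{speaker_array}}.
#' @return Asymptotic RMS error in degrees.
#' @examples
#' analytic_rms_asymptote(speaker_array(3, 180))  # sqrt(10800) = 103.92
#' @export
analytic_rms_asymptote <- function(array) {
  if (!inherits(array, "speaker_array")) {
    stop("`array` must be created with speaker_array()", call. = FALSE)
  }
  az <- array$azimuths
  sqrt(sum(outer(az, az, "-")^2) / array$count^2)
}

#' Monte Carlo distribution of chance-level RMS angular errors
#'
#' Simulates many independent guessing subjects on a localization design and
#' summarizes the resulting distribution of session RMS errors by its mean and
#' sample standard deviation (denominator \code{subjects - 1}). These two
#' parameters feed \code{\link{rms_thresholds}}.
#'
#' @param design A \code{\link{localization_design}}.
#' @param subjects Number of simulated subjects (default 100000).
#' @param seed Optional integer seed for reproducibility.
#' @param chunk_size Subjects simulated per block, to bound memory on designs
#'   with many trials.
#' @return An object of class \code{"rms_chance_distribution"}: list with
#'   \code{mean_rms}, \code{sd_rms} (degrees; \code{NA} with a warning when
#'   \code{subjects < 2}), \code{subjects}, \code{seed} and the design.
#' @examples
#' d <- localization_design(speaker_array(3, 180), repetitions = 10)
#' mc_rms_distribution(d, subjects = 2000, seed = 1)
#' @export
mc_rms_distribution <- function(design, subjects = 100000, seed = NULL,
                                chunk_size = 20000L) {
  if (!inherits(design, "localization_design")) {
    stop("`design` must be created with localization_design()", call. = FALSE)
  }
  subjects <- check_count(subjects, "subjects", min = 1)
  if (!is.null(seed)) set.seed(seed)

  rms <- numeric(subjects)
  done <- 0L
  while (done < subjects) {
    m <- min(chunk_size, subjects - done)
    rms[(done + 1L):(done + m)] <-
      sim_rms_sessions(design$array, design$repetitions, m)
    done <- done + m
  }

  sd_rms <- if (subjects >= 2) stats::sd(rms) else {
    warning("standard deviation undefined for a single simulated subject")
    NA_real_
  }
  out <- structure(
    list(design = design, subjects = subjects,
         mean_rms = mean(rms), sd_rms = sd_rms,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "rms_chance_distribution"
  )
  verbose_message(sprintf(
    "mc_rms_distribution: %d speakers, r=%d, %d subjects -> mean %.2f sd %.2f",
    design$array$count, design$repetitions, subjects, out$mean_rms,
    out$sd_rms))
  out
}

#' @export
print.rms_chance_distribution <- function(x, ...) {
  cat(sprintf(
    "Chance RMS error distribution (%d speakers, %d trials, %d subjects)\n",
    x$design$array$count, x$design$trials, x$subjects))
  cat(sprintf("  mean %.1f deg, sd %.1f deg\n", x$mean_rms, x$sd_rms))
  invisible(x)
}

#' Chance thresholds for observed RMS angular errors
#'
#' Converts the Monte Carlo mean and standard deviation of chance-level RMS
#' errors into lower and upper significance thresholds using normal 5%
#' quantiles: \code{mean -/+ z * sd} with z = 1.645 for one-sided and
#' z = 1.960 for two-sided testing. Observed RMS errors below the lower
#' threshold indicate localization significantly better than guessing; errors
#' above the upper threshold are significantly worse than guessing.
#'
#' @param dist An \code{\link{mc_rms_distribution}} result.
#' @param sided \code{"one_sided"} or \code{"two_sided"}.
#' @return An object of class \code{"rms_thresholds"} with \code{lower} and
#'   \code{upper} in degrees.
#' @export
rms_thresholds <- function(dist, sided = c("one_sided", "two_sided")) {
  if (!inherits(dist, "rms_chance_distribution")) {
    stop("`dist` must be created with mc_rms_distribution()", call. = FALSE)
  }
  sided <- match.arg(sided)
  if (!is.finite(dist$sd_rms) || dist$sd_rms <= 0) {
    stop("RMS thresholds require a positive standard deviation", call. = FALSE)
  }
  z <- if (sided == "one_sided") stats::qnorm(0.95) else stats::qnorm(0.975)
  structure(
    list(distribution = dist, sided = sided, z = z,
         lower = dist$mean_rms - z * dist$sd_rms,
         upper = dist$mean_rms + z * dist$sd_rms),
    class = "rms_thresholds"
  )
}

#' @export
print.rms_thresholds <- function(x, ...) {
  cat(sprintf("Chance RMS thresholds (%s, z = %.3f): L = %.1f deg, U = %.1f deg\n",
              gsub("_", "-", x$sided), x$z, x$lower, x$upper))
  invisible(x)
}

#' Classify an observed RMS angular error
#'
#' Small RMS errors mean good localization, so an observation strictly below
#' the lower chance threshold is significantly \emph{better} than guessing and
#' one strictly above the upper threshold significantly \emph{worse}
#' (suggesting malingering or a systematic fault); anything in between is
#' consistent with guessing.
#'
#' @param observed Observed RMS error(s) in degrees (>= 0).
#' @param thresholds An \code{\link{rms_thresholds}} object.
#' @return Character vector with values \code{"significantly_better"},
#'   \code{"chance_consistent"} or \code{"significantly_worse"}.
#' @export
classify_rms <- function(observed, thresholds) {
  if (!inherits(thresholds, "rms_thresholds")) {
    stop("`thresholds` must be created with rms_thresholds()", call. = FALSE)
  }
  if (!is.numeric(observed) || anyNA(observed) || any(observed < 0)) {
    stop("`observed` must be non-negative RMS errors in degrees", call. = FALSE)
  }
  ifelse(observed < thresholds$lower, "significantly_better",
         ifelse(observed > thresholds$upper, "significantly_worse",
                "chance_consistent"))
}
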