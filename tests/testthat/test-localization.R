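test_that("speaker_array builds equally spaced arrays from count and span", {
  arr <- speaker_array(3, 180)
  expect_equal(arr$azimuths, c(0, 90, 180))
  expect_equal(arr$separation, 90)
  expect_equal(speaker_array(15, 140)$separation, 10)
  expect_equal(speaker_array(2, 90)$azimuths, c(0, 90))

  expl <- speaker_array(azimuths = c(-45, 0, 60))
  expect_equal(expl$count, 3)
  expect_equal(expl$span, 105)
  expect_true(is.na(expl$separation))

  expect_error(speaker_array(1, 90), "at least 2")
  expect_error(speaker_array(3, -10), "positive")
  expect_error(speaker_array(azimuths = c(0, 90, 90)), "strictly increasing")
})

test_that("localization_design counts trials as speakers times repetitions", {
  des <- localization_design(speaker_array(3, 180), 10)
  expect_equal(des$trials, 30)
  expect_error(localization_design(speaker_array(3, 180), 0), "at least 1")
})

test_that("session_rms computes the plain root mean square of azimuth errors", {
  arr <- speaker_array(3, 180)
  # target 0 -> 180, target 90 -> 0, target 180 -> 90
  expect_equal(session_rms(c(1, 2, 3), c(3, 1, 2), arr),
               sqrt((180^2 + 90^2 + 90^2) / 3))
  # all hits: zero error
  expect_equal(session_rms(c(1, 2, 3, 1, 2, 3), c(1, 2, 3, 1, 2, 3), arr), 0)
  expect_error(session_rms(c(1, 2), c(1, 4), arr), "1..count")
})

test_that("analytic asymptote matches brute-force double sums", {
  brute <- function(az) {
    a <- length(az)
    tot <- 0
    for (t in seq_len(a)) for (r in seq_len(a)) {
      if (r != t) tot <- tot + (az[r] - az[t])^2
    }
    sqrt(tot / a^2)  # each wrong speaker has probability 1/a, hits add zero
  }
  expect_equal(analytic_rms_asymptote(speaker_array(3, 180)), sqrt(10800))
  expect_equal(analytic_rms_asymptote(speaker_array(3, 180)),
               brute(c(0, 90, 180)))
  expect_equal(analytic_rms_asymptote(speaker_array(2, 180)),
               sqrt(2 * 180^2 / 4))
  for (arr in list(speaker_array(5, 180), speaker_array(15, 140),
                   speaker_array(azimuths = c(0, 30, 45, 170)))) {
    expect_equal(analytic_rms_asymptote(arr), brute(arr$azimuths))
  }
})

test_that("per-trial guessing behaviour has the right hit and confusion rates", {
  arr <- speaker_array(5, 180)
  set.seed(42)
  nsub <- 40000
  # the session mean square is an unbiased estimate of the squared asymptote,
  # so E[rms^2] pins down the per-trial error distribution's second moment
  rms <- chancelevel:::sim_rms_sessions(arr, 1L, nsub)
  expect_lt(abs(mean(rms^2) - analytic_rms_asymptote(arr)^2),
            3 * stats::sd(rms^2) / sqrt(nsub))

  # direct per-trial check on the smallest array: errors on a 2-speaker array
  # are 0 (hit, prob 1/2) or 180 (miss, prob 1/2)
  arr2 <- speaker_array(2, 180)
  rms2 <- chancelevel:::sim_rms_sessions(arr2, 1L, nsub)
  miss_per_trial <- rms2^2 / 180^2  # per-session fraction of misses (2 trials)
  expect_lt(abs(mean(miss_per_trial) - 0.5), 3 * 0.5 / sqrt(2 * nsub))

  # conditional on a miss, each wrong speaker appears with frequency 1/(a-1):
  # on a 3-speaker array wrong answers from target 0 are 90 or 180, equally
  arr3 <- speaker_array(3, 180)
  set.seed(43)
  one <- replicate(6000, {
    d1 <- localization_design(arr3, 1)
    simulate_session_rms(d1)
  })
  # session errors at r=1 mix targets; test the aggregate second moment
  expect_lt(abs(mean(one^2) - 10800), 3 * stats::sd(one^2) / sqrt(6000))
})

test_that("mc_rms_distribution is seed-reproducible and respects chunking", {
  des <- localization_design(speaker_array(3, 180), 5)
  d1 <- mc_rms_distribution(des, subjects = 3000, seed = 11)
  d2 <- mc_rms_distribution(des, subjects = 3000, seed = 11)
  expect_equal(d1$mean_rms, d2$mean_rms)
  expect_equal(d1$sd_rms, d2$sd_rms)
  d3 <- mc_rms_distribution(des, subjects = 3000, seed = 11, chunk_size = 700L)
  expect_equal(d3$subjects, 3000L)
  expect_lt(abs(d3$mean_rms - d1$mean_rms), 1.5)  # different draw layout, same law
  expect_warning(mc_rms_distribution(des, subjects = 1, seed = 1),
                 "standard deviation undefined")
})

test_that("independently seeded runs agree within Monte Carlo error", {
  des <- localization_design(speaker_array(5, 180), 5)
  n <- 20000
  d1 <- mc_rms_distribution(des, subjects = n, seed = 101)
  d2 <- mc_rms_distribution(des, subjects = n, seed = 202)
  se <- sqrt(d1$sd_rms^2 / n + d2$sd_rms^2 / n)
  expect_lt(abs(d1$mean_rms - d2$mean_rms), 3 * se)
})

test_that("mean session RMS rises toward the asymptote as repetitions grow", {
  arr <- speaker_array(3, 180)
  asym <- analytic_rms_asymptote(arr)
  means <- vapply(c(2, 5, 20, 100), function(r) {
    mc_rms_distribution(localization_design(arr, r),
                        subjects = 20000, seed = 7)$mean_rms
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(means < asym))
  expect_lt(asym - means[4], 0.35)
})

test_that("session RMS standard deviation shrinks like 1/sqrt(trials)", {
  arr <- speaker_array(3, 180)
  sd2 <- mc_rms_distribution(localization_design(arr, 2),
                             subjects = 20000, seed = 5)$sd_rms
  sd20 <- mc_rms_distribution(localization_design(arr, 20),
                              subjects = 20000, seed = 6)$sd_rms
  expect_lt(abs(sd20 / sd2 - sqrt(2 / 20)), 0.15 * sqrt(2 / 20))
})

test_that("rms_thresholds applies the one- and two-sided normal quantiles", {
  dist <- structure(
    list(design = NULL, subjects = 100000L, mean_rms = 101.0, sd_rms = 23.9,
         seed = NA_integer_),
    class = "rms_chance_distribution"
  )
  one <- rms_thresholds(dist, "one_sided")
  expect_equal((one$upper - dist$mean_rms) / dist$sd_rms, qnorm(0.95))
  expect_equal(one$lower, 101.0 - qnorm(0.95) * 23.9)
  expect_equal(round(one$lower, 1), 61.7)
  expect_true(round(one$upper, 1) %in% c(140.3, 140.4))

  two <- rms_thresholds(dist, "two_sided")
  expect_equal((two$upper - dist$mean_rms) / dist$sd_rms, qnorm(0.975))
  expect_equal(round(two$lower, 1), 54.2)
  expect_true(round(two$upper, 1) %in% c(147.8, 147.9))
  # two-sided interval strictly contains the one-sided one
  expect_lt(two$lower, one$lower)
  expect_gt(two$upper, one$upper)

  dist$sd_rms <- 0
  expect_error(rms_thresholds(dist), "positive standard deviation")
})

test_that("classify_rms orders better / consistent / worse around the interval", {
  dist <- structure(
    list(design = NULL, subjects = 100000L, mean_rms = 103.5, sd_rms = 10.2,
         seed = NA_integer_),
    class = "rms_chance_distribution"
  )
  th <- rms_thresholds(dist, "one_sided")  # about (86.7, 120.3)
  expect_equal(classify_rms(20, th), "significantly_better")
  expect_equal(classify_rms(103, th), "chance_consistent")
  expect_equal(classify_rms(150, th), "significantly_worse")
  expect_equal(classify_rms(c(20, 103, 150), th),
               c("significantly_better", "chance_consistent",
                 "significantly_worse"))
  expect_error(classify_rms(-1, th), "non-negative")
})
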