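# chancelevel

Chance-level performance thresholds for closed-set, forced-choice tests.

## The problem

Closed-set, forced-choice methods — closed-set speech audiometry, loudspeaker
localization with a fixed array — force the subject to pick one of *a* known
alternatives on each of *n* trials, so even pure guessing produces hits. The
conventional criterion treats any hit rate above 1/*a* as better than chance,
but 1/*a* is only the *mean* of the guessing distribution: across a session
of *n* trials the hit count *k* is binomial,

    P(k) = C(n, k) p^k (1 − p)^(n−k),   p = 1/a,

and chance-level hit rates form an interval around 1/*a*, not a point.

`chancelevel` turns that distribution into decision thresholds. A hit count
is *chance-consistent* when its point probability P(k) exceeds the criterion
(0.05 one-sided, 0.025 per threshold two-sided); the largest such hit rate is
the upper threshold **U** and the smallest the lower threshold **L**.
Observed rates strictly above U are significantly better than chance; rates
strictly below L (when L > 0) are significantly *worse* than chance — the
statistical signature of malingering, a misunderstood task, or an equipment
fault, since forced choice guarantees hits even without hearing. For
localization tasks the package also derives chance thresholds for the RMS
angular error by Monte Carlo simulation of guessing on the speaker array.

For whom: clinicians and researchers interpreting closed-set speech or
localization scores, and anyone designing such a test who wants trial counts
with a usable lower threshold.

## Worked example

A localization test with 3 loudspeakers and 30 trials:

```r
library(chancelevel)
d <- test_design(alternatives = 3, trials = 30)
chance_thresholds(d, "one_sided")
#> Chance thresholds (one-sided, criterion P(k) > 0.050)
#>   design: 3 alternatives, 30 trials
#>   L = 0.233 (7 hits)   U = 0.433 (13 hits)
```

So hit rates between 0.233 and 0.433 are attainable by guessing; the
conventional rule would already call 0.367 (11/30) "above chance".

```r
classify_hit_count(14, d)
#> Observed 14/30 hits (rate 0.467, P(k) = 0.0463): significantly above
classify_hit_count(6, d)
#> Observed 6/30 hits (rate 0.200, P(k) = 0.0484): significantly below
#>   Significantly below chance: malingering or systematic error suspected.
```

A cohort of 18 subjects, compared under both rules:

```r
hits <- c(14,15,16,14,17,20,18,14,15,22,19,16,14,13,10,8,7,5)
cohort_summary(hits, d)
#> Cohort of 18 subjects (a=3, n=30, one-sided)
#>   binomial rule:     13 above U, 4 within [L, U], 1 below L
#>   conventional 1/a:  14 above 0.333
```

The conventional rule over-calls above-chance performance; the binomial rule
additionally flags one subject as significantly *below* chance.

Chance-level RMS angular error for the same 3-speaker, 90°-spaced array:

```r
des <- localization_design(speaker_array(3, 180), repetitions = 10)
dist <- mc_rms_distribution(des, subjects = 100000, seed = 1)
dist
#> Chance RMS error distribution (3 speakers, 30 trials, 100000 subjects)
#>   mean 103.5 deg, sd 10.2 deg
rms_thresholds(dist, "one_sided")
#> Chance RMS thresholds (one-sided, z = 1.645): L = 86.7 deg, U = 120.3 deg
```

An observed session RMS below 86.7° is significantly better than guessing.

Printable threshold tables over a grid of designs come from
`threshold_table()` / `write_threshold_table()`, and
`inst/cli/chancelevel` exposes the same operations as a command-line tool
(`thresholds`, `table`, `grid`, `classify`, `cohort`, `rms-simulate`,
`rms-classify`, `simulate-cohort`).

See the vignette in `vignettes/chance-level-thresholds.Rmd` for the model,
its assumptions, and numerical choices.

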