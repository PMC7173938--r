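---
title: "Chance-level thresholds for closed-set forced-choice tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance-level thresholds for closed-set forced-choice tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chancelevel)
```

## The problem

In a closed-set, forced-choice listening test — closed-set speech audiometry,
loudspeaker localization with a fixed array — the subject must pick one of
`a` known alternatives on every one of `n` trials. Even a subject who hears
nothing produces hits: with guessing probability `p = 1/a` per trial, the
session hit count `k` is binomial,

$$P(k) = \binom{n}{k} p^k (1-p)^{n-k}, \qquad p = \tfrac{1}{a},$$

with mean hit count `n·p` and mean hit rate `p`. The traditional practice of
calling any hit rate above `1/a` "better than chance" ignores the scatter of
this distribution, which is substantial at clinical trial counts: chance-level
hit rates form an *interval* around `1/a`, not a point.

## The point-probability threshold rule

For a given design this package tabulates `P(k)` for every `k` and compares
each point probability against a significance criterion: 0.05 for one-sided
testing, 0.025 per threshold for two-sided testing. Hit counts with
`P(k)` above the criterion are attainable by guessing; the largest such hit
rate is the upper threshold `U` and the smallest the lower threshold `L`.
An observed rate strictly above `U` is significantly better than chance.
A rate strictly below `L` — possible only when `L > 0`, i.e. for few
alternatives and enough trials — is significantly *worse* than chance, which
is the statistical signature of malingering, a misunderstood task, or an
equipment fault: even total deafness should produce at least `L·n` hits when
responses are forced.

Note the rule tests the *point* pmf value, not a cumulative tail. This is
deliberate: it reproduces the published threshold tables this method is known
by (a cumulative exact test would, for example, call `k = 9` of 20 with
`a = 4` non-significant, whereas `P(9) = 0.027 ≤ 0.05` makes it significant
here). A consequence worth knowing is that the summed probability outside
`[L, U]` can exceed the nominal 0.05 — the rule bounds each point
probability, not the family error. `operating_characteristics()` reports the
realized outside-interval rate; for `a = 4, n = 20` it is about 0.065.

```{r thresholds}
d <- test_design(alternatives = 4, trials = 20)
chance_thresholds(d, "one_sided")
classify_hit_count(9, d)
```

## Numerical and boundary choices

* All threshold logic works on integer hit counts, so "strictly above U"
  is exact; results landing exactly on `L` or `U` are chance-consistent.
* The pmf is compared with the criterion using an absolute guard band of
  1e-12, so floating-point noise cannot flip a table cell. The
  chance-consistent hit counts must form one contiguous run (the binomial pmf
  is unimodal); a violation would be an internal error, and is asserted.
* Rounding to 3 decimals (half away from zero) happens only when rendering
  tables; internal values stay exact.
* `round_pmf = TRUE` reproduces a convention found in published threshold
  tables, where the criterion was evidently applied to pmf values rounded to
  3 decimals: probabilities within 0.0005 above the criterion (e.g.
  `P(12; 25, 1/3) = 0.0503`) are then treated as significant. The default
  compares at full precision; the option exists because a handful of
  published boundary cells differ between the conventions, and table-fidelity
  checks need to express both.
* **Degenerate regime.** For large `n` the binomial mode itself drops to or
  below the criterion (for `a = 2` one-sided this happens near `n ≈ 250`),
  and *no* hit count is chance-consistent. Reporting `L = U = 0` or an empty
  interval would be misleading, so the result carries `degenerate = TRUE`
  with `NA` thresholds and classification refuses to run. This is a genuine
  limitation of the point-probability rule at high trial counts, outside the
  `n ≤ 100` range the published tables cover.
* When no `k > 0` is significant on the low side, `L = 0` is reported with
  `lower_exists = FALSE`: below-chance detection is simply unavailable for
  that design, and the malingering flag can never fire.

## Localization: RMS angular error under guessing

For localization arrays the hit rate is not the only outcome; the
root-mean-square azimuth error over a session is the standard score. Under
guessing on an array of `a` speakers, each trial's response is the target
with probability `1/a` (error zero) and otherwise one of the remaining
`a − 1` speakers uniformly — equivalently, a uniform draw over all `a`
speakers. Every speaker serves as target `r` times, so a session has
`n = a·r` trials and

$$\mathrm{RMS} = \sqrt{\tfrac{1}{n}\sum_i (\theta_{resp,i} - \theta_{targ,i})^2}.$$

Hits contribute zero squared error and stay in the denominator. The
infinite-trial limit has the closed form

$$\mathrm{RMS}_\infty = \sqrt{\frac{1}{a^2}\sum_t \sum_{r\neq t} (\theta_r - \theta_t)^2}$$

(`analytic_rms_asymptote()`), which serves as the analytic oracle for the
Monte Carlo: finite sessions average slightly *below* it (Jensen's inequality
for the square root of a sample mean) and rise toward it as repetitions grow.
`mc_rms_distribution()` simulates 100,000 guessing subjects by default — large
enough that the standard error of the mean is a few hundredths of a degree —
and `rms_thresholds()` converts the resulting mean and standard deviation into
chance thresholds with one-sided/two-sided normal 5% quantiles
(`mean ± 1.645·sd` or `± 1.960·sd`), the construction that published RMS
threshold tables follow. Sample SD uses the `subjects − 1` denominator.
Angular error is the absolute azimuth difference on a line array; no circular
wrap-around is applied, which is unambiguous for spans up to 180°.

```{r rms}
des <- localization_design(speaker_array(3, 180), repetitions = 10)
dist <- mc_rms_distribution(des, subjects = 20000, seed = 1)
rms_thresholds(dist, "one_sided")
```

The vignette example uses 20,000 subjects so it runs in a moment; analyses
meant to match printed thresholds to a tenth of a degree should keep the
100,000-subject default.

## Synthetic responders

There is no public per-subject clinical dataset to exercise the decision rule
against, so the package ships a minimal generative responder model instead:
on each trial the subject knows the answer with probability `q`
(`knowledge_prob`); a *listener* answers correctly when they know it, a
*malingerer* deliberately answers among the wrong alternatives with
probability `v` (`avoidance_prob`) when they know it, and a *guesser* has
`q = 0`. Trials are independent and identically distributed — the stated
assumption of the threshold model itself (no learning or fatigue across
trials) — so the per-trial hit probability has the closed form
`q(1−v) + (1−q)/a` and every simulation has an exact binomial oracle.

What passing these simulations shows is that the decision rule has the
operating characteristics the binomial mathematics predicts. What they do
not show is anything about real listeners: real psychometric behaviour is
adaptive and trial-dependent, real malingerers are rarely perfectly
consistent, and `q` is not observable. The simulator validates the rule, not
the clinic.

```{r oc}
oc <- operating_characteristics(test_design(4, 50),
                                responder_model("malingerer",
                                                knowledge_prob = 0.6,
                                                avoidance_prob = 1),
                                sessions = 5000, seed = 2)
oc$below   # detection rate of the malingering flag
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alternatives` | — | response options per trial; `p = 1/a` must be ≤ 0.5 |
| `trials` | — | trials per session; more trials narrow `[L, U]` and raise `L` |
| `sided` | `one_sided` | criterion 0.05, or 0.025 per threshold two-sided |
| `round_pmf` | `FALSE` | compare 3-decimal-rounded pmf (published-table convention) |
| `subjects` | 100000 | Monte Carlo subjects for RMS distributions |
| `repetitions` | — | times each speaker is target; session has `a·r` trials |

## Known limitations

* The point-probability rule is inapplicable in the degenerate large-`n`
  regime (reported, not worked around).
* The family error outside `[L, U]` is not bounded by 0.05; use the reported
  analytic outside-rate if a calibrated error rate is needed.
* RMS thresholds assume the session RMS distribution is well-approximated by
  a normal in its central 95%; at very small trial counts (e.g. 6 trials) the
  true distribution is discrete and skewed, and the thresholds inherit the
  normal approximation from the published construction.
* Line arrays only; no elevation, wrap-around, or front–back confusions.
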