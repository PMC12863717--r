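---
title: "Information, rates, and the acquisition of conditioned responding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information, rates, and the acquisition of conditioned responding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoacq)
```

## The problem

In appetitive Pavlovian conditioning a rat learns that a conditioned
stimulus (CS, here a magazine light) predicts food delivered at CS
termination. Unlike a pigeon's key peck, the rat's measured response --
poking its head into the food magazine -- has a substantial baseline rate,
so "when did this animal start responding to the CS?" is a statistical
question about two event rates: the poke rate during the CS versus the
poke rate in the experimental context at large. `infoacq` implements an
information-theoretic treatment of that question, together with the
analyses that build on it: segmentation of response records into
constant-rate regimes, corrected response-rate estimation and the scalar
rate--reinforcement regressions, decile growth curves compared by BIC, and
the informativeness-based models of the learning rate.

Two protocol intervals organise everything. `T` is the mean CS--US
interval, so `1/T` is the reinforcement rate during the CS; `C` is the
mean US--US interval, so `1/C` is the contextual reinforcement rate. Their
ratio `iota = C/T` is the *informativeness* of the CS, and `log(iota)` is
the mutual information CS onset conveys about the wait to the next
reinforcement.

## The nDKL statistic

Inter-poke intervals are treated as approximately exponential, so a poke
rate is the single parameter of an exponential distribution, and the
divergence of one rate estimate from another has the closed form

$$D_{KL}(\lambda_X \| \lambda_Y) = \ln\frac{\lambda_X}{\lambda_Y} +
  \frac{\lambda_Y}{\lambda_X} - 1 .$$

The divergence plays the role of an effect size; multiplying it by the
effective sample size $n_e = n_X/(1 + n_X/n_Y)$ gives the evidence
statistic

$$n D_{KL} = n_e \, D_{KL}(\lambda_X \| \lambda_Y),$$

which under the null hypothesis of equal true rates is distributed
Gamma(shape 0.5, scale 1) -- equivalently, twice the statistic is
chi-squared on one degree of freedom, an identity `ndkl_p_value()` and
`odds_to_threshold()` exploit so either special function can be used.
Because the effective sample size is *inside* the statistic, it can be
recomputed trial by trial without fixing a sample size in advance. Odds of
4:1 against the null correspond to 0.82 nats and p < 0.05 to 1.92 nats:

```{r}
odds_to_threshold(c(4, 19))
ndkl(5, 0.25, 5, 0.005)
```

The worked example above -- 5 pokes in 20 s of CS against 5 pokes in
1000 s of observation -- gives a rate ratio of 50, a divergence of 2.93
nats, an effective n of 2.5 and an nDKL of 7.33 (7.32 when the divergence
is rounded to two decimals before multiplying), with odds against chance
on the order of 10^4 : 1.

## Trials to acquisition

`cumulative_rate_series()` accumulates, trial by trial, the CS poke rate
and the contextual rate (pokes and time pooled over the CS and the pre-CS
observation window; the context *includes* the CS, so the two counts share
events). The signed nDKL attaches a negative sign while the CS rate is
below the contextual rate. Acquisition indices:

* `t_exceed` -- the trial from which the cumulative CS rate is permanently
  above the contextual rate (the signed nDKL is permanently positive);
  reinforcements to acquisition is `t_exceed - 1`.
* statistical criteria -- the nDKL is recomputed starting *at* `t_exceed`
  (the restart rule): pre-acquisition trials would dilute the evidence and
  delay the criterion, by tens of trials in unfavourable records. The
  default thresholds are odds 4:1 (0.82 nats) and p < .05 (1.92 nats).
* `t_min_ndkl` -- the trial of the minimum signed nDKL, reported as a
  descriptive marker only; it can sit far from any systematic rise and is
  never used as the default criterion.

"Permanently" is evaluated within the observed record -- a fixed-length
retrospective analysis extrapolates nothing beyond the last trial -- and
exact zero differences count as *not* greater. Undefined entries (before
the first poke) are skipped, neither establishing nor breaking permanence.
A fixed-point variant, which searches for the smallest `t` whose restarted
record is permanently positive, is available as
`acquisition_profile(mode = "fixed_point")`; the default is the simpler
from-trial-1 formulation, and on clean steps the two agree to a trial or
two.

## Parsing response records into rate regimes

`parse_intervals()` recursively segments a vector of inter-poke intervals
into stretches of statistically constant rate. At each stage a divergence
profile is computed over every candidate truncation point `s`; if its
maximum exceeds the decision criterion `c` (in nats) the vector is
truncated at the argmax (earliest index on ties, a conservative preference
for early structure) and the algorithm recurses on the remainder.

The split statistic is the count-weighted divergence of the two
complementary sub-sequences from the full-sequence rate,

$$G(s) = s\,D_{KL}(\lambda_{1:s}\|\lambda_{full}) +
  (n-s)\,D_{KL}(\lambda_{s+1:n}\|\lambda_{full}),$$

which is half the likelihood-ratio deviance for one extra rate parameter
and therefore Gamma(0.5, 1) under the single-rate null -- the same null as
the nDKL, so the same odds conversions apply and a 6-nat criterion is
exceeded by chance about once in 1800 tests. This was a genuine design
choice: a one-sided profile that compares only the prefix against the
full sequence (kept as `comparison = "prefix"`) concentrates at most
about 5 nats at the boundary of a 30 + 30 vector with a tenfold rate
step, so under a 6-nat criterion it is effectively blind to structure at
that scale, while the two-segment statistic detects the same boundary
with over a hundred nats and localises it within two intervals in over
90% of seeded replicates. Because the first truncation is the argmax of
the same statistic an exhaustive single-split search would maximise, the
greedy parse agrees with that oracle by construction; recursion applies
to the post-truncation remainder only, which makes raising `c` a strict
coarsening.

Interval vectors follow the rate-estimation conventions. For the CS
(`build_cs_intervals()`): the first poke of each CS is excluded from the
count, its latency and all head-in time are excluded from the exposure,
and CSs with no pokes are excluded entirely; each countable poke
contributes the head-out gap that preceded it. Pre-CS (ITI) vectors
(`build_pre_intervals()`) use raw counts over a concatenated pre-window
timeline with no exclusions. The first segment of any parse extends back
to the start of observation, so an initial rate is defined even when the
first poke comes many trials in. The parse-based acquisition index is the
smallest trial boundary after which the parsed CS rate exceeds the parsed
ITI rate on at least 95% of trials.

## Corrected response rates and the scalar law

At high response rates the time the head spends inside the magazine (mean
poke duration about 0.5 s) is a substantial fraction of elapsed time, and
first-poke latencies (rarely below 2 s) come from a different
distribution than the later inter-poke intervals. `corrected_rate()`
therefore divides the count after exclusions by the time actually
available for initiating a poke. When a subject never pokes in the
pre-CS windows, the ITI count is set to 0.5 -- an unbiased stand-in for a
rate known only to lie between 0 and one per total exposure -- so its log
remains defined.

`terminal_rates()` pools the final five sessions (ten gives very similar
results and is available via `final_sessions`), and the log10-domain
regressions relate response to reinforcement rates. A slope fixed at 1
means strict proportionality through the origin; `fit_shifted_shared()`
fits one shared scalar plus a uniform log-shift of the ITI reinforcement
rate, interpreted as the CS overshadowing what the context would
otherwise be credited with. Base 10 is used throughout so a shift of 0.28
log units reads directly as a factor of 1.9. The regression BICs use the
same `n ln(RSS/n) + p ln(n)` formula as the growth module, with p
counting free intercepts and slopes.

## Growth to peak responding

`growth_decile_record()` takes the growth segment from an acquisition
criterion trial (the odds-4:1 criterion by default -- the analysis needs a
"reliably greater" starting point and that is the package's default
reliability threshold; it is configurable) to the peak of a three-session
moving average, then finds the trial at which the cumulative record's
slope first exceeded each decile of the rate increase: the argmax of
`(R1 + q * delta_R) * cumT - cumR`. Records with `delta_R` below 0.1
events/s are excluded as too flat for the decile geometry.
`fit_growth_models()` compares a line, an exponential, an inverse
cumulative Gaussian and a log form by BIC with n = 9. Nonlinear forms
start from deterministic coarse grids, so fitting has no seed dependence;
the inverse-Gaussian probability argument `m*d + 0.5` is kept inside
(0, 1) by construction of the profile grid, and a non-converging form is
flagged while the others are still reported.

## Theory models

`informativeness()` computes `iota`, its log (nats, with bits on request),
and the effective informativeness `(C + delay)/(T + delay)` under a US
detection delay -- a 39 s delay barely touches a protocol with iota = 1.5
(to 1.26, a 16% loss) but collapses iota = 300 to 80 (a 73% loss).
`fit_learning_rate()` regresses log median trials-to-acquisition on
`log(iota - 1)`, parameterised as `((iota - 1)/k')^s` so that the
x-intercept -- the informativeness giving one-trial acquisition -- remains
`k' + 1` for any slope, not only at s = -1. `response_probability()` is
the one-parameter generative model: each reinforced trial independently
triggers conditioned responding with probability
`p = 1 - exp(-k (iota - 1))` (the geometric reading; it is what produces
cumulative acquisition curves over trials), with `k = 1/297` as the
default constant. `ret_solve()` performs the rate-estimation credit
assignment by exactly inverting `[1, 1/iota; 1, 1]`; negative ascribed
rates are reported raw, since no truncation rule is part of the model.

## The synthetic cohort

`generate_cohort()` exists so that every stage of the pipeline can be
scored against known ground truth. Its defaults are the study conditions
the analysis targets: the 14-group design of `default_protocols()`
(iota from 1.5 to 300; 10 or 3 trials per session; 42 sessions), CS
durations uniform on `[2, 2T - 2]`, ITIs uniform with minimum 15 s and
mean `C - T` (so maximum `2(C - T) - 15`, the mean-centred reconstruction
of the design's bracketed ITI ranges), reinforcement at CS offset.
Behaviour: a common baseline rate for CS and pre-CS pokes before
acquisition; an acquisition trial drawn from the generative model with
`k = 1/297`; after acquisition an initial step of 25% of the distance to
the peak followed by a linear ramp over one third of the record (the
line is the growth form the decile analysis favours; the step reflects
the fact that the first increment in responding is typically large, and
it is what makes the change detectable close to its true trial); a
terminal CS rate of `beta/T` with `beta = 22` and a terminal ITI rate of
`beta/(1.9 C)`; poke durations 0.1 s + exponential with mean 0.5 s
overall (the mean is the contract, the shifted-exponential shape is a
modelling choice that avoids zero-length pokes); first-poke latencies
2 s + an exponential wait; and log-normal between-subject noise with
spread 2.5 (sd 0.39 log10 units) applied independently to the CS and ITI
scalars. Recording mirrors the measurement model: pokes are generated
only in the CS and the 10-s pre-CS windows, and a poke reaching a window
boundary is clipped there.

What the generator does *not* emulate: magazine-training prehistory and
the US-detection-delay artifact (exposed only as the `delay` adjustment in
`informativeness()`), within-subject rate drift and the non-monotonic
post-acquisition excursions real parses reveal, session-level motivational
effects, and any CS-directed behaviour competing with magazine entry. A
pipeline that passes on this cohort is validated as an estimator of the
generating process, not certified against every pathology of real data.

## Numerical choices and problem sizes

Times are seconds from session start at millisecond precision; trials are
1-based. Zero or negative rates make a statistic undefined (`NA`) rather
than raising an error or substituting a pseudo-count -- the 0.5-count
convention applies only where the terminal-rate analysis specifies it.
Beam re-entries recorded at the same millisecond are separated by 1 ms in
interval vectors. The validation studies shipped with the package use a
14 x 12 cohort at full length (420 or 126 trials per subject) for the
learning-rate law, a 14 x 24 cohort over 8 sessions for the scalar rate
law, 10^4 replicates for the null calibration of the nDKL, and 200
seeded replicates for parser recovery; all complete on a single CPU in a
few minutes.

## Known limitations

The exponential model of inter-poke intervals is an approximation; real
records show burstiness that inflates the nDKL's tails slightly, which is
one reason a conservative 6-nat parsing criterion is preferred. The
greedy parser is not a global segmentation: a configuration whose best
description requires simultaneously re-estimating earlier boundaries can
be mis-segmented, and no bidirectional refinement pass is applied by
default. On short null records the permanent-exceedance index is biased
early (any late upward fluctuation that never reverses counts), so
group-level learning-rate fits should restrict themselves to protocols
informative enough that acquisition is real, as the shipped validation
does (iota >= 4). Finally, the restart rule conditions on the exceedance
trial estimated from the same record; the resulting criterion trials are
slightly optimistic in noisy records, which is the price the analysis
accepts for not diluting post-acquisition evidence.
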