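---
title: "Inferring movement behaviour from acoustic detection gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring movement behaviour from acoustic detection gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Passive acoustic telemetry records presence only: a receiver logs a
time-stamped detection whenever a tagged animal's transmitter is decoded
within range (here a few hundred metres). Arrays deployed over large reef
systems trade positional accuracy for coverage, so most of an animal's time
is spent *between* detections. `telegaps` treats those detection gaps as
data. For obligate swimmers — ram-ventilating sharks that cannot rest
motionless on the bottom — a long absence from an array is evidence of
movement away from the monitored reef rather than of an animal resting in a
blind spot. The package classifies every gap into *restricted* (on-reef)
versus *out-of-range* (wider, off-reef) movement, then models what drives
the out-of-range behaviour.

## The movement events

Consecutive detections of one individual define one movement event:

* a **recursion** — both detections at the same receiver; the animal left
  detection range and returned (a self-loop in the movement network);
* a **transition** — detections at two different receivers.

Two filters clean the events. Recursions shorter than six minutes (two
nominal transmission intervals) are removed: a sub-six-minute gap at one
station is more plausibly a missed detection than a real departure and
return. Transitions need no minimum-gap filter — a detection at a new
station is itself evidence of movement — but implausibly *fast* transitions
are removed: with expected transit time $\hat t = d / v$ (great-circle
distance between the stations over the species' minimum sustainable swim
speed; 0.69 m/s for gray reef sharks, 0.73 m/s for silvertip sharks), the
relative deviation from expected time is

$$\mathrm{RDET} = \hat t / t_{\mathrm{obs}},$$

and transitions with RDET $> 5$ (five times sustainable speed) are treated
as probable false detections and dropped. Both filter rules are strict
inequalities, exactly as stated: a 360 s recursion and an RDET of exactly 5
are retained. Both constants are configuration keys, not code.

## Classification by Fisher optimal partitioning

Gap durations (recursions) and RDET (transitions) are strongly right-skewed
and bimodal when two behavioural states are present. Per species, the
package log-transforms the retained values and splits them into two classes
with Fisher's exact dynamic-programming partition — the contiguous
two-class partition of the sorted values minimising the within-class sum of
squared deviations from class means. Unlike eyeballing histograms, the
split is an optimum, and unlike k-means it cannot get stuck in a local one;
the test suite checks it against exhaustive enumeration of every contiguous
partition. The internal boundary, back-transformed, is the species'
threshold: recursions *longer* than the recursion threshold, and
transitions *slower* (lower RDET) than the RDET threshold, are labelled
out-of-range (1); everything else restricted (0). Ties go to restricted —
the conservative direction, consistent with thresholds loose enough that a
tortuous on-reef movement still counts as restricted.

Two conventions are worth stating. The reported break is the maximum value
of the lower class. And thresholds are computed per species on the full
filtered data set, before any train/test split: classification is treated
as a data-definition step, with cross-validation applying to the
explanatory model downstream.

## The inference model

Each labelled movement contributes one row: the binary label; species, sex
and log total length (cm) of the individual; diel period and season at the
movement's **start** instant (the departure detection — the moment the
behavioural decision is made; using the end or midpoint is a configuration
switch away and makes little difference at these gap lengths); and two
crossed grouping factors, individual and receiver. Day is 07:00–19:00 on
the local clock (a near-equatorial site; the two clock times are
configurable rather than computed from an ephemeris) and the wet season is
October–March. For transitions the receiver factor is the destination
(arrival) receiver by default; `receiver_role = "origin"` switches it.

The global model is a binomial GLMM (logit link, fitted by maximum
likelihood with `glmmTMB`):

$$\operatorname{logit} P(\text{out-of-range}) = X\beta +
  u_{\mathrm{tag}} + u_{\mathrm{receiver}},$$

with independent zero-mean normal random intercepts. Fixed effects are the
five a-priori covariates plus species interactions with each of the other
four. Before fitting, a collinearity gate computes
$\mathrm{VIF}_j = 1/(1-R^2_j)$ on the indicator-coded predictors and warns
above 5.

Model selection follows the information-theoretic recipe: every
marginality-respecting subset of the fixed effects is fitted (97 candidates
for the default term set; random intercepts always retained), ranked by

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$

with $n$ the number of movement rows. Models whose term set is a strict
superset of a better-scoring model are removed, and Akaike weights are
renormalised over the survivors. A single survivor is reported directly; a
best model with weight $\ge 0.9$ is reported alone; otherwise coefficients
are model-averaged — by default *full* (zero-substitution) averaging with
unconditional standard errors
$\sqrt{\sum_i w_i\,(\mathrm{SE}_i^2 + (\beta_i - \bar\beta)^2)}$; the
*natural* variant (averaging only over models containing the term) is a
configuration switch. Reported intervals are Wald bounds at the 97.5%
normal quantile (estimate ± 1.96 SE) with Wald z and p values.

Fit summaries use the Nakagawa decomposition for binomial-logit models,
with distribution-specific residual variance $\pi^2/3$:

$$R^2_m = \frac{\sigma^2_f}{\sigma^2_f + \sigma^2_{\mathrm{tag}} +
  \sigma^2_{\mathrm{recv}} + \pi^2/3}, \qquad
  R^2_c = \frac{\sigma^2_f + \sigma^2_{\mathrm{tag}} +
  \sigma^2_{\mathrm{recv}}}{\sigma^2_f + \sigma^2_{\mathrm{tag}} +
  \sigma^2_{\mathrm{recv}} + \pi^2/3},$$

where $\sigma^2_f$ is the variance of the fixed-effect linear predictor
over the data. Conditional modes (empirical-Bayes estimates) of the random
intercepts quantify individual heterogeneity: a level whose mode ± 1.96
conditional SD excludes zero departs significantly from the population
intercept, and the fraction of such individuals is reported per species.

Predictive validity uses an 80/20 movement-level split, stratified by
species (the split unit is not dictated by the method; movement level with
a recorded seed is the package's choice). The model refitted on the
training fraction predicts held-out probabilities — grouping levels unseen
in training contribute zero random effect, i.e. population-level prediction
— and the AUC of those probabilities against the held-out labels measures
ranking performance; 0.5 is chance.

Residual diagnostics are deliberately numeric and advisory: lag-1..20
autocorrelation of the Pearson residuals in data order against the
$2/\sqrt n$ band, and the ratio of residual SDs across fitted-value
quartile bins.

## What the synthetic generator emulates — and what it does not

`simulate_telemetry()` exists so that every stage can be exercised against
known truth without any field data. It generates:

* a ring (or grid) array with ~2.15 km nearest-neighbour spacing, checked
  against the admissible 0.55–4.57 km range;
* individuals of two species with the study's size distributions
  (119.15 ± 18.07 cm and 123.56 ± 19.14 cm), sex ratios, and swim speeds;
* residence bouts at a receiver with transmissions at the nominal 60–180 s
  delay, thinned by an i.i.d. Bernoulli detection probability (0.5);
* movements whose true state is drawn from the same logistic model the
  inference stage fits — intercept −0.475, silvertip effect +0.449, night
  +0.179, wet season +0.159, random-intercept SDs $\sqrt{0.43}$ for both
  factors (the sign pattern and magnitudes of a fitted reef-shark system) —
  with log-normal durations per state: recursion gap medians 18 min
  (restricted) vs 240 min (excursion), transition RDET medians 0.7 vs 0.05.
  Mode ratios above 10 make the two states genuinely separable, which is
  what the classification-recovery tests quantify.

Default desk scale is 14 + 11 individuals over a 45-day window that
straddles the dry/wet boundary (so season varies); these sizes, like the
residence-bout log-normal (median 90 min), are the package's choice of a
realistic but quickly simulated study and are stated here rather than
hidden in code.

The generator deliberately omits several features of real systems:
continuous-space movement (no correlated random walks — state and duration
are drawn directly), environmental modulation of detection probability
(wind, noise, diel detection efficiency), tag battery death, receiver
outages, and false-positive code collisions. Consequently, passing
recovery tests demonstrates that the *pipeline* is correct and that the
classification separates well-separated states; it does not show that real
arrays satisfy those assumptions. One emergent artefact is shared with
real data: runs of missed detections during a residence bout create short
same-receiver gaps that survive the six-minute filter and dilute the
labelled data with truly-restricted recursions, attenuating fixed-effect
estimates — visible in the generator's recovery reports, and a caution for
interpreting effect magnitudes from sparse arrays generally. Species
effects are also estimated with few effective replicates at desk scale
(they are between-individual contrasts), so parameter-recovery studies of
the inference stage use the direct model-table simulator
(`simulate_model_table()`, 150 individuals) where the mixed model itself is
the object under test.

## Numerical choices and degenerate inputs

* Fisher partitioning collapses ties to weighted unique values (optimum
  unchanged); an all-identical input returns that value with a warning.
* Zero-duration gaps (clock collisions) are dropped with a warning — they
  carry no duration information and would break the log transform and RDET.
* Zero distance between distinct receivers is a hard error: the method
  assumes non-overlapping detection ranges.
* Non-converged candidate models are excluded from the AICc ranking with a
  warning rather than silently ranked.
* Timestamps are stored UTC and read on a configured local clock
  (default UTC+06:00) for diel/season assignment only.
* The AICc sample size is the number of movement rows; no effective-sample
  -size correction is applied for within-individual dependence (the random
  intercepts carry that structure).

## Known limitations

The approach infers behaviour from absence, so its validity rests on the
ram-ventilator premise and on conservative thresholds; for species that
rest, or arrays with much wider spacing, a long gap is weaker evidence of
departure. Labels enter the GLMM as data, so classification uncertainty is
not propagated into the inference. And the per-species thresholds are
estimated from the same data the model is then fitted to; the
cross-validated AUC guards the model, not the thresholds.
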