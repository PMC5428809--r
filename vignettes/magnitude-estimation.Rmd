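---
title: "Simulating and analysing dot-cloud magnitude estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing dot-cloud magnitude estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotmag)
library(dplyr)
```

## The paradigm

dotmag simulates and analyses a magnitude-estimation paradigm in which each
trial presents a dynamic cloud of grey dots on a dark screen. A trial is
characterised by three magnitudes that are controlled independently:

* **Duration (D)** — the total presentation time, mean 800 ms;
* **Numerosity (N)** — the cumulative number of dots, mean 32 after
  calibration;
* **Surface (S)** — the cumulative area covered by the dots over the whole
  trial, mean 476 mm² after calibration.

On each trial one dimension is the *target* the observer must estimate on a
continuous vertical slider whose extremes are the smallest and largest tested
values; the other two dimensions are *non-targets* that can be pinned at
their mean, minimal (0.75×) or maximal (1.25×) values. Each tested dimension
takes six values: 75, 90, 95, 105, 110 and 125% of its mean. Two factorial
designs are provided: a fully crossed interference design under linear
evidence delivery (1080 trials: 3 dimensions × 5 conditions × 6 levels × 12
repetitions), and a design manipulating the temporal *regime* of evidence
delivery (1008 trials) in which dots arrive either front-loaded ("fast-slow":
75 ± 10% of dots within the first quarter of the trial) or back-loaded
("slow-fast": 25 ± 10% of dots within the first three quarters), with
duration tested only in its control condition.

## The synthetic observer

The observer is Bayesian: for each dimension it combines a noisy sensory
measurement with a Gaussian prior by precision weighting. Writing
$\sigma_s = c\,m$ for the scalar (Weber-like) sensory noise at true magnitude
$m$ and $(\mu_p, \sigma_p)$ for the prior,

$$\hat m = w\,x + (1 - w)\,\mu_p, \qquad
  w = \frac{\sigma_p^2}{\sigma_p^2 + \sigma_s^2}, \qquad
  x \sim \mathcal N(m, \sigma_s^2).$$

Because $w < 1$, estimates regress towards the prior mean — the central
tendency (Vierordt) signature — and the expected slope of estimates on
magnitude equals $w$.

Numerosity and surface are *accumulated* quantities. With rate coupling on
(the default), the observer does not read them out directly: it estimates the
delivery **rate** from the event table, weighting early evidence more
strongly (primacy), and multiplies that rate by its **perceived duration**:

$$\hat r = \frac{\sum_i e^{-\lambda t_i} m_i}{\int_0^D e^{-\lambda t}\,dt},
  \qquad \lambda = \frac{\ln 2}{h\,D},$$

where $t_i$ is the onset of event $i$, $m_i$ its contribution (1 per dot for
N, the dot's area for S), and $h$ is the primacy half-life as a fraction of
trial duration. The raw accumulated estimate $\hat r \cdot \hat D$ is then
perturbed by scalar noise and shrunk towards the dimension's own prior. This
single mechanism produces all three qualitative phenomena the package's
tests check:

* **Unidirectional interference.** $\hat D$ regresses towards 800 ms, so on
  short trials $\hat D > D$ and N/S are overestimated, on long trials the
  reverse; duration itself has no rate pathway and is immune to N, S and
  regime manipulations.
* **Regime bias.** For evenly delivered evidence $\hat r$ equals the true
  mean rate; front-loaded (fast-slow) delivery inflates it and back-loaded
  (slow-fast) delivery deflates it, so N and S — but not D — differ between
  regimes.
* **Central tendency** with slope $< 1$ in every dimension.

### Parameter defaults and why

| parameter | default | rationale |
|---|---|---|
| `prior_mean` | 800 ms / 32 dots / 476 mm² | session means; central tendency regresses to the mean of the stimulus set |
| `prior_sd` | 30% of each mean | yields shrinkage weights ≈ 0.7–0.8, i.e. tendency slopes in the range human observers produce |
| `sensory_cv` | 0.15 (D, N), 0.20 (S) | Weber ratios ≈ 0.10–0.13, well under the 0.25 calibration cap; the larger surface noise reproduces the stronger central tendency of surface |
| `primacy_halflife_frac` | 1 | at the admissible maximum: the weight on evidence at trial end is 0.5. Shorter half-lives produce regime biases so large (±30% and more) that psychometric functions saturate outside the tested level range; at 1 the biases are ±16–18%, strong but fittable |
| `lapse_rate` | 0.02 | occasional uniform slider lapses, so goodness-of-fit exclusions actually occur |
| `log_space` | FALSE | the slider analysis is linear in magnitude; a log-space option exists for users who want multiplicative priors |

Between-observer variation (`sample_cohort_params()`) multiplies the sensory
coefficients of variation by log-normal traits: one trait shared by duration
and numerosity, an independent one for surface. This implements the working
hypothesis that duration and numerosity share prior/precision structure
while surface stands apart, and is what makes cohort-level slope
correlations come out high for D–N and low for D–S and N–S.

## The stimulus generator

`onset_schedule()` delivers dots under three regimes. Linear: 9–13 evenly
spaced iterations of 2–7 dots (so cumulative count is proportional to
elapsed time); fast-slow and slow-fast: a per-trial fraction drawn uniformly
from 75 ± 10% (25 ± 10%) of dots placed uniformly in the first quarter
(first three quarters), the remainder uniformly in the rest of the trial —
the published description fixes only the segment totals, so uniform pacing
within segments is this package's choice. Onsets are floored to the 85 Hz
frame grid and capped at `D` minus three frames so the shortest admissible
dot lifetime (35 ms ≈ 3 frames) always fits; lifetimes are drawn uniformly
over 35–294 ms in whole frames and truncated at trial end.

`partition_surface()` converts between degrees and millimetres with the
exact tangent relation at 60 cm viewing distance, draws per-dot areas
uniformly inside the feasible per-dot interval and squeezes them affinely
towards the interval edge so that areas sum *exactly* to the requested
cumulative surface (the contract only requires 0.5%).

`place_dots()` samples positions uniformly over the annulus between the
3.3-degree protected fixation zone and the outer virtual disk, requiring
whole-dot containment, and enforces non-overlap **only between dots visible
at the same time** (rejection sampling, 10,000 attempts per dot, 20 trial
restarts). Overlap across time must be allowed because the cumulative
surface of a trial can exceed the annulus area.

### A geometric corner case

At 60 cm the smallest admissible dot (0.35°) covers ≈ 10.6 mm². Design cells
that pair a maximal dot count (40) with a minimal cumulative surface
(357 mm²) therefore request a mean per-dot area below the feasible minimum.
`partition_surface()` rejects such requests with the feasible interval;
`realize_stimulus()` defaults to `surface_policy = "clip"`, realizing the
nearest feasible surface and flagging the trial, so that full-design
simulations run. The affected cells are a small minority (extreme N↔S
interference cells) and do not touch the duration pathways under test;
`surface_policy = "strict"` restores the hard error.

## The analysis chain

Slider responses are binned into categorical '+'/'−' choices at the axis
midpoint (ties, the cursor's start position, count as '−'; with '+' at the
bottom the rule mirrors). Per participant, dimension and condition the '+'
proportions across the six levels are fitted by Bernoulli maximum likelihood
with a logit link (`stats::glm`); then

$$\mathrm{PSE} = f^{-1}(0.5) = \mu, \qquad
  \mathrm{WR} = \frac{f^{-1}(0.75) - f^{-1}(0.25)}{2\,\mathrm{PSE}}
             = \frac{s \ln 3}{\mu},$$

both of which the tests verify against brute-force numeric inversion of the
fitted curve to 1e-9. Goodness of fit is the residual-deviance test against
the saturated model on the six level bins. Fits with a non-positive slope,
failed IRLS convergence or complete separation are flagged unusable and feed
the exclusion rules. The published exclusion rule drops participants whose
control-condition goodness-of-fit p-values are *above* 0.05; that direction
is implemented verbatim as the default of `exclude_participants()`, but
`run_pipeline()` passes the conventional direction (`gof_rule = "low"`,
drop poor fits) because under a deviance test the p-value of a well-fitting
participant is roughly uniform, so the verbatim rule would empty any
well-behaved cohort. Per-condition PSE/WR values beyond 2 SD of the group
mean are replaced by the original group mean in a single pass.

Continuous estimates are regressed (OLS) on magnitude, both expressed as
percent of the level range; the default pools trials rather than per-level
means (the source description does not say which; both are available).
Cohort-level slope tables feed Pearson correlation matrices with Bonferroni
masking over the number of unique pairs, Fisher z-tests for differences of
correlations (independent-samples formula, which reproduces the published
Z values; Steiger's dependent-correlation test is available behind
`method = "steiger"`), and first-order partial correlations, verified in the
tests against a regression-residual oracle to 1e-12.

`calibrate()` implements the difficulty-matching loop: 30-trial probes
(5 per level) per dimension, logit fit, and a multiplicative update of the
numerosity and surface means towards the observer's indifference points
until all PSEs lie within 95–105% of their means and the Weber-ratio rules
hold (max/min ratio < 3, each WR < 0.25; the published third spread rule is
not interpretable as printed and is exposed as an optional hook, disabled by
default). Failure is declared after 50 iterations.

## Numerical choices, problem sizes, limitations

* Ties, degenerate inputs: slider midpoint → '−'; flat or separated response
  profiles → unusable fit (never silently extrapolated); zero-variance
  predictors are rejected in the tendency regression; constant columns in
  correlation matrices are masked, and correlation-difference tests are
  reported as `NA` when any zero-order correlation is ±1 or n ≤ 3.
* All randomness flows through named integer seeds; schedules, stimuli,
  sessions and whole pipeline runs are bit-reproducible given their seeds,
  and pipeline outputs are stamped with a configuration hash.
* The test-suite cohorts use 17 observers, full published designs (1080 and
  1008 trials), 100-replicate recovery runs, 200 placed stimulus
  realizations and 500-trial regime-signature runs — sizes chosen so the
  whole suite completes in a couple of minutes on one CPU while keeping
  Monte-Carlo error well below the tested margins.
* What the generator does **not** emulate: sequential (trial-order) effects,
  reaction times, motor noise beyond the lapse process, luminance or
  crowding cues, pixel-level rendering, and any deviation of real observers
  from Gaussian priors and scalar noise. Passing tests therefore show that
  the analysis chain recovers the phenomena *of this observer model*, not
  that the model is the true account of human magnitude estimation.
* The primacy-weighted-rate readout is one admissible formalisation of a
  verbal account; its half-life parameter is exposed so users can probe
  other weightings.

## A worked run

```{r pipeline, eval = FALSE}
report <- run_pipeline(pipeline_config(experiment = 1, cohort_size = 17,
                                       seed = 42))
report$flags
report$pse_contrasts
report$correlations$triplet
```

With the defaults this prints four `TRUE` flags (numerosity and surface
overestimated under the shortest duration, duration immune, all mean slopes
below one) and a slope-correlation triplet in which duration–numerosity far
exceeds the correlations involving surface.
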