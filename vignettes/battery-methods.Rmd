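---
title: "Simulating and analysing a vibrotactile psychophysics battery"
author: "tactsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a vibrotactile psychophysics battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactsim)
```

## What the package models

`tactsim` is a complete, testable re-implementation of the computational
chain behind a nine-protocol vibrotactile battery used to compare tactile
perceptual sensitivity across diagnostic group (autism spectrum condition,
ASC, versus typically developing controls, TDC) and sex. The chain runs:

1. **Cohort simulation** — synthetic observers with latent sensory
   parameters and demographic covariates (`effect_spec()`,
   `generate_cohort()`);
2. **Battery simulation** — two-alternative forced-choice (2AFC) trials
   delivered through adaptive staircases, a detection ramp, and fixed
   suprathreshold response-time tasks (`default_specs()`,
   `run_protocol()`, `run_dynamic_detection()`, `run_battery()`);
3. **Scoring** — mean response times by the median-six rule, staircase
   thresholds as final-five means, dynamic-detection means,
   percent-change indices per protocol pair, and median-absolute-deviation
   (MAD) outlier flagging (`score_battery()`, `derive_indices()`,
   `flag_outliers()`);
4. **Cohort matching** — greedy nearest-neighbour propensity matching to
   build demographically comparable groups (`estimate_propensity()`,
   `greedy_match()`, `run_matching_passes()`);
5. **Inference** — Welch t-tests, 2×2×2 factorial linear models over
   Condition × Diagnosis × Sex with partial eta-squared, and
   Jeffreys–Zellner–Siow (JZS) Bayes factors (`welch_t()`,
   `factorial_lm()`, `jzs_ttest_bf()`, `model_bf()`).

The original participant-level data are not public; every stage is instead
exercised against the synthetic-observer model, whose role and limits are
described below.

## The battery

Ten protocols exist on the physical instrument; the package implements the
nine analysed ones, organised in condition pairs (the dual-site-adaptation
variant is excluded for lack of usable data):

| pair | condition 1 | condition 2 | tracked quantity |
|------|-------------|-------------|------------------|
| response time | SRT (any finger) | CRT (matching finger) | RT, ms |
| detection | SDT (static, staircase) | DDT (2 µm/s ramp) | amplitude, µm |
| amplitude discrimination | ADT | ADTssa (single-site adaptor) | amplitude difference, µm |
| frequency discrimination | SQFD (sequential) | SMFD (simultaneous) | frequency difference, Hz |
| order judgement | TOJ | TOJwc (synchronous carrier) | ISI, ms |

Constants follow the published protocol descriptions: 20 trials for
SRT/CRT/SQFD/SMFD/TOJ/TOJwc, 24 for SDT/ADT/ADTssa, 7 ramp trials for DDT;
SDT starts at 20 µm with 1 µm steps; ADT tracks the comparison−standard
difference from 100 µm in 10 µm steps; SQFD tracks from 10 Hz in 1 Hz
steps; TOJ tracks the inter-stimulus interval from 150 ms in steps of 10%
of the current ISI; stimulus amplitudes stay inside the device envelope
(0–350 µm, 0–50 Hz).

### Staircase rule and its equilibrium

All tracked protocols use the same transformed up–down rule: trials 1–10
are one-up one-down; from trial 11 a single error makes the task easier by
one step while one step harder requires two consecutive correct responses
(counter reset on every error, level change, or phase boundary). This is
the Levitt rule whose stationary performance solves \(p^2 = 1/2\), i.e.
70.7% correct. Two readings of "two-up, one-down" are possible; the
package defaults to the convergent two-correct-down reading and exposes
the other as `rule2 = "two_wrong_up"`, which has no stationary point above
chance and therefore drives the track to the floor — the simulation shows
exactly that, which is why the default was chosen.

Numerical choices at the edges: levels are clamped to the device bounds,
with the lower clamp at one step above zero (a zero-difference 2AFC trial
is unscorable); the phase switch happens after the tenth response, so
trial 11 is the first phase-2 trial; practice trials run at the starting
level until three consecutive correct responses and are capped at 50
attempts — exceeding the cap raises an error, which the recovery analyses
treat as an exclusion, mirroring how a real session would end.

## The synthetic observer

Responses come from a Weibull psychometric function for 2AFC,
\[
\Psi(\Delta) = \tfrac12 + \left(\tfrac12 - \lambda\right)
  \left(1 - e^{-(\Delta/\theta)^\beta}\right),
\]
with threshold \(\theta\) per task (detection µm, amplitude-difference µm,
frequency-difference Hz, order-judgement ms), shape \(\beta\), and lapse
\(\lambda\). The parameterisation pins \(\Psi(\theta)\) at
\(0.5 + 0.5(1-e^{-1}) \approx 0.816\) (for \(\lambda = 0\)), slightly
above the staircase's 70.7% target, so staircase estimates sit a little
below \(\theta\) — the recovery tests bound that bias at two steps.

Default latent parameters describe a typically developing male child on
this instrument: \(\theta_{detect} = 10\) µm (between-observer SD 3),
\(\theta_{amp} = 40\) µm (SD 15), \(\theta_{freq} = 4\) Hz (SD 1.5),
\(\theta_{toj} = 40\) ms (SD 15), \(\beta = 6\), \(\lambda = 0.02\).
The steep shape is at the high end of published forced-choice detection
estimates and makes the simulated tracks as clean as practised observers'.
Group effects are additive offsets on each parameter (diagnosis, sex, and
their interaction), so a null specification is simply all offsets zero.
Draws are truncated at \(10^{-6}\) of baseline to keep thresholds
positive; lapse is clamped to \([0, 0.1]\).

The second condition of each pair multiplies the relevant threshold by a
condition multiplier ≥ 1 (defaults: 1.8 for the detection ramp, 1.5 for
adaptation, simultaneity, and the carrier). Multiplicative penalties match
the ratio form of the percent-change indices.

Response times are shifted log-normal
(\(rt = shift + \mathrm{lognormal}(\mu, \sigma)\), defaults
\(shift = 200\) ms, \(\mu = \log 150\), \(\sigma = 0.3\)) plus an additive
150 ms choice cost whenever the response must name the stimulated digit
(all protocols except SRT). Dynamic detection records the ramp amplitude
at the button press: the momentary threshold
(\(\theta_{detect} \times\) multiplier, perturbed by per-trial log-normal
noise, SD 0.15) plus ramp rate × motor latency (default 200 ms); the
pre-ramp delay contributes nothing because the amplitude is zero during
it. Ramps that would exceed 350 µm are censored at the bound and flagged.

What the generator does **not** emulate: learning or fatigue across the
fixed protocol order, attention lapses that cluster in time, within-session
threshold drift, or any item-level structure in the symptom covariates
(age, FSIQ and symptom scores are plain truncated normals per cell).
Passing tests therefore demonstrate that the processing chain is correct
and calibrated — not that real children behave like the model.

## Scoring rules

- **Mean RT**: sort usable RTs (correct-only for CRT), average the six
  central values — for \(n\) values, positions
  \(\lfloor (n-6)/2 \rfloor + 1\) … \(\lfloor (n-6)/2 \rfloor + 6\). With
  fewer than six usable values everything is averaged and the record
  flagged; the centred-window rule is this package's choice for the
  after-exclusion CRT case, which the published rule does not specify.
- **Staircase thresholds**: mean tracked level of the final five trials,
  in the track's unit. The frequency and order-judgement outcomes are
  computed in the tracked unit (Hz, ms); the published wording says
  "amplitude difference" for these, which we read as a typo.
- **Dynamic threshold**: mean recorded amplitude over uncensored trials.
- **Percent change**: \(100 \cdot (x_2/x_1) - 100\) with the second
  condition in the numerator for detection, frequency, and order
  judgement; the amplitude pair as printed inverts the ratio
  (ADT/ADTssa), and the package reproduces that by default with a
  `consistent_orientation` switch to force second/first everywhere.
- **MAD filter**: keep \(x\) iff
  \(|x - \mathrm{med}| / (1.4826 \cdot \mathrm{MAD}) \le 2.5\). The
  1.4826 consistency constant is the package's choice (the published rule
  names only the 2.5 cutoff) and is configurable, as is the grouping:
  default per protocol × diagnosis-by-sex cell, so that a true group
  difference is not flagged away; a per-protocol-global mode exists.

## Matching

Propensity scores come from a logistic model (IRLS, tolerance 1e-8, max
100 iterations) of cell membership on age and FSIQ (covariates are
configuration, since the original covariate list is not recoverable from
the main text). Greedy nearest-neighbour matching without replacement
processes treated units from the highest score down; ties break on the
lower observer id; an optional caliper in SDs of the logit score drops
distant matches. The default three passes anchor on the smallest cell —
autistic females — matching it 2:1 against autistic males, 2:1 against TD
males, and 1:1 against TD females; from a recruitment-scale cohort
(112/18/137/55) this yields an analysis set of 108 with cells close to
the published 36/18/34/20. Balance is reported as standardized mean
differences (pooled pre-match SD denominator) before and after.

## Inference

Each dependent variable (mean RT, detection, amplitude discrimination,
frequency discrimination, order judgement) enters a long table with two
rows per observer (one per condition) and is fit by OLS with sum-to-zero
contrasts on Condition, Diagnosis, Sex and all interactions. Sums of
squares default to Type III (Types I/II available; all three coincide on
balanced designs, which the tests verify). Partial eta-squared is
\(SS_{term}/(SS_{term}+SS_{res})\). When a noise-free construction makes
the residual exactly zero, drop-term sums of squares are computed directly
and affected terms report \(F = \infty\).

Treating the two condition rows per observer as independent copies
follows the published analysis design; under observer-level dispersion
this is anticonservative for between-subject factors, which is why the
calibration study below puts all dispersion in independent measurement
noise. An aggregate-per-observer analysis would be the conservative
alternative; it is deliberately out of scope here because the goal is to
reproduce the published chain.

Bayes factors: `jzs_ttest_bf()` implements the two-sample JZS Bayes
factor — Cauchy prior scale \(r = \sqrt{2}/2\) on the standardized effect,
integrated over the scale mixture by max-shifted adaptive quadrature
(relative error ≤ 1e-6; the tests pin it to a dense-grid brute-force
integral at 1e-4). `model_bf()` compares the factorial model with and
without one term under a Zellner–Siow mixture-of-g prior with a single g
shared by all effect columns (g ~ inverse-gamma(1/2, n/2), Jeffreys priors
on intercept and error variance), each marginal likelihood a
one-dimensional quadrature. A known artefact of the shared g: when the
retained model contains a very strong effect, the Bayes factor for adding
a further null column can exceed 1; per-effect g priors would avoid this
but are out of scope, and the calibration tests establish the
null-favouring behaviour on realistic designs.

## Calibration and recovery studies

Problem sizes were chosen to characterise each property well while keeping
the whole suite fast:

- **Equilibrium**: one 10,000-trial staircase against a stationary
  observer; phase-2 proportion correct lands within 0.02 of
  \(\sqrt{1/2}\).
- **Recovery**: 200 observers with \(\theta_{detect} \sim
  \mathrm{lognormal}(\log 10, 0.5)\), lapse 0.02, default 24-trial SDT
  spec; Pearson \(r(\theta, \hat\theta) \ge 0.9\) with mean signed bias
  within two steps. Observers failing the practice gate (about 1 in 200,
  at the extreme high tail) are excluded, as they would be in a real
  session. The dynamic-above-static ordering holds throughout the
  instrument's operating range; below roughly 4 µm the 24-trial track
  cannot descend far enough from the 20 µm start and overestimates, so
  the directional check samples thresholds within range.
- **Null calibration**: 500 cohorts at the published cell sizes
  (36/18/34/20) with all group offsets zero, outcome dispersion entirely
  from independent multiplicative measurement noise (CV 0.15); the Sex
  term rejects at 5% ± 2%, its p-values pass a Kolmogorov–Smirnov
  uniformity check, and the Sex model Bayes factor favours the null in
  well over 70% of runs. These draws use the latent outcome shortcut
  (`latent_outcome_table()`) rather than 500 full battery simulations;
  the full chain is exercised end-to-end separately.

## Reproducibility

Every stochastic entry point takes or derives from a single integer seed;
`run_pipeline()` writes all intermediate tables as CSV together with a
manifest carrying the package version, a canonical-JSON MD5 configuration
hash, and per-stage row counts, and is byte-identical across repeated runs
with the same configuration.

## Known limitations

- The published residual degrees of freedom (e.g. 172) arise from the real
  data's missingness pattern and are not reproducible; simulated analyses
  have their own df.
- The published headline F, partial eta-squared and BF values depend on
  the unavailable raw data; the package reproduces the published Welch
  p-values from the printed summary statistics, and for everything else
  establishes properties (calibration, recovery, oracle agreement) rather
  than numbers.
- Single-g model Bayes factors and duplicated-observer OLS have the
  caveats noted above; both follow the published analysis design on
  purpose.
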