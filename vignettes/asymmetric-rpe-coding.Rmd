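---
title: "Modeling asymmetric reward prediction error coding in intracranial HFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling asymmetric reward prediction error coding in intracranial HFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymrpe)
```

## The scientific problem

Reward prediction errors (RPEs) — the difference between the reward an agent
receives and the reward it expected — carry two distinct kinds of
information: a signed *value* (better or worse than expected) and an unsigned
*salience* (how surprising the outcome was, regardless of direction).
Classical reinforcement-learning (RL) accounts assume neurons code both on a
single symmetric axis: activity rises with positive RPEs and falls with
negative RPEs. Recordings from dopaminergic and cortical circuits complicate
this picture: some neural populations respond only to positive RPEs, some
only to negative RPEs, some to salience, and the response can go in either
direction. An *asymmetric coding* model — separate gains for positive-RPE
magnitude (pRPE) and negative-RPE magnitude (nRPE) — nests all of these
profiles.

`asymrpe` implements a complete, testable pipeline for studying asymmetric
RPE coding in feedback-locked high-frequency activity (HFA, 70–150 Hz power,
a proxy for local population firing) recorded from the salience network
(dorsomedial prefrontal cortex, dMPFC, and insula, INS). Because patient
recordings cannot be redistributed or regenerated, the package pairs every
analysis stage with a synthetic-cohort generator whose ground truth is known,
so each stage can be validated end to end: how often does the pipeline select
the right model, recover the planted gains, classify channels into the right
coding category, and recover a planted inter-regional coupling lag?

## The behavioral task and its simulation

The task is interval timing under adaptive difficulty. On each trial the
participant tries to respond exactly at a 1-second target; a visual cue shows
the current *error tolerance* (in ms) around the target, and the response
wins (+100 points) if the absolute timing error is within tolerance, loses
(−100) otherwise. Some task versions deliver *neutral* feedback (0 points,
no timing information) on a random 12% of trials. Easy and hard trials come
in separate blocks of 75; tolerance is adapted per condition by asymmetric
staircases: −3 ms after a win / +12 ms after a loss in easy blocks, −12/+3
in hard blocks, bounded to either 15–200 ms or 15–400 ms depending on task
version.

The zero-drift equilibrium of such a staircase clamps accuracy at
`up / (up + down)`: 12/15 = 0.8 for easy, 3/15 = 0.2 for hard. This holds
whenever the equilibrium tolerance lies strictly inside the bounds. For a
stationary Gaussian observer with timing noise SD `s` (in ms), the
equilibrium tolerance of the hard staircase is `s * qnorm(0.6) ≈ 0.25 * s`.
With 60 ms timing noise this lands at 15.2 ms — essentially on the 15 ms
floor — and clamping truncates the downward (win) step, which biases
long-run accuracy *above* 0.2 (to roughly 0.29 in our simulations). This
floor interaction is a genuine property of the staircase dynamics and worth
knowing when choosing observer parameters: the package's equilibrium checks
therefore use a 150 ms timing SD with the 15–400 ms bounds variant, which
puts both equilibria well inside the bounds (≈192 ms easy, ≈38 ms hard).

Simulated observers (`agent_config()`) are stationary Gaussian timers with
optional lapses; `run_session()` also supports a planted adaptation effect in
which the RT on trial *t* shifts by a configurable amount per unit of the
previous trial's pRPE or nRPE magnitude, computed against the observer's true
(closed-form) win probability. This provides ground truth for the RT-change
model ladder below.

Design choices the task description left open, decided once here: neutral and
missing trials do not move the staircase (they deliver no performance
feedback); omitted responses are labeled `missing` rather than treated as
losses; the training phase that initializes the staircases is replaced by a
configurable starting tolerance per condition; RTs and errors are kept in
seconds and tolerances in milliseconds, with conversions in one helper.

## Trial-level RL variables

Because the tolerance cue makes the win probability explicit on every trial,
expectations are modeled with a static psychometric model rather than a
temporal-difference learner: a per-participant logistic regression of
win/loss on tolerance (ms) over the whole session, excluding neutral-outcome
trials. From the fitted curve,

- `p_win = plogis(beta0 + beta1 * tolerance)`,
- expected value `EV = 2 * p_win − 1` (the reward range is −1/0/+1),
- signed RPE `sRPE = reward − EV`, salience `uRPE = |sRPE|`,
- `pRPE = max(sRPE, 0)`, `nRPE = max(−sRPE, 0)`.

The decomposition identities `pRPE − nRPE = sRPE`, `pRPE + nRPE = uRPE`,
`pRPE * nRPE = 0` hold exactly by construction and are asserted over full
synthetic sessions in the tests. Neutral outcomes inherit the block's
expectation, so they carry negative RPEs in easy blocks and positive RPEs in
hard blocks.

## The RT-adaptation model ladder

Trial-to-trial behavioral adaptation is modeled as a hierarchy of linear
mixed models for the change in RT between consecutive trials (first trial of
each block and trials after a gap excluded), with by-subject random
intercepts and previous-RT slopes:

| model | fixed effects added |
|---|---|
| b0 | intercept only |
| b1 | previous RT |
| b2 | + previous outcome |
| b3 | + previous RT × outcome |
| b4 | b3 + previous sRPE (value) |
| b5 | b3 + previous uRPE (salience) |
| b6 | b3 + previous pRPE + nRPE (asymmetric) |

All fits use maximum likelihood so that one-sided likelihood-ratio tests and
AIC are valid across nested models; b4 and b5 have equal parameter counts
and are compared by AIC only. Degrees of freedom for the LRT count fixed
effects plus random variances and covariances (so adding a random slope to
an intercept-only model costs 3 df). The previous-outcome factor uses
treatment coding with *win* as reference, which makes the loss interaction
coefficient directly interpretable as the extra mean reversion after losses.
Previous RT enters uncentered; the target interval is constant, so centering
would only shift the intercept. Fixed-effect p-values use Wald tests — with
Satterthwaite degrees of freedom via lmerTest on request, and a normal
approximation in the window/lag loops where thousands of fits make the
Satterthwaite computation wasteful and group counts are large.

On synthetic cohorts with a planted post-positive-RPE slowing of 0.02 s per
unit pRPE (10 subjects × 300 trials), the b6-versus-b3 likelihood-ratio test
detects the effect in well over 90% of replicates and the recovered
coefficient matches the planted value; on null cohorts the same test's
p-values are uniform. Those two calibration facts are what licenses
interpreting the ladder's output on real data.

## The synthetic neural cohort

Each channel's ground truth is a coding category and polarity drawn from a
configurable mix, realized as a triplet of gains (EV, pRPE, nRPE) with the
sign pattern that defines the category: pRPE-only channels have only the
pRPE gain non-zero (positive for regular coding, negative for inverted);
nRPE-only channels the reverse (regular means HFA *decreases* with growing
negative-RPE magnitude); signed-RPE channels have opposite-signed gains;
unsigned channels equal-signed gains; unresponsive channels all zeros. The
default mix places about a third of channels in pRPE and a third in uRPE,
with the remainder split across nRPE, sRPE and unresponsive, and makes
inverted coding common only for nRPE channels — echoing the empirical
prevalence pattern in human salience-network recordings.

The feedback-locked response is the gain-weighted RL drive times a unit-peak
Gaussian kernel (peak 275 ms in INS, 300 ms in dMPFC, width 100 ms) plus
AR(1) noise on the 25 ms grid (coefficient 0.5, stationary SD 1 by default;
fixture constants, not estimates of any dataset). Envelopes are generated
directly in baseline-normalized z-units so that planted gains live in the
same units as fitted regression coefficients. A separate fidelity layer,
`envelope_to_raw_trace()`, renders an envelope as a broadband voltage trace
— envelope-modulated 70–150 Hz noise over a 1/f-like background, sampled at
1000 Hz — for testing the spectral pipeline itself; the modulation depth
default (0.3 per z-unit) keeps log band power approximately linear in the
envelope.

Coupled INS→dMPFC channel pairs are generated from a smooth latent process:
the dMPFC channel receives a time-shifted copy (positive lags mean INS
leads) scaled by a trial-varying gain. The coupling strength is specified on
the *correlation* scale — the expected lagged Pearson correlation on a trial
is `base_r + m_ev*EV + m_p*pRPE + m_n*nRPE`, with the gain back-computed
through the analytic gain–correlation map — for the same reason envelopes
are generated in z-units: the planted modulation gains are then directly the
regression coefficients the analysis estimates, and the expected correlation
is linear in the predictors by construction rather than saturating at strong
coupling. Defaults: base correlation 0.4, modulation 0.08 per predictor
unit with ±30% per-pair jitter (pairs are heterogeneous in reality, and a
degenerate cohort of identical pairs would make pair-level random effects
unidentifiable), unit latent SD against unit channel noise (coupling SNR 1).

## HFA extraction

Raw epochs are reduced to normalized HFA in four steps, each exposed as a
function:

1. **Sub-band log power** (`extract_hfa_power()`): sliding 50 ms windows
   stepping by 25 ms; each windowed segment is Hann-tapered, zero-padded and
   Fourier transformed, and power is averaged over bins within ±10 Hz of
   each sub-band center (70…150 Hz in 10 Hz steps), then natural-log
   transformed. The ±10 Hz smoothing is the single-taper analogue of a
   multitaper bandwidth matched to the sub-band spacing; it is configurable.
   Window timestamps refer to the window start, half-open convention.
2. **Bootstrap baseline statistics** (`bootstrap_baseline_normalize()`): per
   channel and sub-band, the mean and SD of log power over the pre-stimulus
   baseline (−0.25 to −0.05 s before stimulus onset) are computed on each of
   500 trial resamples and averaged across resamples. Resampling makes the
   statistics robust to occasional contaminated baseline trials, which the
   tests verify directly against plain z-scoring with a planted outlier.
3. **Z-scoring and sub-band averaging**: feedback-locked log power is
   z-scored per sub-band with the averaged statistics, then sub-bands are
   averaged into one HFA series. Averaging correlated sub-band z-scores
   yields a series with SD below 1; per sub-band the baseline z-scores have
   mean ≈ 0 and SD ≈ 1, which is the calibration that matters.
4. **Window averaging** (`window_average()`): 50 ms windows stepping 25 ms
   over 0–0.6 s post-feedback — exactly 23 windows, forced by the
   window/step/range arithmetic.

## Window-wise encoding models and channel classification

Three single-trial models compete per time window and region: *value*
(`hfa ~ srpe + ev`), *salience* (`hfa ~ urpe + ev`) and *asymmetric*
(`hfa ~ nrpe + prpe + ev`), each with subject and subject:channel random
effects. Models are compared by AIC only; with thousands of trial-level
observations likelihood-ratio tests are significant everywhere and carry no
information. Region-level fixed-effect p-values are Benjamini–Hochberg
corrected across the 23 windows per term.

The full random structure (intercepts and all predictor slopes at both
levels) follows the nested-grouping convention; with desk-scale cohorts
(≤ 5 subjects) subject-level random slopes are weakly identified, routinely
singular, and — because every channel of a subject inherits that subject's
slope deviation — they degrade channel-level inference. `random = "channel"`
(subject intercept, full slopes at subject:channel) is therefore the
recommended and tested configuration at these sizes; `"full"` and
`"intercept"` remain available.

Channel-level inference uses conditional (BLUP) coefficients: fixed effect
plus the summed random deviations of the enclosing levels, with a
conditional SE that combines the fixed-effect SE and the conditional
variances (a normal approximation) and uncorrected two-sided p-values,
relying on BLUP shrinkage for conservatism. A channel is responsive to a
term if *any* window is significant at p < 0.05; the per-term peak is the
significant-window estimate of largest absolute value (earliest window on
ties), and the four-category decision table maps significance patterns and
peak signs to {pRPE, nRPE, sRPE, uRPE, none} with regular/inverted (or
increasing/decreasing) polarity. The same decision table — literally the
same function — classifies connectivity pairs.

Two honest caveats about this classification scheme, measured on the default
synthetic cohort (gain 0.5 z, 300 trials, noise SD 1) and visible in the
package's own acceptance tests: BLUPs shrink toward the *fixed* effect, not
toward zero, so when the cohort-average pRPE response is strongly positive,
channels whose true pRPE gain is zero inherit a positive bias; combined with
the any-of-23-windows rule this flags an appreciable fraction of null
channels and leaks some nRPE-only channels into sRPE/uRPE. Category recovery
at these settings is around 75–85%, not arbitrarily close to 100%, and the
rate at which unresponsive channels are called responsive materially exceeds
the nominal 5%. These are properties of the conditional-significance scheme
itself under a positively biased cohort mix, not implementation slack; they
sharpen as per-channel information grows (more trials, higher gain, lower
noise). Downstream category statistics (region comparisons by
Wilcoxon signed-rank with FDR over four categories, Kruskal–Wallis across
categories with FDR-corrected pairwise tests, multinomial spatial-gradient
test on xyz with uRPE reference) operate on whatever classification is
supplied and are validated on constructed inputs with known answers.

A rank-based inverse-normal transform (`rankit_transform()`,
`qnorm((rank − 0.5)/n)` with average ranks on ties) is provided as the
normality sensitivity analysis for heavy-tailed HFA values, alongside the
robust (Huber-reweighted, k = 2 robust SDs) fitting option in every model
wrapper.

## Directed connectivity

Per-trial time-lagged cross-correlation between INS and dMPFC channels on
the 25 ms grid, lags −400…+400 ms in 25 ms steps (33 lags), positive lags
meaning INS precedes dMPFC. The correlation epoch is 0–1.0 s post-feedback
(a configurable choice; the epoch must be long enough that the overlap at
±400 ms still spans ≥ 8 samples, the minimum enforced). Raw Pearson r is
modeled, matching the convention of predicting correlation coefficients
directly; Fisher-z can be applied to the table beforehand if desired.

Per lag, a mixed model `r ~ ev + prpe + nrpe` with subject and subject:pair
random effects is fit; fixed-effect p-values are FDR-corrected across lags
per predictor. Pair-level conditional series over lags yield each pair's
peak (largest absolute conditional estimate; earliest lag on ties), a Wald
test at the peak approximates pair-level significance (uncorrected p <
0.05), and the shared decision table assigns pair categories. Peak-lag
distributions and per-subject category proportions are compared with
Kruskal–Wallis and FDR-corrected rank-sum tests.

On synthetic cohorts with a +75 ms pRPE-modulated coupling the group-level
fixed effect peaks at exactly +75 ms and pair-level peak lags land within
one grid step for ≥ 90% of planted pairs. Pair *category* recovery shows the
same BLUP-shrinkage caveat as channels: null pairs embedded in a cohort with
a positive average modulation inherit part of that fixed effect, and the
peak-selection step (maximum over 33 correlated lags before an uncorrected
test) is anti-conservative for them, so the null-pair false-flag rate
exceeds the nominal 5% in a way that fluctuates strongly between cohorts.

## Problem sizes and numerical choices

The validation suite runs on one CPU in tens of minutes, with sizes chosen
as the smallest that leave the statistical questions well-posed: ladder
power and calibration use 10 subjects × 300 trials (100 and 200 replicates);
encoding model selection uses 50 cohorts of 4 subjects × 4 channels at the
kernel-peak window; classification uses one 5-subject × 6-channel cohort
with the full 23-window sweep; connectivity uses 5 subjects × 8 pairs with
600-trial sessions (two task runs per participant, as repeat sessions occur
in practice). Staircase equilibrium checks use a 150 ms-SD observer with the
15–400 ms bounds so both equilibria are interior (see above). Other
numerical conventions: natural log throughout; sub-bands normalized before
averaging; singular (boundary) random-effect fits retained as the valid ML
solution, with a diagonal-covariance refit (flagged `converged = FALSE`)
only on genuine optimizer failure — swapping covariance structures inside a
nested pair would invalidate the likelihood-ratio test; complete separation in the
value model is clamped to ±100 log-odds and flagged; zero-variance
correlation segments propagate as NA and lags with insufficient overlap are
dropped.

## What the synthetic cohort does and does not establish

The generator emulates the features the analysis depends on — staircase
trial statistics, logistic win-probability structure, kernel-shaped linear
RPE coding with autocorrelated noise, spatially clustered coordinates, and
lag-coupled pairs with RPE-modulated gain. It does not emulate volume
conduction, epileptiform artifacts, non-stationary learning, cross-frequency
structure, or any biophysics of the 70–150 Hz band beyond band-limited
amplitude modulation. Passing tests therefore establish that the pipeline's
inferences are correct *when the generative assumptions hold at realistic
signal-to-noise*, and quantify its error rates in that regime; they do not
certify performance on clinical recordings, whose preprocessing
(re-referencing, artifact review, line-noise removal) is out of scope here.
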