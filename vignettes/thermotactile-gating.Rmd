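---
title: "Simulating thermotactile gating experiments: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating thermotactile gating experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogate)
```

## The problem

Light touch can reduce the perceptual sensitivity to a concurrent, purely
thermal cooling of the skin — a thermotactile analogue of the gating long
known from touch–pain interactions. The behavioural evidence comes from
yes/no cold-detection experiments: a participant's detection threshold is
first estimated with an adaptive staircase, and a signal-detection phase
then presents near-threshold cooling with and without an accompanying
light-touch (or auditory) stimulus, so that sensitivity (d′) and response
bias (C) can be separated.

`thermogate` implements that entire computational chain against *simulated*
participants. The package does not model skin physiology or stimulator
hardware; its purpose is to make every analysis stage — staircase,
session design, SDT correction, planned comparisons, power calculation —
testable, with ground truth available by construction.

## The observer model

Each simulated participant is an equal-variance Gaussian observer with
linear transduction. On a cooling trial of magnitude $|\Delta T|$ (in °C
below baseline), the internal evidence is

$$X \sim \mathcal N(g \cdot \gamma \cdot |\Delta T|,\, 1),$$

where $g$ is the transduction **gain** (evidence units per °C) and
$\gamma \in (0, 1]$ is the **gating factor**, applied only when touch
accompanies the cooling. On a stimulus-absent trial $X \sim \mathcal N(0, 1)$.
The observer answers *yes* when $X$ exceeds a **criterion** $c$; concurrent
sound lowers the criterion by a **sound bias shift** (a liberal shift). A
**lapse** probability mixes in a random response. In closed form,

$$P(\text{yes}) = \frac{\lambda}{2} + (1-\lambda)\,
  \Phi\!\left(g \gamma |\Delta T| - c_\mathrm{eff}\right).$$

This is the minimal observer whose parameters map one-to-one onto the
measured quantities: analytic $d' = g\gamma|\Delta T|$ and (in the sign
convention used throughout, where positive C means a *yes* tendency)
$C = g\gamma|\Delta T|/2 - c_\mathrm{eff}$. Touch is a pure sensitivity
effect and sound a pure bias effect, so each experimental effect direction
is carried by exactly one parameter. We deliberately fix touch as a pure
gain effect — whether touch could also shift bias is left open by the
behavioural data (the bias comparison there was non-significant), and a
one-parameter-per-effect model keeps parameter recovery well defined. No
unequal-variance or high-threshold variants are provided.

The default lapse (0.02) keeps simulated hit rates off ceiling, as
observed empirically in this kind of task.

```{r observer}
obs <- observer_params(gain = 2, criterion = 1, gating_factor = 0.65)
c(cold = p_yes(obs, "Cold", -1), touch = p_yes(obs, "ColdTouch", -1))
```

## The staircase

Thresholds are estimated with two parallel, interleaved weighted
staircases following a 3-down/1-up rule armed by the first *no*: before
the first negative response every *yes* weakens the stimulus by the down
step (a 1-down lead-in, the cited convention for this rule); afterwards
three consecutive *yes* responses weaken by **+0.1 °C** and a single *no*
strengthens by **−0.14 °C**. Levels are clamped to **[−2.0, −0.2] °C**
(the carry-on rule: the run continues at the bound; a clamped non-move
records neither a direction nor a reversal). One branch starts at −0.2 °C
and becomes progressively colder, the other starts at −1.2 °C and becomes
progressively less cold; on each trial one unfinished branch is chosen
uniformly at random (the interleave schedule is otherwise unspecified in
the experimental literature we follow). Each branch stops at **12
reversals**; a reversal is recorded at the level where an executed move
changes direction relative to the previous executed move — consequently
the first *no* after a run of lead-in *yes* moves does count as a
reversal, while the very first move of a branch never does. A safety cap
(200 trials/branch) terminates degenerate runs that can never produce 12
reversals; such branches yield no estimate and are flagged.

The branch threshold is the mean of the reversal levels ignoring the
first three, and the two branches are averaged. An alternative estimator
(mean level of the *no* trials after the first three *no* trials) is
available as `estimate_threshold(..., method = "no_trials")`; the
reversal mean is the default and the one the pipeline uses, since the
reversal-based definition is the standard summary for this procedure.

With unequal steps the asymptotic convergence point of a 3-down/1-up rule
is the level detected with probability
$(0.14 / 0.24)^{1/3} \approx 0.836$; with finite runs and reversal
averaging the simulated procedure tracks ≈ 0.82, i.e. the ~80 %
per cent-correct point:

```{r staircase}
run <- run_dual_staircase(obs, seed = 42)
c(threshold = run$threshold, p_at_threshold = p_yes(obs, "Cold", run$threshold))
```

## The detection session

A session crosses conditions (Cold, Cold-and-touch, and in Experiment 3
Cold-and-sound) with 27 signal and 27 noise trials per condition, fully
interleaved in uniform random order. (Whether the original sessions were
blocked or fully interleaved is not fully specified; full interleaving is
implemented.) Cooling lands on a 3 × 3 grid of skin locations; the
schedule never revisits a location within a window of three trials — the
first nine trials are a random permutation of all locations, and each
later trial draws from the locations absent from the preceding window.
With the trial timing (0.5 s baseline, 2 s pre-stimulus lead, 8 s
inter-trial interval, 1.5 s response allowance), three intervening trials
guarantee more than 30 s of thermal recovery at every site.

Cooling dynamics use a deliberately simple exponential-approach model
$T(t) = -A\,(1 - e^{-t m/\tau})$ sampled at a jittered ~7.24 Hz loop,
with a per-trial lognormal rate multiplier $m$; defaults
($A = 2.4$ °C, $\tau = 4$ s, $\mathrm{sdlog} = 0.6$) give durations of
roughly 1.5–8 s at typical targets and a failure (10 s time-out) rate of
a few percent, the scale seen in practice. Only durations, failures and
the sampled feedback matter downstream, so no attempt is made to model
stimulator physics. Noise trials replay a duration resampled from the
successful signal exposures recorded so far in the session (before any
exist, the model's nominal crossing time is used): this preserves the
duration distribution without forcing a signal-before-noise ordering.

Failed trials are recorded, excluded from analysis, and repeated at a
random later queue position that still respects the revisit window. When
no such position exists (a repeated trial squeezed near the end of a
session), the session waits out the remainder of that location's 30 s
recovery window before delivering the cooling — the simulation analogue
of the experimenter pausing between trials — so the recovery property
holds deterministically, not just with high probability.

## SDT analysis

Outcomes are tabulated per condition (hit = yes|signal, miss = no|signal,
false alarm = yes|noise, correct rejection = no|noise), and rates receive
the loglinear correction,

$$H = \frac{\mathrm{hits} + 0.5}{n_\mathrm{signal} + 1}, \qquad
  F = \frac{\mathrm{FA} + 0.5}{n_\mathrm{noise} + 1},$$

before $d' = z(H) - z(F)$ and $C = (z(H) + z(F))/2$. Two choices deserve
emphasis:

* **Uniform correction.** The correction is applied to every
  participant/condition cell, not only those with a rate at 0 or 1.
  Correcting conditionally mixes corrected and uncorrected cells within
  one comparison and biases it; the conditional variant remains available
  (`variant = "conditional"`) since the verbal description of the method
  ("adjusts when rates are 1 or 0") is ambiguous between the two.
* **Sign of C.** Positive C indicates a *yes* tendency and negative C a
  *no* tendency. This is the **negative** of the common textbook
  $c = -(zH + zF)/2$; it is chosen so the sign reads directly as the
  response tendency, and it is the convention assumed everywhere in the
  package — check it before comparing numbers across sources.

## Cohort inference

The planned comparisons mirror a pre-registered design: Cold vs
Cold-and-touch d′ with a **one-tailed** paired t-test (the gating
hypothesis predicts the direction), the corresponding C comparison
two-tailed, and — where sound is present — Cold vs Cold-and-sound
two-tailed for both measures (no directional prediction for sound).
Pooling across experiments and the tone-vs-LED alerting comparison use
Welch's t-test. The effect size `d_av` divides the mean difference by the
average of the two condition SDs; this is the definition that reproduces
the printed effect sizes of the summary statistics this design targets
(`d_z`, the mean difference over the SD of differences, is available as a
variant but is not the default). A floor/ceiling rule (overall accuracy
above 95 % or below 50 % in any condition) excludes participants before
inference; it is on by default and reports the excluded ids.

The a-priori sample-size solver evaluates exact noncentral-t power
($\mathrm{df} = n-1$, noncentrality $d\sqrt n$) over increasing $n$:

```{r power}
required_n_paired_t(effect_size_d = 0.857, alpha = 0.05,
                    power = 0.80, tail = "one")
```

## Simulation defaults and what they emulate

`cohort_hyperparams()` defaults describe a 12-participant cohort on the
scale of the motivating experiments: gain 2.0 ± 0.4, criterion
1.06 ± 0.25, gating factor 0.65 ± 0.10, sound shift 0.2 ± 0.1, lapse
0.02 ± 0.01 (clamped to legal ranges after sampling). These were derived
once from the published summary scale — a Cold d′ near 1.9 at an ~80 %
threshold near −1 °C implies gain ≈ 2 and criterion ≈ 1.06, and a touch
effect of Δd′ ≈ 0.7 at that level implies a gating factor ≈ 0.65 — and
are not tuned thereafter. The generator emulates between-participant
parameter spread, staircase placement noise, binomial trial noise, lapses
and failed-trial repetition. It does **not** emulate learning or fatigue
across a session, criterion drift, spatially varying sensitivity across
the grid, or serial dependence between trials; passing tests therefore
validate the computational chain under a stationary observer, not those
aspects of real data.

Reproducibility: one master seed drives everything through a documented
splitting scheme (`split_seed()`), with one child stream per participant
and phase, so any participant's staircase or session can be re-simulated
in isolation. Two runs of `run_pipeline()` under the same configuration
are byte-identical.

## Numerical choices and degenerate inputs

* d′/C require rates strictly inside (0, 1); uncorrected extreme rates
  are rejected rather than silently clamped.
* Staircase levels are clamped to the bounds; reversal counts are capped
  by construction; estimation with ≤ 3 reversals raises an error rather
  than extrapolating.
* Zero-variance differences (every participant identical) make the paired
  t-test undefined and raise an explicit degenerate-input error.
* Welch's test reduces to the pooled t when variances and group sizes are
  equal (verified to 1e−9 in the tests); the noncentral-t power solver is
  cross-checked against `stats::power.t.test`.
* The thermal model's analytic failure probability
  (`thermal_fail_prob()`) ignores the finite sampling grid, which can
  only delay detection of the threshold crossing; the simulated failure
  rate therefore sits at or marginally above it.

## Problem sizes used in the shipped checks

The package's own verification runs at desk scale, chosen to make
Monte-Carlo error small relative to the tolerances under test: 500
staircase runs for the convergence study (mean P(yes) at threshold within
±0.06 of 0.80), 100 full sessions for the thermal-recovery minimum, 1000
simulated null cohorts for the type-I error of the planned one-tailed
comparison (0.05 ± 3 binomial SE), and 200 cohorts for effect recovery
under study-scale gating. Calibration studies use the binomial shortcut
`simulate_cohort_sdt()` — identical in distribution to the full session
for this observer — so they run in seconds.

## Known limitations

The observer is stationary and trial-independent; gating is multiplicative
on gain only; thermal dynamics are phenomenological; the interleave and
break structure of real sessions is reproduced only as timeline gaps. None
of these affect the analysis-stage computations, which is what this
package exists to verify.
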