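---
title: "Modeling and analyzing vasovagal responses to sGVS: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analyzing vasovagal responses to sGVS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vvsim)
```

## The problem

Sinusoidal galvanic vestibular stimulation (sGVS) — a low-frequency
sinusoidal current applied binaurally over the mastoids — triggers a
vasovagal-like response in anesthetized rats: mean arterial pressure (MAP)
and heart rate (HR) fall during stimulation, and cerebral blood flow (CBF,
measured by laser-Doppler flowmetry in relative perfusion units) shows a
*delayed*, rapid, sustained drop that mirrors the cerebral hypoperfusion of
human vasovagal syncope. The analysis questions are tabular and statistical:
how large are the changes relative to a pre-stimulation baseline, when does
the CBF drop occur, which animals responded at all, and do the groups
(sham, sGVS, sGVS after isoflurane preconditioning) differ across the
analysis windows?

`vvsim` implements that analysis pipeline — window segmentation,
percent-change summaries, a baseline-referenced sustained-drop detector with
its drop-delay statistic, a stimulus-locked oscillation score, the responder
inclusion rule, and a balanced two-way group × window ANOVA with
Šidák-adjusted pairwise comparisons — together with a phenomenological
simulator of complete sessions, so that every stage can be verified by
parameter recovery on synthetic cohorts. No public recordings of this
preparation exist; the simulator is therefore a first-class, tested part of
the package, not a fixture.

## The session model

A session covers a 4-minute baseline, 3 minutes of stimulation (default
4 mA at 0.025 Hz, starting at $t_0 = 240$ s), and 30 minutes
post-stimulation: 37 minutes sampled at 10 Hz by default (≈22 k samples).
The sampling rate is configurable; 10 Hz resolves the 15-second sustain
criterion with 150 samples while keeping sessions small.

For a responding, stimulated animal each physiological channel is

$$x(t) = b + \delta\,t + o(t) - d\,b_0\,u(t) + \varepsilon(t),$$

where $b$ is the channel baseline, $\delta$ a linear anesthesia drift,
$o(t)$ the stimulus-locked oscillation (MAP and HR only, during stimulation
only, amplitude `osc_amp_frac` × baseline at the stimulus fundamental),
$u(t)$ a unit response shape, $d$ the calibrated response depth, and
$\varepsilon$ iid Gaussian noise with SD `noise_sd_frac` × baseline
(1% by default). Non-responders and sham animals keep only
$b + \delta t + \varepsilon$; sham sessions also carry zero current.

The unit shapes are:

* **MAP/HR**: a cubic smoothstep from 0 to 1 over the first 15 s of
  stimulation (the pressor fall is rapid), a plateau until stimulation ends,
  then exponential relaxation (MAP time constant `map_recovery_tau`, 60 s).
  HR holds its plateau for `hr_recovery_delay` (10 min for the sGVS preset,
  0 for the preconditioned preset) before relaxing. With probability
  `phase1_prob` (7/16) HR additionally receives a brief rise at onset,
  modeled as a 10-s half-sine bump of +5% of baseline — the early transient
  seen in a subset of animals.
* **CBF**: flat until a drawn delay, then a rapid cubic-smoothstep drop with
  a 5-s rise time *completing exactly at the drawn delay* (so the drop-delay
  statistic has an unambiguous programmed value), a plateau until
  stimulation ends, then recovery of only `cbf_recovery_frac` (70%) of the
  drop — CBF does not return to baseline. With probability
  `gradual_decline_prob` (5/16) the drop is preceded by a slow linear
  decline lasting 21 ± 5.6 s that reaches 10% of the full drop depth: a
  subtle pre-drop sag, deliberately below the 3-SD detection criterion at
  default noise so the delay statistic stays anchored at the rapid drop.

The CBF drop delay is drawn per animal from a normal distribution
(51 ± 21.7 s for the sGVS preset; 72 ± 36.4 s for the preconditioned
preset), redrawn up to 20 times if it falls outside
$[5, \mathrm{duration} - 1]$ s, after which the animal is demoted to
non-responder with a logged message.

### Effect sizes and their calibration

Per-animal effect sizes for MAP, HR, and CBF are drawn from normal
distributions (winsorized into $[0.01, 0.95]$; the CBF draw is floored at
0.05 because a "responder" whose drop cannot exceed the ~3%-of-baseline
observability criterion is a contradiction in terms). The drawn effect is
defined as the **noise-free stimulation-window mean fractional change from
the baseline-window mean** — precisely the quantity the percent-change
pipeline estimates. The underlying plateau depth $d$ is solved analytically
from the drawn delay, the drift, and the oscillation term:

$$d = \frac{\bar m_S - (1 - f)\,\bar m_B}{b_0\,\bar u_S},$$

with $\bar m_B$, $\bar m_S$ the window means of the depth-free deterministic
trace and $\bar u_S$ the stimulation-window mean of the unit shape. Because
the CBF drop is delayed by ~51 s of the 180-s window, the plateau is
correspondingly deeper than the drawn window-mean effect (≈31% below
baseline for a 22% window-mean effect at the mean delay). This choice makes
the generator's parameters directly recoverable end-to-end by the pipeline
and is asserted exactly (to 1e-6) in the test suite with noise disabled.

### What the presets encode

| parameter | sham | sgvs | sgvs_iso_pc | provenance |
|---|---|---|---|---|
| MAP / HR / CBF baseline | 90 mmHg / 350 bpm / 1780 PU | same | same | CBF as reported for this preparation; MAP/HR are synthetic conventions typical of anesthetized rats |
| MAP effect (window mean) | 0 | 8 ± 4% | 8 ± 4% | reported mean; SD a convention matching the CBF coefficient of variation |
| HR effect | 0 | 10 ± 5% | 10 ± 5% | synthetic convention (no reported value) |
| CBF effect | 0 | 22 ± 11.7% | 12 ± 6% | sGVS values as reported; preconditioned mean attenuated (reported only qualitatively) |
| CBF drop delay | — | 51 ± 21.7 s | 72 ± 36.4 s | as reported |
| phase-1 HR rise | — | 7/16 | 7/16 | as reported |
| gradual pre-drop decline | — | 5/16, 21 ± 5.6 s | same | as reported |
| HR post-stim depression | — | 600 s | 0 s | HR stays depressed ~10 min after sGVS; recovers immediately after preconditioning |
| drift (MAP, HR, CBF) | −0.3%/min, −0.4%/min, 0 | same | drift_hr = 0 | steady anesthesia decline in MAP and HR, none in CBF; magnitudes are conventions |
| responder probability | 1 | 8/10 | 7/10 | exclusion rates of the stimulated groups |

## Segmentation and summaries

`standard_windows()` returns Baseline `[0, 240)`, Stimulation `[240, 420)`,
and the post-stimulation subdivision `[420, 720)`, `[720, 1020)`,
`[1020, 1620)`, `[1620, 2220)` s (0–5, 5–10, 10–20, 20–30 minutes after
stimulation ends). Two conventions are fixed deliberately: windows are
half-open so boundary samples are never double-counted, and the Stimulation
window starts at minute 4 — baseline collection lasts exactly 4 minutes and
stimulation starts when it ends, so an analysis window mixing the last
baseline minute into "stimulation" would dilute every effect estimate.
Summaries use the arithmetic mean and the sample SD ($n-1$ denominator, the
convention of the common graphing software); percent change is
$100\,(\bar x_W - \bar x_B)/\bar x_B$ against the baseline window, which is
exactly 0 for baseline against itself. Only the three physiological
channels are summarized; the current channel is carried for plotting and
the oscillation score.

## The sustained-drop detector

Given baseline statistics (mean and sample SD per channel over the baseline
window; a zero SD is a hard error because the thresholds would be
undefined), the detector:

1. smooths the channel with a centered moving average of half-width 1 s
   (at 10 Hz nearly every raw sample is a local extremum; the half-width is
   configurable and 0 disables smoothing — constructed noise-free fixtures
   are analyzed unsmoothed so detected times are exact);
2. finds local minima of the smoothed trace inside the stimulation window —
   samples no greater than both neighbors, plateaus resolved to their first
   sample, boundary samples compared to their single neighbor (a
   monotonically decreasing window yields one candidate at its end);
3. returns the **first** candidate (one delay is reported per animal;
   ties break to the earliest time) that is more than `k_sd = 3` baseline
   SDs below the baseline mean *and* whose surrounding excursion stays below
   the sustain level for more than `min_duration = 15` contiguous seconds.

The sustain level defaults to the same mean − 3 SD threshold as the depth
criterion, so the two criteria describe one coherent excursion; the laxer
below-baseline-mean reading is available via `sustain = "baseline"`. The
drop delay is the time of the qualifying minimum minus the stimulation
onset. Raising `k_sd` or `min_duration` can only remove events, never add
them — asserted on fixed fixtures.

## The oscillation score and inclusion rule

The responder criterion needs a quantitative reading of "oscillatory
response of MAP or HR". The score is the ratio of periodogram power at the
stimulus frequency during stimulation to the noise power at that frequency
during baseline. Two numerical choices matter:

* the stimulation-window (numerator) power uses a Hann taper: the stimulus
  frequency sits 4.5 Fourier bins from DC at the default parameters, and a
  rectangular window would leak substantial power from harmonics and from
  the step-like MAP decline into the probe frequency;
* the baseline (denominator) power is averaged over a ±3-bin band at the
  baseline window's resolution (the first harmonic lies outside it). A
  single-ordinate denominator would give the score an F(2, 2) null —
  infinite variance, 20% of null scores above 4 — making any threshold
  useless; band-averaging yields an approximately F(2, 14) null.

The default decision threshold, 20, sits at roughly the 99.99th percentile
of that null, chosen analytically from the null distribution rather than
from any simulation run: misclassifying a true non-responder as oscillating
should be rare at cohort scale, and genuine stimulus-locked oscillations at
the preset amplitude (3% of baseline against 1% noise) score in the
thousands, so the threshold placement has orders-of-magnitude slack on both
sides.

An animal is excluded only when MAP *and* HR both fail the decrease
criterion (stimulation-window percent change below −2%, a level well beyond
what anesthesia drift produces in 3 minutes) *and* both fail the
oscillation criterion. Sham controls are included by definition: the rule
screens stimulated animals for a response, and applying it to controls
would empty the control arm. The generator's responder flag is never read
by the rule — inclusion is re-derived from the analyzed evidence, and the
test suite checks the two agree.

## Group statistics

The percent changes of included animals form a long table (animal × window
× channel, baseline excluded since it is identically zero). Per channel,
a two-way crossed ANOVA on group × window is computed from the closed-form
balanced decomposition — factor and interaction sums of squares from cell
and marginal means, F as factor mean square over residual mean square, p
from the upper tail of the F distribution. The decomposition is verified
against an independent nested least-squares oracle (RSS differences of
`lm` fits) to 1e-8 over randomized balanced tables. Design decisions:

* the ANOVA is ordinary (between-subject); a repeated-measures treatment of
  the window factor is out of scope, and the within-animal correlation
  across windows is a known limitation of the default report;
* unbalanced designs (the usual outcome of exclusions) are a hard error
  with guidance to equalize group sizes, rather than a silent switch to a
  different sums-of-squares type;
* a cohort with one animal per group fails cleanly (no residual degrees of
  freedom).

Pairwise contrasts compare group means within each window using the pooled
residual mean square on the residual degrees of freedom, Šidák-adjusted
over the full family (windows × group pairs):
$p_\mathrm{adj} = 1 - (1-p)^m$, computed via `expm1`/`log1p` so the
adjusted value never dips below the raw one through floating-point
cancellation. Adjusted p values are classified at 0.05 (significant) and
0.1 (tendency). With a single pair and five windows the effective
per-comparison level is ≈0.0102, so the null rejection rate of the
Stimulation-window contrast is conservative by construction; the test suite
measures it over 500 two-sham-group replicates.

## What the simulator does and does not emulate

It reproduces the *statistical structure* the analysis consumes: group-mean
effect sizes with across-animal spread, the delay distribution of the rapid
CBF drop, stimulus-locked oscillations, post-stimulation recovery
asymmetries, anesthesia drift, white measurement noise, and non-responding
animals. It does not attempt pulsatile pressure waveforms (MAP and HR are
separate smooth channels), respiratory or cardiac artifacts, colored noise,
baroreflex mechanisms (the model is phenomenological, not an ODE of the
Bezold–Jarisch loop), or behavior. Passing parameter-recovery tests
therefore shows the pipeline is unbiased and the detector correct under
realistic signal geometry — not that the biology is as modeled; with real
recordings, colored noise and artifacts would mainly stress the baseline-SD
estimate and the smoothing half-width, which are the knobs to revisit
first.

Two reported quantities are deliberately not targets: baseline MAP/HR
values (never reported for these animals; the defaults are labeled
synthetic conventions) and the single-session CBF drop of a representative
figure.

## Problem sizes and numerical conventions

The test suite simulates 200 sessions per stimulated preset for
parameter-recovery checks (recovery asserted within 3 Monte-Carlo standard
errors), 200 sham sessions for the false-positive bound, 500 two-group null
replicates at 2 Hz for the type-I error of the pairwise test (window means
and the ANOVA are invariant to the sampling rate), and 100 randomized
balanced tables for the ANOVA oracle. The acceptance script
(`scripts/acceptance.R`) uses 400 sessions per preset. Seeds are always
explicit: sessions are deterministic given their seed, cohorts derive
per-animal seeds from a master seed, and the full pipeline writes
byte-identical CSVs on repeated runs of the same configuration.
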