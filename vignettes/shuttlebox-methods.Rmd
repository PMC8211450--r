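---
title: "Methods: photometry and behavior quantification in shuttle-box learned helplessness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry and behavior quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuttlebox)
library(dplyr)
```

## The problem

In the learned-helplessness (LH) shuttle-box paradigm an animal can escape an
escapable foot shock by crossing to the other compartment; after repeated
inescapable shocks it increasingly fails to do so, and a single low dose of
ketamine restores escape behavior. Fiber photometry of a calcium indicator in
VTA dopamine neurons shows outcome-specific responses: failure trials carry a
biphasic transient (fluorescence dips during the shock and rebounds after),
escape trials a monophasic rise. LH damps the failure-specific lobes and
ketamine restores them, and how well a subject's dopamine signal
discriminates the two outcomes at baseline predicts later behavior.

This package implements the quantification chain for such experiments —
dF/F normalization, event alignment, transient metrics, the trace-distance
statistic, behavioral transition models and learning curves, motion-bout
detection, and Welch spectral summaries — together with a synthetic cohort
generator whose ground truth makes every stage testable by parameter
recovery. Group-level hypothesis tests (ANOVA families, post-hoc
corrections) are out of scope; standard R tools apply directly to the tidy
outputs.

## Preprocessing model

Raw fluorescence is normalized in non-overlapping windows (default
`window_s = 100` s) as $(F - \mathrm{median}\,F)/\mathrm{median}\,F$ per
window. Two consequences are used as exact test invariants: the median of
every full window of the output is zero, and the output is invariant to
rescaling the raw signal by any positive constant. A final partial window
uses its own median rather than extrapolating the previous one, keeping the
formula local; a signal shorter than one window degenerates to a
whole-signal median. Window medians must be positive — a non-positive median
aborts with the window index rather than silently producing unusable dF/F.
No isosbestic correction or bleaching fit is applied; the windowed median is
the only baseline model.

Decimation is by block means at an integer factor (1000 → 250 Hz for
time-locked work, → 10 Hz for session summaries, by default). Block
averaging is deterministic, preserves the mean exactly, and its frequency
response is the closed-form boxcar (Dirichlet) gain, which the tests verify
against a 5-Hz sinusoid. Filtered polyphase resampling was deliberately not
used: the decimation factor is always integer here and an invertible,
exactly testable operation is worth more than a flatter passband.

Alignment cuts the half-open window $[-\mathrm{pre}, +\mathrm{post})$
(defaults 5 and 8 s) around each shock onset at the time-locked rate, the
onset sample belonging to the post side. Trials whose window leaves the
recording are excluded, warned about, and recorded in the result. The grid
convention makes trial lengths unambiguous: every row has exactly
$(\mathrm{pre}+\mathrm{post}) \cdot f_s$ samples.

## Transient metrics

The baseline of each aligned trial is the mean (and SD) of the 5 s before
onset. Peaks are extrema relative to that baseline mean, in a *during*
window $[0, d]$ and an *after* window $(d, 8]$ s. For failures $d$ is the
full shock duration; for escapes the shock terminates at the shuttle, so $d$
is the recorded escape latency. A peak is omitted when its amplitude is
below 5% of the trace's min-to-max range **or** below three baseline SDs;
both thresholds, both signs and both windows are checked against a
brute-force oracle on randomized traces in the tests. The 5%-of-range rule
is applied per aligned trace (not per session) — the per-trace reading
matches how the rule is used trial by trial, and the choice is recorded
here because the alternative is defensible. Latency to peak is the time of
the maximum within 8 s of onset, earliest sample on ties. AUC is the
trapezoidal integral of the baseline-subtracted trace's positive and
negative parts separately, so `auc_pos + auc_neg` is the net integral by
construction.

The trace distance
$D = \lVert \bar{x}_{\text{escape}} - \bar{x}_{\text{failure}} \rVert_2$
is computed sample-wise on the full aligned window at the time-locked rate,
without normalizing by sample count — the grid and rate are fixed
pipeline-wide, so distances are comparable across subjects and conditions
(a `window` argument restricts the range when wanted). $D$ is a metric on
mean-trace pairs; symmetry, translation invariance and the triangle
inequality are property-tested.

## Behavior

Failure percentage excludes spontaneous (pre-shock) crossings from the
denominator: they are neither escapes nor failures of the shock trial. Mean
escape latency scores failures at the cap (the shock duration: 10 s strong
paradigm, 3 s weak). Learning curves start at zero and move +1/−1/0 for
escape/failure/spontaneous.

Transition models count the nine ordered outcome pairs pooled across
animals — never across animal or session boundaries — and normalize each row
by that state's outgoing transitions, which keeps rows stochastic. The
normalization denominator is genuinely ambiguous (dividing by total state
occurrences counts each animal's terminal trial too); both variants are
computed, `probs` being the stochastic one and `probs_by_occurrence` kept
alongside for comparison — at cohort scale they differ by at most one count
per animal per state. Model similarity is $1 - \lVert T_a - T_b\rVert_F$,
symmetric, 1 for identical models, and deliberately unclipped (it can go
negative for very different models). Undefined rows make similarity an
error, not a silent NA.

The Gaussian fit to per-animal failure percentages is the closed-form
maximum-likelihood Normal fit ($\hat\mu$ the sample mean, $\hat\sigma$ with
denominator $n$) on the raw values; the bin-width-4 histogram on [0, 100]
is display-only and never enters the fit. A test cross-checks the estimates
against an independent distribution-fitting routine.

## Locomotion and spectra

Speed is a central difference (one-sided at the ends) with optional 5-frame
running-median smoothing — tracking jitter at 30 fps otherwise fragments
bouts; smoothing is configurable off, and whether to smooth before
thresholding is a genuine open choice recorded here. A motion bout is a
maximal run of frames above 30 mm/s whose length (frames × frame period) is
at least 0.5 s; onset is the first supra-threshold frame and offset the
last, the offset rule chosen symmetric to the stated onset rule. Detection
is monotone in the threshold and equals a brute-force interval scanner on
random series.

The Welch estimator averages Hann-windowed, 50%-overlapping, mean-removed
segment periodograms, scaled as one-sided density (power per Hz). Segment
length defaults to 256 samples — about 21 s at the 12-Hz ex vivo frame
rate, giving ~0.047 Hz resolution around the ~1 Hz oscillations of
interest — and is configurable since no single value is canonical. The
max-power search excludes the DC bin: baseline-adjusted traces retain
residual offsets that would otherwise always win. Tests pin frequency
recovery to within one bin across 0.2–5 Hz, quadratic power scaling, and a
Parseval check on white noise.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. Its defaults are
the weak-paradigm study conditions: three phases (baseline, LH, LH+KET),
100 escapable 3-s shocks per session with random 5–15 s inter-shock
intervals, 1 kHz acquisition analyzed time-locked at 250 Hz, and
condition-level transition matrices whose stationary failure fractions sit
near 25% / 60% / 35% across the three phases. Escape latencies are drawn
uniform on (0.3 s, shock duration) — the empirical latency distribution is
not pinned down beyond its mean, so a simple stand-in is used and flagged
here; failures are scored at the cap; spontaneous trials carry no
shock-locked transient.

Transient templates are raised-cosine (Hann-shaped) lobes with compact
support: a negative lobe inside the shock window plus a positive rebound
after offset for failures, a single positive lobe for escapes. Compact
support was chosen over Gaussian lobes because Gaussian tails overlap
between the two failure lobes, so configured amplitudes would no longer be
the exact extrema; raised cosines keep peak = amplitude exactly and have
analytic area (amplitude × half-width), which the AUC tests use. The raw
signal model is $F(t) = B(1 + \text{templates} + \varepsilon) + \text{drift}$
with baseline level $B$, dF/F-scale Gaussian noise $\varepsilon$ and a slow
sinusoidal drift. Because templates occupy well under half of any 100-s
window, the window median is exactly $B$ in the noise-free case, making the
dF/F step exactly invertible — the basis of the template-recovery tests.
Trial onsets are quantized to the time-locked grid so decimated aligned
windows sit in phase with the embedded templates.

Individual variability enters through a per-subject gain, uniform on
[0.5, 1.5], scaling the failure-template lobes; the subject's true baseline
trace distance follows analytically (templates laid down at the acquisition
rate and block-mean decimated, exactly as the measurement path does). The
distance-to-behavior coupling shifts each subject's LH-phase stationary
failure fraction linearly in their true distance
(`coupling_slope`, fraction per unit distance, negative by default:
larger baseline separation → fewer failures). The shift is applied by
root-solving for the row perturbation whose chain has exactly the target
stationary fraction, so the designed slope holds on the same scale the
pipeline measures. `coupling_for_target_r2()` inverts the designed
signal-to-noise ratio (slope² × distance variance against binomial trial
noise) to hit a requested R². Randomness uses per-subject substreams derived
from the master seed, so adding a subject never perturbs existing ones, and
every output is a pure function of (config, seed).

What the generator does **not** emulate: spike-to-fluorescence biophysics,
hemodynamic or movement artifacts, sensor bleaching beyond slow drift,
session-to-session nonstationarity, and latency-dependent transient timing
on escape trials. Passing recovery tests therefore demonstrates the
correctness of the measurement chain under the stated signal model, not
robustness to every artifact of real recordings.

## Problem sizes and numerical choices

Tests and the acceptance script run scaled-down cohorts chosen to keep the
statistical targets meaningful: estimator-consistency checks use 10,000
transitions; the end-to-end recovery experiment uses 50 subjects × 40 trials
at 50 Hz acquisition (25 Hz time-locked) over 20 seeds, with noise SD 0.02
dF/F and drift amplitude 0.5 — at these sizes the designed R² ≈ 0.7 carries
binomial noise comparable to the coupling signal, which is exactly the
regime worth testing. The acceptance script's cohort uses the full
100-trial, 12-subject structure at 100 Hz acquisition. Tolerances mirror
the underlying arithmetic: dF/F identities at 1e-12, template inversion at
1e-6 (accumulated float error through normalization and decimation), AUC
closed forms at 1%, frequency recovery at one spectral bin.

Degenerate inputs are defined, not guessed at: flat traces omit all peaks
with reason "zero range"; outcomes with no trials yield flagged-missing
means and distances; empty transition rows stay NA and block similarity
with an informative error; zero-variance correlation inputs warn and return
NA; empty bout schedules and zero-trial alignments return empty,
well-formed objects.

## Known limitations

Escape-trial templates do not shift with the escape latency, so
latency-to-peak distributions on synthetic escapes are narrower than real
ones. The uniform escape-latency model is a placeholder. The designed-R²
calculation treats trial outcomes as exchangeable within a session, which
slightly understates noise for strongly persistent chains. Transition-model
pooling weights animals by trial count, as the pooled-count definition
implies — per-animal models can be built by passing single sequences and
compared explicitly.
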