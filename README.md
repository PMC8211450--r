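# shuttlebox

Quantification of ventral-tegmental-area (VTA) dopamine fiber-photometry
signals and escape behavior in shuttle-box learned-helplessness (LH)
experiments, with a synthetic cohort generator carrying full ground truth so
the whole pipeline can be validated by parameter recovery.

## Who this is for

Behavioral neuroscientists analyzing calcium-indicator photometry recorded
during aversive learning: trials in which an animal either escapes an
escapable foot shock, fails to escape, or shuttles spontaneously before the
shock. The package covers the full analysis path from raw fluorescence to
cohort-level statistics, and every stage is exercised end-to-end on simulated
cohorts with known parameters.

## What it computes

**Photometry preprocessing.** Raw fluorescence is baseline-adjusted in
non-overlapping 100-s windows as dF/F = (F − median(F)) / median(F), then
block-mean decimated (1 kHz acquisition, 250 Hz for time-locked and 10 Hz
for non-time-locked analyses by default). Segments are aligned to shock
onset on a half-open [−5 s, +8 s) grid.

**Transient metrics.** Per trial: signed peaks relative to the 5-s pre-shock
baseline mean, measured *during* the shock (for escapes the window ends at
the recorded escape, since the shock terminates at the shuttle) and *after*
it; trapezoidal positive/negative AUC; latency to peak within 8 s of onset.
A peak is omitted when its amplitude is below 5% of the trace's min-to-max
range or below 3 baseline standard deviations.

**Trace distance.** For each subject, the Euclidean norm of the difference
between the mean escape-trial and mean failure-trial traces,

&nbsp;&nbsp;&nbsp;&nbsp;D = ‖ mean(escape trials) − mean(failure trials) ‖₂,

an amplitude- and kinetics-agnostic measure of how well the dopamine signal
discriminates trial outcomes.

**Behavior.** Failure percentages (failures / (failures + escapes)) and
escape latencies with failures scored at the shock-duration cap; cumulative
learning curves (+1 escape, −1 failure, 0 spontaneous); three-state
transition models T (3×3 row-stochastic over escape/failure/spontaneous,
counts pooled across animals) with similarity 1 − ‖T₁ − T₂‖_F; run-length
statistics; maximum-likelihood Gaussian fits to cohort failure-percentage
histograms (bin width 4).

**Locomotion.** Body-center speed from tracked positions; motion bouts as
maximal intervals with speed > 30 mm/s lasting ≥ 0.5 s; distance per minute;
photometry aligned to motion onsets/offsets.

**Spectral.** Welch power spectral density (Hann window, 50% overlap) for
spontaneous calcium traces, summarized by max power and frequency at max
power, with paired before/after deltas.

**Cohort statistics.** Pearson correlations between per-subject trace
distance and failure percentage, and `recovery_experiment()`, which designs
a cohort with a known distance-to-behavior coupling, runs the entire
measurement pipeline, and compares recovered slope and R² to the design.

## Worked example

```r
library(shuttlebox)
library(dplyr)

cfg <- cohort_config(n_subjects = 4, trials_per_session = 50,
                     sample_rate_hz = 100, timelocked_rate_hz = 25, seed = 7)
cohort <- simulate_cohort(cfg)

failure_stats(group_by(cohort$trials, condition))
#> # A tibble: 3 × 6
#>   condition n_escape n_failure n_spontaneous pct_failures mean_latency_s
#> 1 LH              73       117            10         61.6           2.49
#> 2 LH+KET         118        74             8         38.5           2.12
#> 3 baseline       132        58            10         30.5           2.06

cohort_trace_distances(cohort) |>
  group_by(condition) |> summarise(mean_distance = mean(trace_distance))
#> 1 LH                 2.24
#> 2 LH+KET             3.25
#> 3 baseline           3.62
```

Failure rates rise under LH and partially recover after the ketamine-like
condition, and the escape-vs-failure trace distance is damped by LH and
restored afterwards — the cohort generator builds in exactly these effects,
and the pipeline measures them back out.

```r
m_base <- transition_model(filter(cohort$trials, condition == "baseline"))
m_lh   <- transition_model(filter(cohort$trials, condition == "LH"))
m_ket  <- transition_model(filter(cohort$trials, condition == "LH+KET"))
model_similarity(m_base, m_lh)   #> 0.372
model_similarity(m_base, m_ket)  #> 0.645  (post-ketamine closer to baseline)

glance(welch_psd(simulate_oscillation(1, 300, 12, noise_sd = 0.3, seed = 7)))
#>   max_power freq_at_max_power_hz ...
#> 1      5.98                0.984
```

Result objects have `tidy()`/`glance()` methods and `autoplot()`s
(aligned traces, outcome means, transition models, PSDs, failure-histogram
fits), and `run_pipeline()` executes the whole chain, writing CSV/JSON
reports plus a checksummed `manifest.json`.

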