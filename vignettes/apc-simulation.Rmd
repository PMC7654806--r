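---
title: "Simulating a gravity-fed optical larva counter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a gravity-fed optical larva counter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcsim)
```

## The system being modelled

Automated particle counters for mosquito mass rearing dispense a target
number of first-instar (L1) larvae by letting a stirred suspension flow by
gravity from a feed reservoir, through a pinch valve, down a narrow glass
capillary (1 mm internal diameter) past an optical sensor. Each larva
occludes part of the light beam; an on-board algorithm turns the sampled
light-intensity series into counts in real time, and the valve closes when
the count reaches the target. `apcsim` is a desk-scale simulator of that
whole loop plus the statistics used to characterise its accuracy (mean
percent deviation of the number dispensed from the target) and precision
(the dispersion of dispensed counts).

## Hydraulics

Gravity flow depends on the water-column height (head) above the outlet.
The two calibration points measured on the physical device — 0.48 ml/s at
the 24 cm "low" mark and 0.77 ml/s at the 31 cm "high" mark — are
inconsistent with both a Torricelli $\sqrt{h}$ law and a pure Poiseuille
$\propto h$ law (tubing losses and the pinch-valve constriction dominate),
so `flow_rate()` makes no mechanistic claim: it interpolates piecewise
linearly through whatever calibration points are supplied, extrapolates
linearly past the endpoints, and clamps at zero. Users with more calibration
points simply pass a longer `flow_calibration()`.

Particle speed uses the plug-flow mean velocity $v = Q/A$. In a 1 mm tube,
hydrodynamic focusing concentrates larvae in the faster central flow and the
mean velocity reproduces the device's observed transit speed:

```{r}
v <- stream_velocity(flow_rate(31, flow_calibration()), 1.0)
v                      # ~980 mm/s
transit_time(2, v)     # a 2 mm sensor window is "visible" for ~2 msec
```

The reservoir cross-section default (100/7 ≈ 14.3 cm²) is inferred from the
calibration protocol itself: the 100 ml added to reach the high mark spans
the 7 cm between the high (31 cm) and low (24 cm) levels. It only matters in
depletion mode, where `drain_step()` integrates the drawdown explicitly at
the sensor sampling interval — head moves so slowly relative to a 2 msec
pulse that no stiff integrator is warranted.

## The synthetic sensor trace

`generate_arrivals()` draws larva arrivals as a Poisson process. A
motor-stirred suspension is as close to a well-mixed point process as
laboratory equipment gets, and Poisson arrivals are the natural null model;
`mode = "depletion"` couples the instantaneous rate to the declining flow
(concentration stays fixed, flow falls) for runs where the reservoir is not
topped up. The routine operating condition — reservoir held near the high
mark — is `mode = "fixed"`.

`synthesize_trace()` builds

$$ y(t) = \text{baseline} + \text{drift}\cdot t + \varepsilon(t) -
   \sum_i \text{pulse}_i(t), \qquad \varepsilon \sim N(0, \sigma^2), $$

clipped below at zero (full occlusion). Choices that matter:

* **Pulse shape.** Each larva contributes a rectangular dip of depth equal
  to its amplitude and duration $(\text{window} + \text{body})/v$ — about
  3 ms, i.e. ~30 samples at the default 10 samples/msec. Diagnostic-mode
  traces from the physical device show near-rectangular below-baseline
  peaks, and at ~30 samples per transit nothing finer is resolvable. A
  1-sample half-amplitude ramp is available (`ramp = TRUE`).
* **Sampling rate.** 10 samples per msec (10 kHz), the device's measurement
  interval; this makes sensor response time a non-factor, as on the device.
* **Amplitudes.** Truncated normal, mean 100, sd 20, floor 10 intensity
  units. Pulse heights are not published for the device; these defaults put
  the routine thresholds (z = 2.5–6 on a noise sd of 6) deep in the
  clean-detection regime while z = 7–8 (absolute threshold ≈ 42–48 units)
  begins to clip the weak tail of the amplitude distribution — the
  qualitative pattern reported for the device.
* **Noise.** Gaussian, default sd 6, well inside the device's calibration
  rule (baseline sd < 18, checked by `is_calibrated()`).
* **Contaminants.** Food particles, eggshell fragments and electronic
  spikes are short (0.4 msec) dips with exponentially distributed amplitude
  (mean 20) at a configurable rate (default 2 events/s), standing for the
  residue that survives careful hatching and decanting.
* **Seeding.** One root seed per run; sub-seeds for arrivals, amplitudes,
  contaminants and noise are derived arithmetically so each component is
  independently reproducible.

What the generator deliberately does not emulate: larvae are points (no
excluded volume, so arbitrarily close arrivals are possible), occlusion
profiles are flat rather than tapered, and amplitude is independent of flow.
Passing tests therefore demonstrate the correctness of the counting logic
and the closed loop under a clean, known ground truth — not sensor physics.

## The three counting algorithms

All detectors work on the occlusion deviation (baseline − sample), so
"above threshold" means deeper occlusion.

**Smoothed z-score** (`smoothed_zscore_count()`), the algorithm of interest:
a moving-window mean and SD over the last `lag` samples (default 500 = 50
msec: long against a 2 msec pulse, short against drift) define an adaptive
baseline; a sample is flagged when its deviation exceeds `z_start` baseline
SDs; a count fires after `n_above` (default 3) consecutive flagged samples.
Flagged samples enter the baseline with weight `influence` (default 0, so a
passing larva cannot inflate the baseline SD — the adaptation is meant for
slow changes in water absorbance). The SD is floored at $10^{-6}$ so z
stays computable on noiseless synthetic traces, and the first `lag` samples
are warm-up, mirroring the device's calibration before dispensing.

After a count the detector disarms; the *re-arm rule* is what separates
larvae passing in close succession. Two rules are supported:

* `decline_amount` (default, 50 units = half the default pulse amplitude):
  re-arm when the deviation has dropped by that much from its running peak
  since the count.
* `n_decline`: re-arm after that many consecutive declining deviations.

The default is the drop rule, and deliberately so: with any continuous
noise, a run of $k$ strictly declining samples occurs with scale-free
probability $1/(k+1)!$ per position, so a 30-sample pulse plateau would
re-arm (and double-count a single larva) about once per pulse at
`n_decline = 3` no matter how quiet the sensor. An absolute drop of half a
pulse height is essentially unreachable by noise alone yet is produced
immediately when one larva of a cluster clears the window, so genuinely
clustered individuals still register individually. `n_above = 3` and the
50-unit drop are unpublished device settings; they are surfaced in the
configuration and documented as assumptions.

**Threshold reset** (`threshold_reset_count()`): a fixed deviation
threshold; count after `n_above` consecutive samples above it, re-arm only
after `n_below` consecutive samples below it. **Refractory period**
(`refractory_count()`): count at each upward threshold crossing, ignoring
crossings within `refractory` msec of the last count. Both are intended for
well-separated particles and merge overlapping ones — which is why the
z-score variant exists.

Every algorithm has a non-streaming brute-force twin behind
`offline_oracle_count()`, written independently (full-window `mean()`/`sd()`
recomputation, run-length encoding), and the test suite holds the streaming
and offline counts equal on more than a thousand randomized traces.

Edge conventions: a pulse truncated by the end of the trace still counts
once `n_above` is satisfied (counts fire on the `n_above`-th flagged sample,
not at pulse end); ties in the comparison are broken strictly (`>`), so a
deviation exactly at threshold does not flag.

## The closed dispensing loop

`run_dispense()` runs arrivals → trace → detector until the count reaches
the target, closes the (upstream) valve after an optional `closure_lag`, and
then resolves the book-keeping. Because ~1.5 cm of capillary extends below
the sensor, larvae within `dead_length` of the sensor at stoppage have been
*counted but not dispensed* (`residual_out`); a following run flushes them
out *dispensed but not counted* (`carryover_in`). `run_chain()` threads this
between consecutive runs, and conservation
(`dispensed = counted − residual_out + carryover_in` under perfect
detection) is enforced by tests, per run and telescoped over chains.

Under instantaneous closure the expected dead-segment occupancy is
`residual_below_sensor()` = rate × transit time (≈ 0.38 larvae at 25 LPS)
*plus the larva that triggered the final count*, which is still at the
sensor when the valve shuts — the simulator realizes ≈ 1.2–1.4 residual
larvae per run at 25 LPS, which is also where direct observation of the
physical device puts it. `closure_lag` (default 0) is exposed for users who
want to model a decelerating pinch valve.

The loop reproduces both failure directions of a real counter: a threshold
too high to catch weak pulses under-counts, so the controller keeps the
valve open too long and *over*-dispenses; contaminant-triggered counts
inflate the tally and *under*-dispense. At the routine threshold (z = 3.5)
with contaminants enabled the simulated mean error is a few percent
negative, the same sign and magnitude class as reported for the device
(−2 to −3%).

## Evaluation statistics

`summarize_runs()` reports mean percent error with a t-based 95% CI of the
mean, the integer mode (all tied maxima — ties are real on synthetic data),
the proportions within ±2 and ±5 of the target, a Shapiro-Wilk normality p
(`stats::shapiro.test`), and the skew direction. With a single run the
interval statistics are `NA`, never fabricated.

`zscore_anova()` runs the one-way ANOVA either from raw values (via
`stats::aov`) or from published-style group summaries (n, mean, 95% CI
half-width). In the summary route the within-group variance is recovered as
`sd = ci · √n / crit`; `crit` defaults to the t quantile, matching this
package's own CI convention, with `ci_quantile = "normal"` for summaries
produced with the normal quantile, as spreadsheet `CONFIDENCE`-style tables
are. Recovering a published nine-group table this way reproduces its
between-group SS to < 0.1% (limited only by the table's rounding) and its
within-group SS to < 0.02% under the normal convention.

"Tukey HSD with a Bonferroni correction" is a common but ambiguous
prescription, since HSD already controls the family-wise rate. It is
implemented literally — studentized-range p-values judged at
`alpha / n_pairs` — with plain HSD behind `bonferroni = FALSE`. On the
recovered nine-group table, plain HSD reproduces the published letter
pattern exactly (thresholds 2.5–6 share a letter; 7 and 8 form a second
group); under the Bonferroni tightening one borderline pair (6 vs 8,
p ≈ 0.004) loses significance and the borderline group picks up both
letters. Compact letters come from maximal contiguous blocks of mutually
non-different groups in mean order.

`lps_accuracy_correlation()` (Pearson, via `stats::cor.test`),
`two_sample_ttest()` (pooled or Welch from summary statistics),
`z_error_probability()` (two-sided Gaussian tail; 0.00047 at z = 3.5, i.e.
one random trigger per ~2100 samples) and the percent calculators round out
the published worked examples. Display rounding (integer percent headlines,
one-decimal rates) is always separated from the stored full-precision value.

## Run logs, diagnostics, CLI

Run logs and diagnostic traces are comma-delimited UTF-8 with a versioned
marker line; readers reject other major versions and report the line and
field of any malformed value. Doubles are written with 17 significant
digits so `read_runlog(write_runlog(x))` is lossless and re-writing is
byte-identical. `inst/cli/apc.R` is a thin Rscript over the exported
functions with `simulate`, `dispense`, `evaluate`, `physics` and `demo`
subcommands; given the same seed and flags its outputs are byte-identical,
which is why logs carry no wall-clock timestamps — runs are identified by
seed and a config hash instead.

## Problem sizes and numerical choices

The shipped tests use traces of 10³–10⁵ samples, dispensing chains of
12–80 runs at targets of 30–100, and ~1300 randomized traces for the
streaming/offline equivalence property — sizes chosen so the full suite
exercises every regime (clean detection, clustering, contamination,
depletion) in about a minute on one core. Moving-window statistics use
running sums (cancellation is harmless here: intensities ~600, variances
~36, double precision leaves ~10 guard digits); the offline oracle
deliberately recomputes them naively instead. Degenerate inputs are pinned
by tests: zero flow, empty traces, single runs, zero-variance correlations,
constant groups.

## Known limitations

* Point larvae: no excluded volume, so clustering (and hence merged counts)
  is slightly overestimated at high LPS relative to physical larvae that
  cannot overlap.
* Rectangular occlusion: no partial-occlusion taper at the window edges.
* Depletion mode synthesizes the trace at the run's initial velocity;
  within-run velocity decline affects arrival times only.
* The statistics module recovers within-group variance from summaries
  exactly only when the summaries' quantile convention is known; both
  conventions are exposed.
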