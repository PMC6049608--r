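---
title: "Estimating silent synapses from minimal-stimulation recordings: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating silent synapses from minimal-stimulation recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minstim)
```

## The question and the model

Glutamatergic synapses can be *silent*: they carry NMDA receptors but no
functional AMPA receptors, so they transmit at a depolarized holding
potential (+40 mV, where the NMDA-receptor Mg²⁺ block is relieved) but not
at a hyperpolarized one (−60 mV). An excess of silent synapses depresses
basal transmission while leaving a large reservoir for potentiation, which
is why the silent fraction is a key quantity when dissecting synaptic
maturation phenotypes.

Minimal stimulation probes one or a few synapses with stimuli weak enough
that transmission fails on a sizable fraction of trials. `minstim` models
release per trial as a single Poisson count,

$$P(k) = \frac{m^k e^{-m}}{k!},$$

with $m$ the mean quantal content. The failure rate is then
$r_f = P(0) = e^{-m}$, so $m = -\ln r_f$. If a fraction $s$ of the
stimulated synapses is silent and silent and functional synapses share the
same per-synapse release behaviour, the quantal content at −60 mV counts
only the functional synapses, $m_{-60} = m_{+40}(1 - s)$, giving the
estimator implemented in `silent_fraction_estimate()`:

$$\hat s = 1 - \frac{\ln r_{f,-60}}{\ln r_{f,+40}}.$$

The shared-release-probability assumption is what makes the estimator
exact under the generative model; it is untestable from failure rates
alone and is stated here as a model assumption, not a finding. A
site-level binomial model is deliberately not offered: the collapsed
Poisson count *is* the analysis model, and its generative inverse is what
the simulator produces, so the estimator/simulator pair is exactly
self-consistent (a property the test suite checks on a grid of $m$ and
$s$ to machine precision).

The estimator can return negative values when sampling noise makes
$r_{f,-60} < r_{f,+40}$. These are flagged (`sampling_noise_flag`) and
never clipped, so group averages are not biased upward.

### Worked example

The package carries one worked example as a permanent cross-check
(`worked_example_check()`): applying the estimator to the published
knockout group-mean failure rates (36.3% at −60 mV, 12.7% at +40 mV) gives
$1 - \ln(0.363)/\ln(0.127) = 0.509$, i.e. the published ~51%, and the
wild-type means (16.3%, 13.2%) give 10.4%, within a percentage point of
the published ~11% (the printed inputs are rounded to one decimal; whether
the published wild-type figure came from group-mean rates or averaged
per-cell estimates is not recorded, and both aggregations are therefore
reported by `run_pipeline()`).

## Synaptic potency and the quantal size

The apparent synaptic potency $S$ is the mean amplitude of trials that
qualified as successes. Two relationships between potency, failure rate
and the mean quantal size $q$ are implemented in `fit_quantal_size()`, and
both are always computed:

* **paper variant**: $S = -\ln(r_f)\, q = m q$. This is the conventional
  fitting form; under the Poisson model $mq$ is the mean response over
  *all* trials, not over successes only.
* **corrected variant**: $S = -\ln(r_f)\, q / (1 - r_f) =
  q\,E[k \mid k \ge 1]$, the conditional mean over successes, which
  matches the definition of potency. Parameter-recovery tests use this
  variant; it recovers the simulator's $q$ without the systematic
  underestimate the paper variant incurs on success-conditioned data.

Both variants are linear in $q$ given $r_f$, so the fit is least squares
through the origin with a $t$-based confidence interval; requiring at
least three experiments keeps the residual degrees of freedom positive.

## Detection conventions

`classify_failures()` turns sweeps into an event table under the following
conventions (constants in `detection_params()`):

* **Units and windows.** Currents are stored as recorded, inward negative.
  Sample 0 is the sweep start, stimulus time is in ms from sweep start,
  and every analysis window is half-open $[a, b)$.
* **Noise** is the SD of the signal in a 3-ms window averaged over all
  sweeps at a holding potential. The window placement is not part of the
  convention; it is placed pre-stimulus, ending 1 ms before the stimulus,
  so the artifact cannot contaminate it.
* **Charge** (depolarized failures) is the baseline-subtracted Riemann sum
  over the 5–40 ms post-stimulus window, in pC. A sweep at +40 mV is a
  failure when its charge *does not exceed* the threshold — equality is a
  failure, taking the wording literally. The conventional printed
  threshold of 0.9 pC presupposes compound responses much larger than the
  printed quantal sizes (a 4.4 pA quantum carries only ~0.14 pC over this
  window); the package honours 0.9 pC as the default but exposes
  `suggest_charge_threshold()`, half the analytic single-quantum charge,
  for internally consistent simulated-scale analyses.
* **Peaks** (hyperpolarized failures and potencies) are measured after
  subtracting the average-failure template, which removes the stimulus
  artifact. Two measurement details are the package's own: the artifact
  interval is blanked to the baseline before smoothing, and the trace is
  smoothed with a light boxcar (default 1 ms) before taking the extremum.
  The boxcar matters quantitatively: the raw single-sample extremum of
  band-limited noise over a 9-ms search window carries an extreme-value
  bias comparable to twice the noise SD, which would defeat the
  "peak smaller than twice the signal noise" failure criterion; after a
  1-ms boxcar the noise extremum drops well below the criterion while a
  fast EPSC peak (rise 1 ms / decay 8 ms) loses under 1% of its
  amplitude. A sweep at −60 mV is a failure when the smoothed peak
  magnitude is *smaller than* twice the noise SD — equality is a success.
* **Template circularity.** The average failure is needed to measure the
  peaks that define failures. The classification therefore iterates:
  peaks are first measured on raw (blanked, smoothed) traces, the average
  failure is formed, peaks are re-measured on template-subtracted traces
  and sweeps reclassified, to a fixed point (at most 5 rounds; in
  practice it converges in 2).
* **The +40 mV amplitude** is read 25 ms after stimulation on the
  (smoothed, baseline-subtracted) trace, where the slow NMDA-receptor
  component dominates; with the default slow kinetics (rise 5 ms, decay
  60 ms) the waveform still carries ~89% of its peak there. This read
  convention, not a peak, is also what enters the +40 mV potency, so the
  fitted $q_{\mathrm{NMDA}}$ is expected to sit ~11% below the generative
  amplitude — well inside the 15% recovery tolerance the tests enforce,
  and consistent between groups, which is what the between-genotype
  comparison needs.

## Quality control

Experiments with run-up or run-down (linearly trending failure rates or
success amplitudes at either potential) or with high background noise are
excluded. `qc_experiment()` implements the trend screen as OLS slope
$t$-tests of (i) success amplitude and (ii) the failure indicator against
acquisition order, at each potential — up to four tests. Two design
choices keep the screen calibrated:

* the per-test level is Bonferroni-corrected, so the whole screen
  operates at the experiment-wise level `trend_alpha` (default 0.05);
* a statistically significant trend is only acted on when its fitted
  magnitude is practically relevant: a total change of at least 0.25 in
  failure probability, or 25% in relative amplitude, across the
  recording. At the sizes used for calibration (300 sweeps/potential)
  these floors sit around 3 standard errors of the fitted change under
  stationarity, so the expected stationary pass rate is ~99% — safely
  above the 95% the calibration tests demand — while a run-down that
  halves release is detected essentially always. Both floors were set by
  this a-priori power calculation, before the calibration tests were run.

With fewer than 10 sweeps at a tested potential the verdict is
`indeterminate`, never a silent pass. The acquisition-time guideline that
failures at +40 mV should occur in roughly 10–40% of events is treated as
an acquisition target, not a post-hoc exclusion. The noise ceiling
(`max_noise_sd`, default 3 pA) has no printed conventional value; the
default is matched to the simulator's 2 pA noise scale and must be chosen
per dataset for recorded data.

## The simulator and what it does (not) emulate

`simulate_minstim_experiment()` is the generative inverse of the analysis
model. Its defaults are the study conditions: 40 sweeps per potential
(the 20–50-event acquisition range), $m_{\mathrm{total}} = 1.6$ (placing
the +40 mV failure fraction at $e^{-1.6} \approx 20\%$, inside the 10–40%
target), quantal amplitudes 4.4 pA (slow component) and 9.7 pA (fast
component magnitude), quantal CV 0.3 (truncated-normal multiplier, kept
sign-consistent; no conventional value exists for the CV), kinetics
1/8 ms (fast) and 5/60 ms (slow), 2 pA Gaussian noise, 5 kHz sampling,
a 1-ms biphasic artifact, and a 1-ms synaptic onset latency.
`silent_fraction` defaults to 0 so that simulating the phenomenon is
always an explicit choice. The optional `drift_slope` ramps release
linearly across the recording for QC testing.

The simulator emulates exactly what the estimators assume — Poisson
counts, synchronous quanta scaling a fixed waveform, stationary white
noise — plus the artifact and optional drift. It does *not* emulate
latency jitter, asynchronous release, short-term plasticity, Mg²⁺-block
voltage dependence, electrode/series-resistance artifacts, or correlated
(1/f) noise. Passing recovery tests therefore demonstrates the internal
consistency and calibration of the pipeline, not its robustness to every
feature of recorded data.

`simulate_fepsp_course()` is a deliberately stylized fixture for the
plasticity module: a linear 3-ms falling phase followed by an exponential
decay, with multiplicative amplitude noise. The linear rise makes the
20–80% slope exactly proportional to the amplitude, so the noiseless LTP
identities (a 1.5× step is exactly 50% potentiation) hold to rounding
error.

## Field-potential conventions

`fit_fepsp_slope()` fits a least-squares line to the samples between 20%
and 80% of the fEPSP peak amplitude on the falling-voltage phase. The
peak search starts 2 ms after the stimulus by default — the fitted
deflection is the largest negative one whose latency exceeds the
configurable fiber-volley exclusion — and a peak smaller than
`min_amplitude` (default 0.05 mV) is a no-response error rather than a
slope of noise. LTP is quantified as the mean baseline-normalized
response in a stated post-induction window minus 100%; the conventional
windows are 2–3 h post-induction for long-lasting and 1–2 h for
short-lasting LTP, and for shorter in-vitro recordings the package treats
the averaging window as an explicit argument rather than hard-coding one.
Input–output slopes are fitted through the origin by default (the
input–output function passes through (0,0) physically; an intercept
variant is available by flag, and fitting offset data through the origin
is biased by exactly $\sum xy / \sum x^2 - a$, which the tests pin down),
then normalized to the wild-type population mean within each recording
condition.

## Numerical choices and degenerate inputs

* Failure-rate confidence intervals are exact Clopper–Pearson
  (`stats::binom.test`); $r_f = 0$ makes $m$ unbounded and is an error
  that points at the exact upper confidence bound instead.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), fixed and documented.
* The Poisson pmf is evaluated in log space
  ($\exp(k \ln m - m - \ln k!)$) and agrees with `stats::dpois` to
  $10^{-12}$ over $k \le 30$, $m \le 10$.
* Ties in peak search resolve to the earliest sample; smoothing at sweep
  edges falls back to raw samples (all analysis windows are interior).
* Classifying a sweep set whose recorded noise is exactly zero makes the
  2-SD criterion degenerate (everything is a success); tests of noiseless
  classification pass an explicit nominal noise floor instead.

## Problem sizes used by the test suite

Calibration and recovery tests run at sizes chosen to make their
tolerances meaningful at interactive timescales: closed-form agreement at
10⁴ sweeps (3 binomial SE), end-to-end recovery over 20 seeded
experiments of 300 sweeps/potential per condition at $s \in \{0, 0.25,
0.5\}$ (median absolute error ≤ 0.08; corrected-variant $q$ within 15%),
and QC calibration over 100 stationary plus 100 strongly drifting
simulations (≥ 95% pass / ≥ 95% exclusion). At these sizes the observed
margins are comfortable: median $|\hat s - s|$ lands between 0.03 and
0.07 (the residual bias at $s = 0$ comes from the small asymmetry between
the charge- and peak-based criteria near threshold), fitted $q$ within
about 5–10%, and a 97/100 stationary pass rate.

## Known limitations

* The estimator inherits the Poisson model's assumptions; with few
  release sites and high release probability, binomial saturation biases
  $m$ and hence $\hat s$.
* The silent-fraction estimator uses only failure rates; it cannot
  distinguish silent synapses from conduction failures that spare the
  slow component.
* The 0.9 pC charge threshold and the quantal scale of the simulator are
  mutually inconsistent (see above); analyses mixing the two must choose
  a threshold consciously.
* Potency at +40 mV uses the 25-ms read, which underestimates the peak
  by a kinetics-dependent factor; comparisons across groups are valid,
  absolute $q_{\mathrm{NMDA}}$ values are convention-bound.
* `run_pipeline()` seeds experiment simulations deterministically from
  the top-level seed; file-based (recorded) inputs are analyzed
  identically but their provenance is whatever the files carry.
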