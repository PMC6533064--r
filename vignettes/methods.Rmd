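---
title: "Models and methods behind conflictr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind conflictr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflictr)
```

conflictr implements, as one tested pipeline, the analysis stack used to ask
whether response-conflict recruits the same non-selective motor-inhibition
machinery as outright action-stopping: behavioral estimators for the Simon
and stop-signal tasks, a filter-Hilbert spectral layer, selection of a
fronto-central "inhibition" EEG component with onset detection, single-trial
time-frequency regression with FDR control, STN–M1 phase-locking and
spectral Granger prediction, and TMS-evoked MEP quantification. Because the
human recordings behind such studies are not reproducible at a desk, every
analysis ships with a synthetic generator that plants the corresponding
effect with known ground truth; the test suite closes the loop by asking
each analysis to recover what its generator planted.

## Behavioral models

**Simon task.** Trials are half congruent, half incongruent, with balanced
stimulus side. Correct-trial RTs are Gaussian with mean 326 ms (congruent)
plus a 35 ms congruency cost, SD 80 ms; error rates default to 10.38% and
22.67%. The means and error rates are the operating point the estimators
are exercised at; the 80 ms trial SD is a typical within-subject value for
speeded two-choice tasks.

**Stop-signal task.** Go finish times are ex-Gaussian
(`mu = 400, sigma = 60, tau = 70` ms, so the mean go RT is ~470 ms, with
the right skew real RT distributions show). The stop process has latency
238 ± 20 ms. A stop trial fails iff the go process finishes before
`SSD + stop latency` — the independent-race assumption. The SSD staircase
starts at 200 ms and moves in 50 ms steps (down after failed stops, up
after successful ones, floor 0), independently per go direction; every go
trial records the staircase position of its direction, which is what makes
staircase-matched go sampling possible later.

**SSRT.** `ssrt_integration()` uses the integration method: the
`ceiling(p * n)`-th smallest correct-go RT at `p = p(respond|stop)`, minus
the mean SSD. The order-statistic convention (no interpolation) is the
classic description of the method; interpolated quantiles are available via
`quantile_type = "interp"`. Go omissions are excluded from the go
distribution. Both directions' SSDs are pooled by default (`by_side`
estimates per direction and averages) — pooling is the common convention
when the directions' staircases share a start and step.

## The spectral layer

`filter_hilbert()` band-passes at 30 integer center frequencies (1–30 Hz,
±0.5 Hz) with symmetric two-way FIR filters and takes the analytic signal;
power is the squared magnitude, phase the argument.

Numerical choices that matter:

* **Filter design.** The kernel is the truncated ideal band-pass impulse
  response — the unweighted least-squares optimum for a linear-phase FIR.
  Kernel length is three cycles of the center frequency (configurable).
  Because a three-cycle kernel cannot reach full gain inside a 1 Hz
  passband, the two-pass response is normalized to unit gain at the center
  frequency; without this, narrowband envelope power would be attenuated
  ~30-fold at 10 Hz.
* **Two-pass filtering in the frequency domain.** Forward–backward
  filtering of a symmetric FIR equals multiplication by the squared
  magnitude response, so filtering and the Hilbert step are fused into one
  inverse FFT per band (zero-padded to avoid wrap-around). Zero phase shift
  is asserted by test (an envelope peak moves by at most one sample).
* **Edges.** Continuous traces are decomposed before epoching whenever
  possible; already-epoched input is zero-padded 500 ms per side and
  trimmed, which leaves residual envelope droop near epoch edges — the
  continuous path is the one the pipelines use.
* **Broadband conditioning.** `broadband_filter()` applies the standard
  0.5–50 Hz two-way pre-filter to scalp EEG before component work; LFP is
  left broadband and decimated to 1000 Hz (`decimate_recording()`), which
  makes a model order of 50 equal 50 ms of history inside a 200-sample
  window.

`ersp()` converts trial-mean power to dB against the trial-averaged
pre-stimulus baseline (−300 to 0 ms). A stationary signal gives 0 dB
everywhere; doubling power gives +3.0103 dB once the filter settles —
both are asserted at tolerance in the tests.

## EEG component selection and onset detection

The scalp generator mixes four sources (fronto-central burst, posterior
alpha, 1/f background, lateralized motor beta) through a random but
structured forward model, plus white sensor noise. The decomposition itself
is pluggable: `component_set()` accepts any unmixing matrix. In the closed
loops the true mixing inverse is injected, which isolates the selection and
onset logic from the convergence behavior of any particular ICA
implementation.

Selection follows the functional-localizer rule: candidates are components
whose absolute map weight peaks at FCz, Cz, C1, C2, FC1 or FC2; each
candidate's fronto-central back-projection over 0–500 ms post-stop-signal
is correlated with the all-components ERP, and the highest correlation
wins. Ties break to the lowest index (and are logged). Multi-component
selection (`multi = TRUE`) exists for datasets where two components split
the P3 but is off by default, since no principled threshold for "explains
significant parts" presents itself.

Onset detection works backwards from the peak: sample-wise tests of stop
against matched-go amplitudes over 0–500 ms at two-sided p = 0.01, peak of
the positive difference wave, then the first sample of the contiguous
significant positive run containing that peak. Two departures from a naive
reading are deliberate:

* The stop and matched-go sets differ in size, so the default per-sample
  test is Welch's two-sample t; a paired variant exists for 1:1 matchings.
* The generator's burst envelope uses a 10 ms raised-cosine attack followed
  by a Hann-shaped decay on a 4 Hz carrier. A symmetric Hann envelope
  would reach statistically detectable amplitude only ~100 ms after its
  nominal start, making "the planted onset" unrecoverable by any
  sample-wise rule; a fast attack makes the planted onset a well-defined
  quantity that the backwards-from-peak rule can recover to within a few
  samples.

One property of the peak-then-test procedure deserves a warning: the peak
is chosen as the *maximum* of the difference wave, so testing it inherits a
selection bias. On pure-noise input the peak sample tests significant in
roughly 60% of runs — not at the nominal alpha. The per-sample machinery is
calibrated (null rejection rate ≈ alpha, asserted in the tests); the
peak-level test is not, and cannot be without a correction the original
procedure does not include. The suite documents both numbers rather than
hiding the bias.

## Single-trial regression and group statistics

`tf_power_rt_regression()` regresses single-trial power on z-scored RT per
pixel (OLS with intercept; z-scoring over the selected trials only). Power
enters in raw units — dB transformation is applied to condition averages,
not single trials — with a `db = TRUE` option. Zero RT variance is an
error; zero-variance pixels at the group stage yield p = 1 rather than
errors, and a zero-variance pixel with a nonzero mean difference is treated
as its noise-free limit (p → 0).

`group_stat_map()` runs pixelwise one-sample or paired t-tests across
subjects and corrects over all pixels jointly; `fdr_correct()` is classic
Benjamini–Hochberg step-up (q = 0.01 default), switchable to
Benjamini–Yekutieli. The BH mask is verified against an independently coded
brute-force step-up on random p-vectors, and the realized false-discovery
proportion is checked by simulation. Granger maps get one-sided tests
(`granger_onesided_tests()`) since raw spectral estimates cannot be
negative.

## Connectivity

**Montages and contact selection.** `make_bipolar()` derives adjacent-pair
differences. STN montage selection scores each montage's Welch spectrum by
its maximum 1/f-detrended elevation within 13–30 Hz (3-bin smoothing; a
montage must exceed 0.4 log10 units — about a 2.5× elevation — before the
"no clear peak" warning path is avoided). M1 selection scores mean
beta-band ERSP in a ±250 ms peri-response window on congruent trials; most
negative (strongest desynchronization) wins, and a montage showing only a
power increase is never selected.

**PLV.** The magnitude of the trial-averaged unit phasor of the phase
difference, per time-frequency point, optionally baseline-subtracted
(−300 to 0 ms). Exactness under perfect locking (including constant phase
offsets) and the Rayleigh small-sample mean `sqrt(pi / (4 n))` under
independence are both asserted.

**Granger prediction.** Windowed bivariate AR models (order 50, 200 ms
windows, window-wise demeaning, trials stacked into one design; lags never
cross trial boundaries) are fitted by least squares via the normal
equations; the same Gram matrix yields both univariate models, used by the
time-domain log-variance ratio that cross-checks the spectral estimates
(Geweke consistency, asserted on AR(2) toys). The spectral measure is the
standard log-ratio of the target's full spectral density to its intrinsic
part, from the fitted transfer function and residual covariance, evaluated
at 21 frequencies spanning 10–30 Hz. Windows slide at 10 ms by default
(the window stamp is its center); windows whose fit has companion-matrix
eigenvalues on or outside the unit circle are flagged and excluded.
Estimates are expressed as percent change from the mean over baseline
windows (those fully inside −300 to 0 ms), per frequency and direction.

Percent-change baselining has a known small-sample property: because the
baseline mean sits in the denominator, estimates are positively biased
(Jensen's inequality), so one-sided group tests on null data reject
somewhat above the nominal rate unless sessions are long. The tests
quantify this at realistic session lengths instead of assuming it away;
directional conclusions always compare the two directions, which share the
bias.

**LFP generator.** Inside the coupling window each site's band component is
`(s + a·n_i)/sqrt(1 + a^2)` — a shared narrowband process plus a private
one — with `a` calibrated to the requested PLV by a Monte-Carlo lookup
computed once per session (there is no closed form). M1 additionally
receives STN's in-window band signal delayed by `granger_lag` samples
(default 10 at 1000 Hz) and scaled by `granger_gain`. All non-planted
content scales with `noise_sd`, so a noiseless, fully coupled pair gives
PLV = 1 exactly. The default coupling window (180–240 ms) and band
(18–22 Hz) mirror the reported effect's extent; note that a 60 ms coupled
interval inside 200 ms analysis windows is a deliberately hard condition
for the Granger layer, and the directionality checks therefore aggregate
band/window pixels by their median and, at cohort level, average two
sessions before comparing directions.

## MEP quantification

Sweeps start 150 ms before the pulse at 1000 Hz. Screening applies the two
stated rules strictly: pre-pulse RMS (100 ms window) must not *exceed*
0.01 mV, and the peak-to-peak amplitude within (10, 50] ms post-pulse must
exceed 0.01 mV. Summaries use the median by default (the preprocessing
convention) with a mean option (the analysis-section convention); the
discrepancy between the two conventions in the source procedures is the
reason both exist. Normalization divides by the baseline (null-trial)
statistic, which makes summaries invariant to recording-chain gain — though
not to gains so large that the scaled noise floor crosses the screening
threshold, which is a property of the thresholds, not a bug. The MEP
template is a biphasic difference of Gaussians peaking 20–30 ms post-pulse,
scaled to the requested peak-to-peak amplitude.

## Pipelines and reproducibility

`run_exp1/2/3()` chain the stages over synthetic cohorts and return
reports embedding flags, group statistics and provenance (root seed, config
hash, package version). Every generator is a pure function of
`(parameters, seed)`; a single root seed drives deterministic per-subject
and per-generator substreams, so identical configurations reproduce
identical reports. Default cohort and session sizes in the pipelines and
tests (e.g. 2–21 subjects, 64–768 trials, 40–100 simulation seeds,
25 ms Granger window steps) are chosen as the smallest sizes at which the
planted effects are comfortably recoverable; all are configuration
arguments, and the full-study sizes (21 subjects, 768 Simon trials,
200 go/100 stop trials) remain the generator defaults where they matter.

## What the generators do and do not emulate

The synthetic data reproduce the statistical structure the analyses assume:
congruency costs, an independent race with a staircased SSD, a
fronto-central low-frequency burst whose amplitude tracks RT slowing and
whose onset differs by stop outcome, transient beta-band STN→M1 coupling
with a directed lag, and suppressed biphasic MEPs with controllable
pre-pulse contamination. They do not emulate volume conduction through a
realistic head model, non-stationary artifact classes (blinks, muscle,
electrode drift), oscillatory asymmetries, or patient-specific
pathophysiology. Passing closed-loop tests therefore demonstrates that the
estimators recover what they claim to estimate under their stated
assumptions — not that those assumptions hold in any particular recording.

## Known limitations

* No ICA algorithm ships with the package; `component_set()` consumes an
  unmixing matrix from wherever the user obtains one.
* The single-trial amplitude model (linear in z(RT)) is a stand-in: the
  underlying studies report a positive regression but no generative form.
* Serialization is plain text (TSV + JSON sidecars); there is no HDF5
  writer.
* The peak-level significance test in onset detection is selection-biased
  under the null, as discussed above.
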