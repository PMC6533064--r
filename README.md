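# conflictr

Multimodal analysis of motor inhibition during response conflict, in R.

When people must choose between incompatible motor responses — as on
incongruent trials of a Simon task — their reaction times slow, and a body
of work argues that this slowing reflects the same fronto–basal-ganglia
braking mechanism that cancels actions outright in the stop-signal task:
a fronto-central low-frequency (2–8 Hz) EEG source, beta-band (13–30 Hz)
communication from the subthalamic nucleus (STN) to primary motor cortex
(M1), and a broad, non-selective drop in cortico-spinal excitability
measurable as TMS-evoked motor potentials (MEPs). Testing that account
takes four very different kinds of data and a long chain of estimators.
conflictr implements that chain as one coherent, tested package for
researchers in cognitive neurophysiology, together with synthetic
generators that plant each effect with known ground truth so every
estimator can be validated closed-loop.

## What is implemented

**Behavior.** Simon-task condition contrasts; the independent-race model of
stopping with a staircased stop-signal delay (SSD); SSRT by the integration
method,

    SSRT = F_go^-1( p(respond | stop) ) - mean SSD,

with the go-RT quantile taken as the `ceiling(p·n)`-th order statistic; and
staircase-matched go-trial sampling for onset comparisons.

**Spectral layer.** Filter–Hilbert time-frequency decomposition (30 center
frequencies, 1–30 Hz, ±0.5 Hz symmetric two-way least-squares FIR filters),
power `|analytic|²`, and event-related spectral perturbation in dB against a
−300 to 0 ms baseline.

**EEG components.** Functional-localizer selection of the fronto-central
"motor inhibition" independent component (maximal map weight at
FCz/Cz/C1/C2/FC1/FC2, highest correlation with the all-components ERP over
0–500 ms post-stop-signal), selective back-projection, and P3 onset
detection by the backwards-from-peak rule (sample-wise tests at two-sided
p = 0.01, onset = first sample of the significant run containing the peak).

**Single-trial statistics.** Per-pixel OLS regression of single-trial
time-frequency power on z-scored RT; group-level mass-univariate t-maps
with Benjamini–Hochberg FDR control (q = 0.01).

**Connectivity.** Bipolar montage construction and physiological contact
selection (resting beta peak for STN, movement-related beta
desynchronization for M1); phase-locking value

    PLV(t, f) = | n⁻¹ Σ_r exp(i(θ_x − θ_y)) | ;

and time/frequency-resolved spectral Granger prediction from windowed
bivariate autoregressive models (order 50, 200 ms windows, 21 frequencies
spanning 10–30 Hz, percent change from a −300 to 0 ms baseline, one-sided
group tests).

**MEPs.** EMG sweep screening (pre-pulse RMS > 0.01 mV or peak-to-peak
≤ 0.01 mV rejected), peak-to-peak quantification within 10–50 ms
post-pulse, baseline normalization, and condition contrasts including the
suppression-vs-slowing correlation.

**Pipelines.** `run_exp1()`, `run_exp2()`, `run_exp3()` chain these stages
over synthetic cohorts and emit reproducible, provenance-stamped reports.

## A worked example

```r
library(conflictr)

behavior <- gen_simon_behavior(simon_params(), n_trials = 768, seed = 7)
simon_summary(behavior)
#> <simon_summary>
#> # A tibble: 2 x 5
#>   condition       n mean_rt sem_rt err_rate
#>   <chr>       <int>   <dbl>  <dbl>    <dbl>
#> 1 congruent     384    329.   4.17    0.115
#> 2 incongruent   384    358.   4.72    0.247
#> contrast (incongruent - congruent):
#> # A tibble: 1 x 2
#>   rt_diff err_diff
#>     <dbl>    <dbl>
#> 1    29.5    0.133

sst <- gen_stop_signal_session(race_params(), n_go = 200, n_stop = 100, seed = 7)
race_model_check(sst)
#> # A tibble: 1 x 4
#>   mean_go_rt mean_failed_stop_rt race_ok reason
#>        <dbl>               <dbl> <lgl>   <chr>
#> 1       455.                403. TRUE    <NA>

ssrt_integration(sst)
#> # A tibble: 1 x 6
#>    ssrt p_respond_given_stop mean_ssd go_quantile_rt  n_go n_stop
#>   <dbl>                <dbl>    <dbl>          <dbl> <int>  <int>
#> 1  237.                 0.49      205           442.   200    100
```

The simulated session shows the expected structure: incongruent trials are
~30 ms slower and more error-prone than congruent ones; failed-stop RTs
(403 ms) are faster than go RTs (455 ms), as the race model requires; the
staircase holds stopping success near 50%; and the integration-method SSRT
(237 ms) recovers the generator's true stop latency of 238 ms.

Every result object has `tidy()`/`glance()` methods returning tibbles and
an `autoplot()` method (ggplot2), so pipelines compose with dplyr and
ggplot2 idioms.

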