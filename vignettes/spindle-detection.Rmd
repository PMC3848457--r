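---
title: "Detecting oscillatory bursts with discounted autoregressive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting oscillatory bursts with discounted autoregressive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Alpha spindles are short (0.5–2 s) bursts of high-amplitude narrowband
alpha ([8, 13] Hz) activity, most prominent over parietal and occipital
cortex, and a well-replicated electrophysiological correlate of fatigue and
drowsiness. Detecting them reliably — and with onset/offset timing good
enough to estimate spindle rate and duration — is the problem this package
addresses. The approach treats a spindle not as a spectral feature but as a
*change point*: a sudden interval during which the statistical structure of
the band-passed EEG departs from its recent past.

## The discounted AR model and the sequential recursion

The band-passed, zero-mean EEG trace $x_t$ is modeled as an autoregression
of order $p$,
$$x_t = \sum_{i=1}^{p} A_i\, x_{t-i} + \varepsilon_t,\qquad
  \varepsilon_t \sim N(0, \sigma^2),$$
whose Gaussian conditional likelihood makes maximum-likelihood estimation
equivalent to least squares. The *discounted* AR (DAR) model replaces the
ordinary sum of squared errors with an exponentially forgotten one,
$$\hat A_t = \arg\min_A \sum_{i=p+1}^{t} (1-r)^{t-i}
  \left(x_i - A^\top \bar x_i\right)^2,
  \qquad \bar x_i = (x_{i-1},\dots,x_{i-p})^\top,$$
so samples lose influence at rate $(1-r)$ per step and the fit adapts to
slow non-stationarity. The sequential (SDAR) recursion maintains this
estimate online with a handful of vector operations per sample: a gain
scalar $c_t = r\,\bar x_t^\top V_{t-1} \bar x_t$, a moment vector
$M_t = (1-r)M_{t-1} + r\,\bar x_t x_t$, a Sherman–Morrison update of the
gain matrix $V_t$, coefficients $A_t = V_t M_t$, predictive mean
$\mu_t = A_t^\top \bar x_t$, and the exponentially weighted model variance
$\sigma_t^2 = (1-r)\sigma_{t-1}^2 + r(x_t-\mu_t)^2$. The recursion is
initialized at $t = p$ with $V = I_p$ and Burg estimates of $(A, \sigma^2)$
from a training segment. The detection statistic is the quadratic loss
$$\psi_t = (x_t - \mu_t)^2,$$
which spikes when the discounted model mispredicts — precisely at the
onset of an oscillatory burst whose amplitude and phase structure the
recent past does not explain.

Two implementation points are worth making explicit:

* **Update ordering.** The coefficients are refreshed with $x_t$ *before*
  $\mu_t$ is computed, exactly as the sequential algorithm is defined, so
  $\psi_t$ is a partially in-sample residual rather than a strict one-step
  ahead error. We preserve this ordering; it changes the loss only at
  order $r$.
* **Equivalence to batch weighted least squares.** $V_t^{-1}$ equals
  $(1-r)^{t-p} I_p + r\sum_i (1-r)^{t-i}\bar x_i \bar x_i^\top$, so the
  recursion solves the discounted normal equations with an exponentially
  vanishing ridge from the identity initialization. The test suite checks
  the sequential coefficients against an independent batch solve of the
  weighted normal equations on short series.

```{r}
library(sdareeg)
sim <- simulate_ar_changepoint(model1_spec(seed = 1))
fit <- sdar_run(sim$signal, p = 2, r = 0.01, train_len = 500)
plot(fit, "coefficients")
```

## Parameters that matter

* **Discounting rate `r`** (dimensionless, default 0.01): the inverse
  memory of the model; the effective sample size of the estimate is about
  $2/r$ samples. Rates of 0.01–0.001 work well at 128 Hz: fast enough to
  follow drift, slow enough that a 64-sample (500 ms) burst still looks
  anomalous rather than being absorbed into the model. The rate should
  scale down as the sampling rate goes up.
* **Model order `p`** (default 1 in the pipeline): after a [6, 15] Hz
  band-pass the signal is so narrowband that one or two lags capture its
  local dynamics; the point is to know *when* the signal is irregular, not
  to model its spectrum.
* **Training length** (default 10 s): the Burg initialization segment.
  Anything long enough for a stable low-order fit works; the initialization
  is forgotten at rate $(1-r)$ regardless.
* **Smoothing window** (5 samples): a centered moving average over
  $\psi_t$; sets the effective temporal resolution (≈ 40 ms at 128 Hz) and
  suppresses single-sample outliers.
* **Channel voting fraction** (1/3): a sample counts as detected when at
  least $\lceil$ fraction × channels $\rceil$ of the analyzed channels
  exceed threshold; with the default 12 posterior channels that is 4.
* **Merge/prune (250 ms each)**: detected regions separated by less than
  250 ms are merged, then isolated regions shorter than 250 ms are dropped
  (in that order — a short fragment near a long event survives via the
  merge). These mirror the physiological 0.5–2 s spindle duration.
* **F-measure weight `beta`** (2): threshold selection maximizes
  $F_\beta = (1+\beta^2)PR/(\beta^2 P + R)$ computed from time-based
  precision and recall; $\beta = 2$ favors recall because spindles occupy
  well under 1% of a recording and misses are costlier than false alarms.
* **Fuzzy window** (0–100 ms): when comparing two labelings, false
  positive/negative time within this distance of an agreement region is
  forgiven, absorbing inter-rater-scale boundary jitter.

## Evaluation semantics

`compare_labels()` classifies every instant into Agreement, Null
Agreement, False Positive or False Negative by set arithmetic between the
two interval sets; the four durations always partition the compared time.
All interval arithmetic is done on the discrete sample grid (default
128 Hz) so the sums are exact; endpoints are rounded to the nearest
sample. The fuzzy window is realized as a boundary tolerance: agreement
runs are dilated by the window and FP/FN mass inside the dilation becomes
agreement. A truth event with no overlapping detection gets no
forgiveness. Derived metrics: precision, recall (= sensitivity),
specificity, count-based hit rate, and the temporal error (total FN time
per truth event), which summarizes boundary localization. ROC curves use
the time-based rates (TPR = recall, FPR = 1 − specificity), keeping them
commensurate with the $F_\beta$ optimization.

## The spectral baseline

For comparison the package implements the sliding-window
amplitude-spectral-density detector: 1 s Hamming-windowed segments slid by
250 ms; peak search in [3, 40] Hz; if the peak falls in [8, 13] Hz its
full width at half maximum is measured by linear interpolation and the
window is a spindle iff FWHM < 2 × 1.37 Hz (twice the Hamming noise
bandwidth). An exponential $f(x) = e^{\gamma x}$ is fit to the spectrum by
1-D least squares (excluding the peak's FWHM band) and the oscillation
index — peak area over fitted-noise area across that band — is reported as
a spectral SNR proxy but not used for gating. Two caveats the
implementation makes visible: (i) the printed form of the noise model is
ambiguous between $e^{\gamma x}$ and $e^{x^\gamma}$; we default to the
log-linear decay $e^{\gamma x}$, the standard reading for 1/f-like spectra
on this scale, and expose the alternative via `form = "power"`. (ii) The
FWHM gate alone is false-positive prone: chance narrow peaks in the alpha
band of pure white noise pass it in a sizable fraction of windows, which
is consistent with this baseline's low precision when run without artifact
removal. The FWHM of a full-window pure tone is ≈ 1.81 Hz (the Hamming
main lobe at half maximum) independent of amplitude, comfortably under the
2.74 Hz criterion, while a 500 ms burst inside the window widens toward —
but typically stays under — the gate.

## What the synthetic generators emulate (and what they do not)

**AR change-point processes** (`simulate_ar_changepoint`): piecewise AR(2)
with continuous lag carry-over at boundaries and a 500-sample burn-in.
The two canonical studies are a coefficient change
$(0.6,-0.2) \to (0.4,-0.6)$ at sample 2000 of 4000 (Model 1) and an
innovation-variance change $1 \to 4$ with fixed coefficients (Model 2).
A note on printed coefficients: Model 2's second coefficient is taken as
$-0.2$, matching the pre-change model — the deviant value that appears in
one printed rendering of it is a typographical slip.

**Spindle EEG** (`simulate_spindle_eeg`): 33 channels on a 10–10 mosaic at
300 Hz; independent white Gaussian background at 3 μV RMS per channel;
10 Hz bursts of 500 ms every 5 s from the 10 s mark, 20 bursts, with peak
amplitude = SNR × 3 μV on the strongest channels. Scalp topographies of
this kind are classically produced by a two-dipole forward model of a
posterior alpha source; we use fixed per-channel spatial gains peaking
over parietal/occipital electrodes and falling off anteriorly instead,
since detector validation needs a posterior-weighted source, not a head
model. Bursts carry a 10% cosine
(Tukey) taper to avoid spectral splatter from rectangular onsets; the SNR
convention is peak amplitude over noise RMS.

What the simulation deliberately does **not** contain: spatially
correlated background (volume conduction), 1/f spectral structure, eye and
muscle artifacts, or variability in burst frequency, duration and
amplitude. Consequences worth stating plainly: after the [6, 15] Hz
band-pass, white background noise loses most of its power while the 10 Hz
burst keeps all of it, so the *in-band* SNR is several times the nominal
amplitude SNR and detection remains easy even at nominal SNR 1. Passing
the simulated benchmark therefore demonstrates the machinery end to end
and the monotone improvement of $F_\beta$ with SNR, not performance on
real EEG at those nominal SNRs.

## Adaptation latency versus band-holding

How fast does the recursion track a coefficient change? The bias of the
discounted estimate decays as $(1-r)^k$ after the change, so with
$r = 0.01$ the largest coefficient jump in the Model 1 study
($-0.2 \to -0.6$) crosses into a ±0.15 band after about
$\ln(0.15/0.4)/\ln(0.99) \approx 98$ samples — adaptation genuinely takes
about a hundred samples. A different quantity is how long until the
estimate enters that band *and never leaves again*: with an effective
sample size of $2/r = 200$ the estimator's standard deviation is ≈ 0.06,
the band is only ≈ 2.2σ wide, and excursions over a 2000-sample tail are
near-certain, so enter-and-remain statistics are dominated by stationary
fluctuation rather than adaptation speed and come out an order of
magnitude larger. Both numbers are computed by the test and benchmark
code; when quoting a "settling time", say which one is meant.

## Numerical choices

* $V_t$ is re-symmetrized as $(V + V^\top)/2$ every step; asymmetry stays
  at rounding level ($<10^{-9}$) over $10^5$-sample runs.
* $\sigma_t^2$ is floored at $10^{-12}$ so constant segments cannot
  collapse the variance to exactly zero; a constant-zero input gives
  $\psi_t \equiv 0$ and geometric variance decay down to the floor.
* $\psi_t$ for $t \le p$ is defined as 0 and excluded from smoothing and
  thresholding; `sdar_run` accepts an explicit `init` for degenerate
  inputs a Burg fit must reject (constant signals).
* The threshold sweep uses 200 quantile-spaced candidates over the pooled
  smoothed-loss distribution; ties in $F_\beta$ break toward the smallest
  threshold. The above-threshold sample set is non-increasing in the
  threshold, so the swept ROC is monotone.
* Resampling 300 → 128 Hz uses the rational factor 32/75 with a polyphase
  anti-aliasing filter; the band-pass is an order-8 Butterworth applied
  forward-backward (zero phase), which preserves burst timing at the cost
  of doubling the effective order. A causal pass is the natural variant
  for online use, where detection latency is bounded below by the 250 ms
  post-processing horizon anyway.
* The burg fit delegates to the standard lattice implementation in
  `stats::ar.burg`; Butterworth design, zero-phase filtering and
  resampling delegate to the `signal` package.

## Problem sizes used by the validation code

The test and benchmark suites run the Model 1/2 studies at their native
n = 4000 with 20 replicate seeds, the spindle study at its native 115 s ×
33 channels (≈ 14,700 analysis samples per channel at 128 Hz) with up to 5
replicate seeds, the batch least-squares cross-check on 50 signals of
n = 200, and the evaluation algebra on 1000 random interval-set pairs —
sizes chosen so every study runs at full fidelity in seconds.

## Known limitations

* The frequency band of interest must be chosen *a priori*; the method
  detects statistical irregularity within the band, not which band is
  irregular.
* Threshold selection requires a labeled training stretch (or a
  transferred threshold); there is no unsupervised threshold rule.
* The synthetic background understates real EEG difficulty (see above);
  absolute synthetic F-measures are optimistic.
* Event-level (as opposed to time-level) precision/recall and statistical
  tests on metric differences are out of scope, as are ICA artifact
  removal, model-order selection and multivariate AR modeling.
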