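# sdareeg

Change-point detection of short narrowband oscillatory bursts ("alpha
spindles") in EEG, using sequentially estimated **discounted autoregressive
(DAR) models**.

Alpha spindles — 0.5–2 s bursts of high-amplitude [8, 13] Hz activity over
parietal/occipital cortex — track fatigue and drowsiness, so detecting them
with good onset/offset timing matters for fatigue monitoring, driving
research and BCI work. `sdareeg` treats a spindle as a *change point*: an
interval where the statistical structure of the band-passed EEG departs
from its recent past. It is aimed at EEG researchers who need an online,
computationally light detector plus the evaluation machinery to validate it
against expert labels.

## The method

The band-passed, zero-mean trace `x_t` is modeled as AR(p) with Gaussian
innovations; the *discounted* fit minimizes the exponentially forgotten sum
of squares

    Â_t = argmin_A Σ_{i≤t} (1−r)^(t−i) (x_i − Aᵀ x̄_i)²,   x̄_i = (x_{i−1},…,x_{i−p})ᵀ

so the model adapts to slow non-stationarity at forgetting rate `1−r`
(`r ≈ 0.01` at 128 Hz). The sequential (SDAR) recursion maintains `Â_t`,
the predictive mean `μ_t = Â_tᵀ x̄_t` and the model variance
`σ_t² = (1−r)σ_{t−1}² + r(x_t − μ_t)²` online, initialized from a Burg fit
of a training segment. Each sample is scored by the quadratic loss

    ψ_t = (x_t − μ_t)²,

which spikes at burst onsets. Smoothed loss traces are thresholded per
channel, combined by a 1/3 channel vote, merged/pruned at 250 ms, and the
threshold is chosen by maximizing the weighted F-measure
`F_β = (1+β²)·P·R / (β²·P + R)` (β = 2, favoring recall) against labeled
events under a time-based four-state comparison (Agreement / Null /
False Positive / False Negative, with an optional fuzzy boundary window).

The package also includes the sliding-window amplitude-spectral-density
baseline (Hamming-windowed 1 s windows, alpha-peak FWHM < 2×1.37 Hz
criterion, exponential 1/f fit, oscillation index), seeded generators for
the two synthetic validation studies, CSV/TSV/JSON I/O and a small CLI
(`inst/cli/sdareeg`).

## Worked example

Simulate the 20-burst ground-truth study (10 Hz, 500 ms bursts every 5 s
from the 10 s mark, 3 μV RMS background, SNR 3), run the full pipeline and
evaluate against the schedule:

```r
library(sdareeg)
rec <- simulate_spindle_eeg(spindle_sim_spec(snr = 3, seed = 42))
rec
#> EEG recording: 33 channels x 34500 samples @ 300 Hz ( 115 s )
#>   channels: Fp1 Fpz Fp2 F7 F3 Fz F4 F8 ...

det <- detect_spindles(rec, truth = attr(rec, "truth"))
det
#> Spindle detection: 20 events on 12 channels @ 128 Hz; tau = 0.5855
#>   optimized F_beta = 0.978

head(det$events, 3)
#>      onset   offset
#> 1 10.00000 10.54688
#> 2 15.00000 15.54688
#> 3 19.98438 20.54688

compare_labels(attr(rec, "truth"), det$events,
               total_dur_s = ncol(rec$data) / rec$fs, fs = det$fs)
#> Labeled-interval comparison (fuzzy window 0 s)
#>   Sensitivity/Recall  0.999
#>   Specificity         0.990
#>   Precision           0.901
#>   Hit Rate            100.00% (20/20)
#>   Temporal Error      ~0 ms
#>   Agreement           9.992 s
#>   Null Agreement      103.898 s
#>   False Negative      0.008 s
#>   False Positive      1.102 s
```

All 20 scheduled bursts are recovered (hit rate 100%) with sub-sample
temporal error; the peak weighted F-measure of the threshold sweep is
0.978. `sdar_run()` exposes the raw recursion (loss, coefficient and
variance traces) for the AR change-point studies, e.g.
`sdar_run(simulate_ar_changepoint(model1_spec(1))$signal, p = 2, r = 0.01,
train_len = 500)`.

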