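---
title: "Multi-channel superposition denoising for weak wearable ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel superposition denoising for weak wearable ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgstack)
```

## The problem and the model

Surface ECG recorded away from the chest is weak: roughly 1000 µV of R-peak
amplitude on the chest falls to 30–50 µV at the mastoid (behind the ear) and
50–70 µV on the upper arm, while front-end noise of even a good acquisition
system is of order 1 µV peak-to-peak per channel. At those amplitudes the P
and T waves drown in channel noise, and only the R spike survives — enough
for heart rate, not enough for anything diagnostic.

`ecgstack` implements the superposition remedy: record the *same* ECG on K
closely spaced electrodes simultaneously and average the channels. Each
channel is modelled as

$$g_i(t) = f(t) + \eta_i(t), \qquad i = 1, \dots, K,$$

where $f$ is the common ECG (electrodes a few mm apart see essentially the
same potential) and $\eta_i$ is zero-mean channel noise, independent across
channels because it originates in each channel's own electronics. The
channel mean

$$\bar g(t) = \frac{1}{K}\sum_{i=1}^{K} g_i(t) = f(t) + \frac{1}{K}\sum_i \eta_i(t)$$

is unbiased for $f$, and independence gives
$\sigma_{\bar g} = \sigma_\eta / \sqrt{K}$. In the amplitude-ratio (dB)
sense the SNR therefore improves by $20\log_{10}\sqrt{K} = 10\log_{10}K$:
**9.03 dB for K = 8** (`predicted_snr_gain_db(8)`). Unlike beat-synchronous
ensemble averaging, nothing here needs a fiducial point, so the method runs
in real time on raw samples.

A note on the variance law: the per-channel derivation is sometimes quoted
with the noise *standard deviation* scaling as $1/K$. That reading is
inconsistent with the variance algebra ($\sigma^2_{\bar g} = \sigma^2_\eta/K$)
and with the 9.03 dB figure itself, which equals $10\log_{10}8$, not
$20\log_{10}8$. The package implements the $1/\sqrt{K}$ law throughout
(`predicted_noise_sd_ratio()`).

### When alignment fails

The derivation assumes the channels are *in phase*. A propagation or filter
mismatch of one sample at 180 samples per cycle is
$360/180 = 2°$ of cycle phase (`degrees_per_sample()`). With a cumulative
one-sample offset per channel the eight R apices no longer coincide, the
averaged QRS is blunted, and most of the theoretical gain is lost — the
aligned-vs-misaligned experiment pair in `superposition_experiment()`
quantifies exactly this collapse (from ≈ 9 dB down to ≈ 1–3 dB under the
package defaults). This is why the companion hardware design keeps
electrodes millimetres apart, uses matched 1 % front-end components, and
equal-length differential traces.

## The SNR metric

All waveform quality in this package is the peak-to-peak ratio

$$\mathrm{SNR} = 20\log_{10}\frac{\mathrm{QRS}_{pp}}{\mathrm{noise}_{pp}},$$

with $\mathrm{QRS}_{pp}$ = max − min over a **120 ms window centered on the
R apex** and $\mathrm{noise}_{pp}$ = max − min over a **40 ms window on the
isoelectric T–P segment**, centered midway between the end of the T wave and
the onset of the next P wave (`ecg_snr()`). Two conventions circulate for
the noise window — "T-P" and "inside the R-T interval" — and they disagree;
this package deliberately uses the T-P segment, because a window inside R-T
would count the T wave itself as noise. Over multi-beat recordings the
per-beat values are aggregated by the **median** (`snr_over_recording()`),
robust to one corrupted beat. A flat noise window is reported as an
infinite-SNR flag rather than an error.

## The synthetic generator

No real recordings ship with the package; every experiment runs on
synthetic data from `generate_template()` / `generate_clean_recording()` /
`make_multichannel()`.

* **Morphology.** One cycle is a sum of five Gaussian bumps (P, Q, R, S, T),
  truncated at ±4σ so the baseline between waves — in particular the T-P
  noise-measurement segment — is exactly isoelectric. Defaults at 180
  samples/cycle (720 ms at 250 Hz): centers at samples 30/53/60/67/105,
  widths (σ) 5/2/1.5/2/10 samples, amplitudes 0.15/−0.1/1/−0.2/0.3 relative
  to R. That gives a P wave of ≈ 80 ms, a QRS complex of ≈ 90 ms and a T
  wave of ≈ 160 ms — canonical adult durations — with a sharp (σ = 6 ms) R
  apex. The template is rescaled so max = `r_amplitude` exactly;
  `location_amplitude()` provides chest/mastoid/upper-arm presets (1000, 40,
  60 µV).
* **RR variability.** `rr_jitter` resamples each cycle to a length drawn
  uniformly from ±that fraction — a deliberately crude stand-in for sinus
  variability that is sufficient to give the heart-rate series nonzero
  variance (without which a correlation between two detectors would be
  undefined).
* **Channels.** Each channel applies a gain, an integer-sample delay
  (edge-replicated, since a physical delay does not wrap within a
  recording; circular shift is reserved for isolated single templates), and
  adds iid Gaussian noise. All randomness flows through an explicit seed,
  and identical seeds give bit-identical recordings.
* **Noise calibration.** Experiments specify noise by *target SNR* or
  *target Vpp*, not by σ directly. `sigma_for_target_snr()` divides the
  clean QRS Vpp by the target ratio and by the expected range of Gaussian
  noise over the 40 ms window; `sigma_for_target_vpp()` does the same for a
  full window (e.g. 10 s). The expected-range factor is estimated once by
  Monte-Carlo (`gaussian_vpp_factor()`, 400 draws), because the extreme-value
  constant for finite n has no convenient closed form.

What the generator does **not** emulate: electromyographic and motion
artifacts, electrode-impedance drift, baseline wander, powerline pickup,
inter-channel noise correlation, and real morphological variety (arrhythmia,
biphasic T waves). Passing the simulation suite therefore demonstrates the
averaging mathematics and the pipeline's correctness under the independence
assumptions — not robustness to structured real-world interference, which is
exactly the regime where averaging uncorrelated channels is *least* helpful.

## Simulation experiments and their sizes

* `superposition_experiment()`: 100 replicates of a 4-cycle recording on 8
  channels, single-channel calibration SNR 12 dB — noisy enough that P and T
  are visibly buried, as in the motivating simulations. Reports the median
  (over replicates) of the median-per-beat SNR improvement of the average
  over channel 1. Aligned offsets give ≈ 8–9 dB; cumulative 2° offsets give
  ≈ 1–3 dB.
* `averaged_noise_experiment()`: eight noise-only channels calibrated so
  each channel's expected 10 s Vpp matches the bench values (1.4, 1.5, 1.7,
  1.2, 1.5, 1.25, 1.1, 1.2 µV); 100 replicates; reports the 95th percentile
  of the 8-channel average's Vpp. The √8 law predicts ≈ 0.5 µV here.
* `hr_correlation_experiment()`: one 60-beat RR process (5 % jitter)
  rendered twice with independent noise at 15 dB single-channel SNR — the
  quality of a typical single mastoid/arm channel, which is the setting the
  heart-rate comparison is meant to emulate; independent R-peak detection on
  each; Pearson correlation of the beat-matched bpm series.

These sizes (≤ 100 replicates, ≤ 60 beats, 250 Hz) were chosen so the whole
validation suite runs in seconds while keeping the Monte-Carlo error of each
reported median well below the width of its acceptance band.

## The filter chain

`filter_chain()` reproduces the real-time display chain: notches at 50 and
100 Hz, a 100 Hz low-pass, a 0.1 Hz high-pass. Families and orders are not
dictated by the chain's description, so the package uses standard choices:
RBJ biquad notches (Q = 30), 4th-order Butterworth low-pass, 2nd-order
Butterworth high-pass. At 250 Hz the 100 Hz corner sits close to Nyquist
(125 Hz), so the 100 Hz notch and the low-pass overlap; both are kept,
mirroring the deployed list.

Every stage is applied once backward and once forward in time
(`apply_zero_phase_chain()`), so the chain has **zero net phase** at every
frequency and the magnitude response is the squared stage response. The
numerical details matter more than the filter design here:

* **Initial conditions.** Each pass starts from the stage's steady-state
  response to a step of the first sample's amplitude (the companion-matrix
  solve familiar from `lfilter_zi`). This makes a constant input map to its
  steady-state output *exactly* — zero, for any chain containing the
  high-pass — instead of producing a multi-second start-up transient.
* **Padding.** Signals are extended by odd reflection (point symmetry about
  each endpoint, which continues the signal's slope across the boundary).
  Even reflection was tried first and rejected: it folds the signal's slope
  back on itself, and the resulting kink rings the narrow notches — about
  11 % residual RMS on a pure 50 Hz tone versus ~10⁻⁶ with odd reflection.
  The pad length is 3× the stage order or the stage's effective
  impulse-response length (time for the slowest pole to decay to 10⁻⁴),
  whichever is longer, capped at signal length − 1; the fixed "3× order"
  pad is hopeless for the 0.1 Hz high-pass, whose slowest pole decays over
  ≈ 560 samples at 250 Hz.
* **Analog front end.** The hardware places a first-order 0.15 Hz RC
  high-pass before each channel. `frontend_hp_phase_deg()` gives its phase
  arctan(fc/f); `frontend_phase_mismatch_deg()` propagates a ±1 % component
  tolerance through the corner and confirms that worst-case inter-channel
  phase mismatch stays far below the 2° alignment budget at all ECG
  frequencies ≥ 1 Hz.

## R-peak detection

`detect_r_peaks()` is a Pan-Tompkins-style envelope detector: zero-phase
5–30 Hz band-pass, derivative, squaring, centered 150 ms moving average,
then local envelope maxima accepted against an adaptive threshold
(`noise + 0.25·(signal − noise)`, both levels tracked with 1/8 exponential
updates) under a 250 ms refractory period. Each accepted envelope peak is
refined to the apex of a 40 Hz low-passed copy of the raw signal within
±60 ms — the low-pass halves the chance that a noise excursion on a
neighbouring sample steals the apex, which matters because a one-sample apex
error is 4 ms of RR error. An all-zero or beat-free signal returns an empty
annotation with a warning, not an error.

`heart_rate_series()` converts RR intervals to bpm; `hr_correlation()`
matches beats greedily by nearest R time within ±150 ms (half a refractory
period, so no double matching) and correlates the paired bpm series,
dropping and counting unmatched beats.

## Packet codec

The acquisition board frames each sampling instant as 26 bytes: header, 8 ×
24-bit two's-complement ADC codes in channel order, tail. The published
description fixes the length and content but not the sync bytes or byte
order, so the codec defaults — header `0xAA`, tail `0x55`, big-endian
samples — are explicit assumptions, configurable at every entry point.
`decode_stream()` resynchronizes byte-by-byte after corruption and reports
dropped bytes, resync runs and trailing remainder; appending bytes never
changes frames already emitted. `code_to_microvolts()` uses the
input-referred LSB `2·Vref / gain / 2²⁴` (0.0447 µV at Vref = 4.5 V,
gain = 12), and the throughput identity 26 × 250 × 10 = 65 000 bps < 115 200
baud (`serial_throughput_bps()`) is the real-time transmission margin.

## Known limitations

* The proximity assumption (identical $f$ on all channels) is taken as
  exact in the generator; real arrays see small amplitude gradients across
  electrodes, which averaging turns into slight morphology smoothing even
  when perfectly aligned.
* Only integer-sample channel delays are modelled; sub-sample misalignment
  degrades the gain continuously, and its effect here is bounded between
  the 0- and 1-sample cases rather than resolved.
* The RBJ notch width (Q = 30) and Butterworth orders are package defaults,
  not measured properties of any particular hardware.
* `hr_correlation()`'s greedy matching assumes both recordings run on a
  common clock; it does not estimate or remove clock drift.
* The frequency-response helper interpolates −3 dB crossings from sweep
  points; with fewer than ~10 points per decade the recovered corners
  inherit the sweep's granularity.
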