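---
title: "Methods: single-trial stopping latencies and frontal beta bursts"
author: "stopBeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial stopping latencies and frontal beta bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stopBeta)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the numerical and design decisions that were
genuinely open.

## The race model and its single-trial readout

A stop-signal trial is modeled as a race. The go process produces an
EMG-onset latency `t_on` from the go signal, drawn from an ex-Gaussian
(normal mean `muOn`, SD `sigmaOn`, plus an exponential tail `tauOn`),
and a key press follows after an electromechanical delay
`EMD ~ N(emdMean, emdSd)`. The stop process, launched by the stop
signal at delay SSD, cancels the motor command after a cancellation
latency `cancel ~ N(cancelMean, cancelSd)` truncated below at
`cancelMin`. With `t_c = SSD + cancel`:

* `t_c <= t_on`: Successful Stop without any EMG;
* `t_on < t_c < t_on + EMD`: Successful Stop with a *partial* EMG burst
  truncated at `t_c`;
* `t_c >= t_on + EMD`: Failed Stop, key press at `t_on + EMD`.

The defaults (`muOn = 200`, `sigmaOn = 30`, `tauOn = 60`,
`emdMean = 135`, `emdSd = 10`, `cancelMean = 160`, `cancelSd = 30`,
`cancelMin = 80`, all ms) were chosen once so that simulated cohort
means approximate the group means published for this task family (go
RT near 390 ms, EMG onset near 256 ms, cancellation near 160 ms);
those printed group means are the only calibration data available. The
SSD staircases (one per response direction) start at 200 ms, step by
50 ms (up after a Successful Stop, down after a Failed Stop) and clamp
at a floor of 0 ms with no ceiling; any 1-up/1-down staircase with a
continuous latency distribution converges to 50% stopping, which the
tests verify within ±2 percentage points over 480+ stop trials.

CancelTime — the single-trial stopping latency — is the interval from
the stop signal to the decline of the partial EMG burst. SSRT, the
classical latent estimate, is computed with the integration method:
go omissions are replaced by the maximum observed go RT, the
`ceiling(p·n)`-th order statistic of the sorted go RTs is taken at
`p = P(respond | stop)`, and the mean SSD is subtracted. Both
conventions (omission replacement, order-statistic quantile) follow
consensus practice; the method is expected to slightly overestimate the
generator's cancellation mean because response-side variability
(including the ~135-ms electromechanical delay) enters the go RT
distribution; the recovery test allows 20 ms for this.

## EMG synthesis and landmark detection

Detection chain (all defaults are the field-standard values): optional
58–62 Hz 4th-order Butterworth band-stop applied forward and backward
(zero phase), 50-ms centered RMS envelope (edges truncated), per-trial
threshold at baseline mean + 8 SD of the envelope between the fixation
and go markers (a zero-variance baseline falls back to a pooled SD,
with a message), burst peak at the global suprathreshold maximum after
go, onset backtracked to the first ≥5-ms run below 20% of the peak,
decline at the first run of 5 strictly decreasing milliseconds after
the peak, CancelTime = decline − stop with negative values excluded.
The "8 SD" is deliberately computed on the *envelope*, not the raw
rectified signal, so the threshold and the detected quantity live on
the same scale (the source description does not fix this choice).

The generator writes traces at 1000 Hz as band-limited (30–300 Hz)
noise — the spectral footprint of a surface-EMG interference pattern —
plus, when the race leaves a motor command, a burst of rectified
band-limited noise whose short-time RMS is normalized to 1, under a
deterministic envelope. The envelope rises as `(t/riseMs)^0.35` over
`riseMs = 150` ms (rapid initial recruitment, then slower growth; the
rise time exceeds the maximal electromechanical delay so partial bursts
are always still rising when truncated and therefore peak at the
cancellation time). Full bursts fall linearly over `fallMs = 100` ms.
Truncated bursts briefly derecruit (mirroring the rise for 15 ms) and
then collapse within 30 ms; the mirrored segment keeps the argmax of
the 50-ms-RMS-smoothed envelope centered on the truncation time, which
is exactly the property the CancelTime estimator relies on. Partial
motor commands shorter than 10 ms are below surface-EMG detectability
and are not synthesized. Baseline noise SD defaults to 0.1 of the
full-burst amplitude (a clean surface preparation); per-trial amplitude
jitter is lognormal with SD 0.15.

These shapes are engineered idealizations: real EMG envelopes carry
motor-unit granularity, amplitude nonstationarity and movement
artifacts that the generator does not emulate, so passing recovery
tests demonstrate the *estimator contract* (unbiased CancelTime within
10 ms, correlation with the true latency above 0.9 at the default SNR),
not robustness to real-world artifacts. A consequence of the smooth
envelope plus the centered RMS window is that the 20%-of-peak onset is
recovered within ~15–20 ms rather than sample-exactly; the onset
examples that are sample-exact are asserted directly on step and ramp
envelopes at the detector level.

## EEG synthesis, spatial filtering and beta bursts

Epochs (64 channels, 512 Hz, −2000 to +1520 ms around the stop signal
on stop trials and around go on go trials) contain spatially smooth
1/f background sources mixed through Gaussian scalp profiles, white
sensor noise (channel RMS ≈ 1), and — with probability
`burstProb = 0.5` on stop trials — a Hanning-windowed sinusoid at the
subject's peak beta frequency (drawn uniformly from 13–25 Hz), with
200-ms envelope width, source amplitude `snr = 2` times the background
RMS, injected through a mixing vector centered on F6 with Gaussian
spatial spread 0.25 (montage units). The burst peaks at
`cancel − lead + jitter` with `lead ~ N(30, 10)` ms and independent
25-ms jitter; this is the entire generative source of the
BurstTime–CancelTime coupling. The published burst probability of
roughly 20% conflates generation with detection, so generation defaults
to 0.5 and the detector is left to miss what it misses. No eye or
muscle artifacts, no continuous recordings and no biophysical forward
model are simulated.

Preprocessing: zero-phase band-pass 2–100 Hz plus notches at 60, 120
and 180 Hz implemented as symmetric (zero-phase) frequency responses
applied to reflection-padded epochs, optional polyphase resampling to
512 Hz, then common-average referencing.

The right-frontal spatial filter is derived per subject by GED on
Successful Stop epochs. For each integer frequency 10–25 Hz the epochs
are narrowband filtered (frequency-domain Gaussian, FWHM 5 Hz, unit
peak gain), channel covariances are averaged per trial over a stop
window (0–250 ms) and a baseline window (−1500 to −1000 ms), and
`S w = λ R_reg w` is solved with shrinkage
`R_reg = (1−γ) R + γ (trace(R)/n) I`, `γ = 0.01` (regularization is a
package choice; tiny, but it stabilizes near-singular baselines).
Candidates must rank in the top 6 by generalized eigenvalue (the
"decreasing variance" ranking is read as eigenvalue order) and have a
right-frontal activation pattern; where the published procedure used
visual judgment of scalp maps, the package scores
`mean |pattern| over ROI / mean |pattern| over all channels` against a
threshold of 1.2, with ROI {AF4, F4, F6, F8, FC4, FC6, FT8} and a
frontal fallback ROI (AFz, Fz, F1–F8) used only when no right-frontal
candidate exists anywhere. The activation pattern is computed as
`(S − R) w` — the stop-specific covariance excess — rather than `S w`:
in a planted-source model `S − R` is exactly rank one along the true
mixing, whereas `S w` is contaminated by the baseline term `R w`
(empirically this costs about 0.1 in pattern-mixing cosine). Validation
projects the epochs onto each candidate and requires a positive beta
power gain (dB) between the stop-to-SSRT window and the baseline; the
candidate with the highest gain wins, and "no right-frontal component"
is an explicit, expected outcome (participants were excluded for the
same reason in the source studies). Note that after common-average
referencing the recoverable pattern is the zero-mean projection of the
true mixing; planted-recovery checks compare against that projection.

Peak beta frequency is the argmax (13–25 Hz) of baseline-corrected
Morlet power between the stop signal and SSRT. Wavelets run 4–30 Hz on
a 1-Hz grid with `3 + 0.5·(grid index)` cycles — one concrete reading
of a "3 cycles increasing by 0.5" rule whose exact convention is
ambiguous; they are implemented as analytic frequency-domain Gaussians
with unit peak gain (spectral SD `f / n_cycles`), which the tests show
agrees with direct Gaussian band-pass filtering within 5% on white
noise. The dB baseline is −500 to −200 ms before the go cue (shifted
by the mean SSD for stop-locked epochs); exact spectral ties resolve
to the lowest band frequency and are flagged.

Burst extraction thresholds the analytic amplitude of the projected,
narrowband component: baseline amplitudes are pooled across all trial
types (−1000 to −500 ms before the stop signal on stop trials; mean
SSD − 1000 to mean SSD − 500 ms after go on go trials), and a burst is
any maximal run strictly above median + 1.5 SD, with BurstTime at the
run's amplitude peak and width between the surrounding median + 1 SD
crossings (truncated at epoch edges, flagged). burst% counts trials
whose burst *peak* falls inside a window — the reading consistent with
single percentages per window — and a per-sample suprathreshold
timecourse is emitted alongside for timecourse-style figures. When a
window holds several bursts the largest height wins. Trial pairing
keeps Successful Stop trials with a valid CancelTime and at least one
beta burst between the stop signal and the EMG decline.

## The statistical toolbox

All statistics are assembled from explicit sums of squares or textbook
formulas, and the test suite cross-checks each against an independent
route (base R's `t.test`, `aov`, `cor.test`, design-matrix least
squares, and fine-grid quadrature): repeated-measures correlation
(subject intercepts, common slope,
`r_m = sign(b)·sqrt(SS_measure/(SS_measure+SS_error))`,
`df = N − k − 1`), paired and one-sample t with Cohen's d on the
differences, a JZS Bayes factor (Cauchy prior scale `sqrt(2)/2`, the
de-facto default; the source names no software or prior) integrated
adaptively over the Cauchy mixing variance, one-way repeated-measures
ANOVA (`F = MS_level / MS_(subject×level)`, partial eta squared, no
sphericity correction, matching the uncorrected df convention),
Pearson correlation with a t-based p, and Bonferroni `min(1, m·p)`.
Effect sizes carry the small/medium/large labels at the conventional
cutoffs.

## TMS condition

The generative TMS model is an invented stand-in, clearly flagged as
such: no quantitative disruption model is published. A pulse at
`tmsTimeMs = 80` ms after the stop signal elongates the cancellation
latency by `deltaMs · exp(−(t_pulse − burst_center)² / (2·tuningSd²))`
(defaults 20 ms and 40 ms) with the subject's burst center at
`cancelMean − burstLead`; both real and sham pulses add a nonspecific
`distractionMs = 12` ms to EMG onsets on pulse trials. Between-subject
dispersion (`betweenSdMuOn = 20`, `betweenSdCancel = 15` ms) is what
makes the between-subject contrasts (percent change in CancelTime
versus relative TMS time, i.e. pulse latency as a percentage of the
sham CancelTime) non-degenerate; without it every subject would be
identical. The model reproduces the qualitative signatures — positive
mean prolongation, a positive across-subject correlation with relative
TMS time, a real-vs-sham difference in the failed-stop latency proxy —
and nothing quantitative should be read into its parameters.

The failed-stop latency proxy takes, per retained SSD level, the
median Failed Stop RT minus the SSD, keeps levels with at least 3
observations in both conditions and pulse trials whose pulse preceded
the response by at least 60 ms, and aggregates across levels by a
trial-count-weighted mean (the weighting rule is a package decision;
the source states only "an aggregate measure across all stop signal
delays").

## Problem sizes, determinism and limitations

Cohort generation is bit-deterministic given the configuration seed
(all child seeds derive from it and stay below 2^31). The test and
benchmark runs use desk-scale sizes chosen to exercise every code
path with comfortable statistical margins: single sessions of 1440
go / 480 stop trials for behavioral recovery, 200 partial-burst trials
for CancelTime recovery, 20 independent seeds of 30-stop-trial sessions
for planted-source GED recovery, and cohorts of 8–10 subjects with
60–80 stop trials each for the repeated-measures correlation and the
TMS contrasts. Real studies in this family use comparable per-session
trial counts (240–1920 trials per subject).

Known limitations: the generator's stationarity (no fatigue, learning
or electrode drift), the idealized EMG envelope, the absence of
artifacts and of continuous (non-epoched) EEG, a Gaussian-in-time TMS
model with no empirical basis, and ROI-based topography scoring in
place of expert visual judgment. EDF/BrainVision ingestion is not
implemented; real data enter through the documented float32 + JSON
sidecar and TSV interfaces.
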