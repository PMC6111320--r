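---
title: "Multimodal stress markers and three-level classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal stress markers and three-level classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmark)
```

## The problem and the protocol

`stressmark` implements an offline analysis pipeline for detecting mental
stress from four simultaneously recorded biosignals: frontal EEG (Fp1, Fp2,
F3, F4 of the 10–20 system), single-lead ECG, differential trapezius EMG,
and the voltage output of a galvanic skin response (GSR) sensor, all sampled
at 1000 samples/s on an eight-channel portable amplifier.

The experimental protocol the pipeline analyses is a fixed session
structure: a 5-s maximum voluntary contraction (MVC) of the trapezius, 2 min
of eyes-closed rest (RS1), a psychosocial stressor (mental arithmetic with
adaptive time pressure: 3 min training, 6 min task), 10 min of relaxation in
a blue-lighted room, and a final 2-min rest (RS2). Self-perceived stress is
rated 0–4 at three points (after RS1, after the stressor, after
relaxation). Transitions between blocks default to 30 s; the block durations
alone sum to 1385 s.

All analysis is restricted to *regions of interest*: the central minute of
each resting block, the full stressor session, and the full relaxation
block — 630 non-overlapping 2-s epochs on the default timeline.

## The four stress markers

Each marker is computed per 2-s epoch and aligned on a common grid:

* **Relative gamma (RG).** Each EEG channel is zero-phase band-passed
  1–48 Hz (4th-order Butterworth), cut into 2-s epochs, detrended
  (least-squares line) and z-scored. Band powers in theta–alpha (4–13 Hz)
  and gamma (25–45 Hz) are estimated per channel and averaged across the
  four channels; RG is the gamma/theta–alpha power ratio.
* **Heart rate (HR).** The ECG is zero-phase band-passed 16–24 Hz
  (2nd order), which concentrates the energy of the QRS complex; R-peaks
  are local maxima of the magnitude above an adaptive threshold. HR is
  60/AvRR (AvRR = mean R–R interval) per 10-s epoch, then interpolated to
  the 2-s grid with a natural cubic spline through the 10-s epoch
  midpoints, clamped beyond the outer knots.
* **Trapezius activity (TA).** The lateral EMG electrode is subtracted
  from the medial one, the differential signal is zero-phase band-passed
  1–350 Hz (2nd order), and TA is the epoch RMS divided by the RMS over
  the MVC window.
* **Skin conductance (SC).** The GSR channel carries the sensor voltage;
  SC = 2 (AvVoltage − 0.5) / 100 000 Siemens, the affine calibration of
  the acquisition front-end, applied to the epoch mean voltage. The
  constants are inherited from the hardware platform and are applied
  verbatim; a mean voltage below 0.5 V yields a (flagged) negative SC.

### Numerical choices

* *Filter orders* are the orders of the designed filters; the zero-phase
  result is obtained by one forward and one backward pass, so the
  effective magnitude response is the squared Butterworth magnitude. The
  application step extends the signal by odd reflection before filtering
  and always filters the whole continuous channel before segmenting, so
  epoch interiors carry no start-up transient.
* *Spectral estimator*: Hann-windowed periodogram per 2-s epoch (0.5-Hz
  bins at 1000 samples/s); band power integrates the PSD over the
  half-open band [low, high). With this convention the band power of
  white noise is proportional to the nominal bandwidth, so the
  gamma/theta–alpha ratio of white noise converges to
  (45−25)/(13−4) = 20/9 — the long-run sanity check used in the tests.
  When verifying that limit, band powers are averaged across epochs
  *before* taking the ratio: the mean of per-epoch ratios carries a
  small-sample (Jensen) bias of a few percent, which we measured with an
  independent periodogram experiment and deliberately avoid.
* *R-peak picker*: threshold 0.5 × the rolling 95th percentile of the
  filtered magnitude (10-s blocks), refractory period 250 ms, larger peak
  wins inside the refractory window.
* *Degenerate epochs*: a constant channel cannot be z-scored and maps to
  zeros with a warning; missing HR epochs (no R–R interval onset) are
  excluded from the spline support rather than zero-filled, which avoids
  fabricating bradycardia.

## Group statistics

For grand averages, each subject's 630-epoch marker series is z-scored over
its full region-of-interest extent, smoothed with a 10-sample centred
moving average (window −4…+5, shrinking at the edges), and averaged across
subjects with the standard error of the mean. Pearson correlations between
grand-averaged curves use the Fisher z-transform interval
tanh(atanh r ± 1.96/√(n−3)) with n the number of epoch pairs (630);
smoothing-induced autocorrelation is deliberately ignored, matching the
reference analysis this package reconstructs (that choice is what makes the
printed interval bounds reproducible from r and n alone).

Between-period contrasts are paired t-tests (α = 0.05, two-sided, no
multiple-testing correction) across subjects of per-window marker means
over three 30-s windows: the last 30 s of RS1, the last 30 s of the
stressor, and the second-to-last 30 s of relaxation. The first of these
windows lies *outside* the central-minute region of interest, so the
statistics stage extracts markers over that extra 30-s region
(`regions_of_interest(timeline, include_rs1_late = TRUE)`); the canonical
630-epoch marker set is unchanged.

## Classification

Three classes are defined from the timeline: **stress** = minutes 7–8 of
the stressor session (counted from training start; the window of maximal
stress, inside the task part), **relax** = minutes 2–3 of the relaxation
block, **neutral** = the central minute of each resting block. At 2-s
epochs this gives a balanced 60/60/60 design, n = 180 per subject.

The classifier is linear discriminant analysis: per-class means, pooled
within-class covariance, equal priors (the design is balanced), and a fixed
ridge of 1e-6 × trace/dim on the covariance so degenerate cross-validation
folds cannot crash. Features enter as raw marker values — no per-subject
normalization — under both cross-validation schemes; this is deliberate,
because the collapse of leave-one-subject-out (LOSO) accuracy under
between-subject offsets is part of the phenomenon being modelled.
Accuracy intervals are the binomial normal approximation
1.96 √(p(1−p)/n); percent displays round half-up, the convention of the
reference tables.

Ties in the discriminant scores break deterministically by the fixed class
order stress < relax < neutral.

## The synthetic-session generator

No recordings are distributed with the reference analysis, so the package
ships a generator whose defaults encode the protocol conditions, and every
downstream claim is tested against it. A per-second arousal level
a(t) ∈ [0, 1] drives all modalities: baseline 0.15 during rest, linear rise
to 1 across the stressor, exponential decay toward a floor of 0.05 after
the stressor ends — time constant 20 s for the EEG/ECG/EMG dynamics and
180 s for skin conductance (sweat reabsorbs slowly) — and, for the EEG
modality only, a slow upward drift (+0.35 over the last 8 min of
relaxation) modelling the boredom effect in which relative gamma creeps
back up while a participant lies waiting.

Modality models: EEG = unit 10-Hz oscillation + 35-Hz oscillation with
programmed power ratio 0.4 + 1.6 a(t), plus white and AR(1) low-frequency
background; ECG = Gaussian R-wave templates (σ = 12 ms) at beat times
obtained by integrating the instantaneous rate 65 + 30 a(t) bpm (the true
beat times are retained as the oracle for the R-peak tests); EMG =
band-limited noise with RMS equal to (0.08 + 0.42 a(t)) × MVC RMS plus a
maximal burst inside the MVC window, split into medial/lateral channels
with common-mode noise that the differential montage cancels; GSR = voltage
affine in a(t) over 1–3 V plus small noise. Where the reference study
reports no effect sizes (bpm rise, EMG fraction, voltage range) the
defaults were chosen once as physiologically reasonable values and are
documented parameters of `sim_params()`, not tuning knobs.

Per-subject heterogeneity: each subject draws Gaussian offsets (default SDs
5 bpm, 0.25 ratio units, 0.06 MVC fraction, 0.3 V) that shift its coupling
ranges. Clamping to physiological bounds preserves the range *width*, so
within-subject class separation — and therefore leave-one-epoch-out
accuracy — is invariant to the offset magnitude, while between-subject
generalization degrades (LOSO ≈ 0.8 at the default scale versus ≈ 1.0 for
LOOCV).

Gaussian offsets alone cannot reproduce the chance-level LOSO regime: a
Gaussian always leaves some subjects near the pooled centre of the training
data, and those subjects classify well. The chance-level scenario is
therefore realized explicitly with `offset_marker_sets()`: constant
per-subject shifts of all four markers, collinear with the stress axis,
with symmetric multipliers ±2, ±4, …, ±10 separation units — every
subject's marker distribution is then disjoint from the pooled training
data of the others, leave-one-epoch-out accuracy is untouched (constant
shifts cancel within a subject), and LOSO falls to ≈ 1/3.

### What the generator does and does not emulate

It reproduces the timeline, the qualitative marker dynamics (gradual rise
under the stressor; fast post-stressor decay for RG/HR/TA; slow decay for
SC; late RG drift), realistic marker ranges, subject heterogeneity, and
exact ground truth for beats, MVC fractions and band-power ratios. It does
*not* emulate EEG artifacts (blinks, motion), true QRS morphology, heart
rate variability structure, electrode impedance effects, or hardware noise;
passing tests therefore demonstrate correctness of the *pipeline*, not
field performance on real recordings — on real data the within-subject
accuracies would be lower (the reference regime is ≈ 86%, not ≈ 100%).

## Problem sizes used by the test suite

The stochastic acceptance battery simulates 20 independent ten-subject
cohorts at the full 1000 samples/s and full timeline (≈ 25 min of recording
per subject) and runs marker extraction plus all cross-validation schemes
on each: large enough for the binomial bands used in the assertions, small
enough to run on a single CPU in minutes. Deterministic unit tests use a
proportionally shortened timeline where only the I/O or filter logic is
under test.

## Known limitations

* The SC calibration constants produce conductances on the 1e-5 S scale;
  they are applied verbatim from the acquisition platform without a
  physical-units audit.
* No multiple-testing correction across the marker/window t-tests, by
  design (each test at α = 0.05).
* Correlation intervals treat smoothed epochs as independent pairs
  (n = 630), again by design.
* The EDF importer is read-only, assumes a uniform sampling rate across
  signals, and takes the event timeline from a JSON sidecar (EDF itself
  carries no session events).
* Artifact detection/removal is out of scope; inputs are assumed to be
  movement-free recordings.
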