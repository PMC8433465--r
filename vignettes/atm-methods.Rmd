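---
title: "Automated template matching for cardiomyocyte beating signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated template matching for cardiomyocyte beating signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmbeat)
```

## The measurement and the classification problem

Cardiomyocytes cultured on an interdigitated electrode (IDE) array modulate
the electrode impedance as they contract and relax. Driving the array with a
10 kHz sinusoid and amplitude-demodulating the returned voltage yields the
*mechanical beating signal*: a slow (~0.6 Hz) periodic impedance-magnitude
time series. Pharmacological blockade of the hERG K⁺ channel (astemizole,
droperidol, sertindole, E-4031) delays repolarization and provokes
EAD-like extra contractions, visible as additional peaks inside a beat.
The classification problem is per-beat: is this valley-to-valley beat unit
rhythmic (one dominant peak) or arrhythmic (two or more)?

Automated template matching (ATM) answers it with a correlation test
against stored reference beats:

1. **Demodulate**: non-overlapping rectangular FFT windows over the raw
   carrier; the magnitude of the bin at the carrier frequency, scaled so a
   pure sinusoid of amplitude $A$ reads $A$, gives one output sample per
   window (12.8 ms by default).
2. **Condition**: a centred 5-point moving average, then cubic-spline
   upsampling by 10 (12.8 ms → 1.28 ms) so that peak and valley feature
   points can be localized precisely without distorting the profile.
3. **Segment**: adaptive-threshold valley detection cuts the trace into
   valley-to-valley beat units.
4. **Length-match**: a stored template rarely has the target beat's sample
   count, so it is prolonged by cubic-spline interpolation to (the smallest
   integer) $m$ times the target length and resampled by taking every
   $m$-th point — equivalently, the spline is evaluated at exactly the
   target number of uniform points across the template's support. Only
   duration is rescaled; there is no time warping.
5. **Correlate and decide**: the Pearson correlation
   $r(X,Y) = \mathrm{Cov}(X,Y)/\sqrt{\mathrm{Var}[X]\,\mathrm{Var}[Y]}$
   between the beat and the length-matched template is compared with a
   fixed threshold. In *rhythmic-template* mode a beat is arrhythmic when
   $r < 0.94$; in *arrhythmic-multitemplate* mode the best correlation over
   the arrhythmic templates is taken, and the beat is arrhythmic when
   $r_{\max} > 0.90$, the best-matching template being reported as winner.

Threshold calibration follows the same logic in reverse: given template
correlations with same-class and other-class beats, the threshold is the
other-class maximum rounded *up* to two decimals (`calibrate_threshold()`);
same-class correlations falling below it are reported as outliers rather
than silently absorbed, and calibration fails when the other-class maximum
reaches 0.99, i.e. when the classes are not separable at two-decimal
resolution.

## Decision conventions

Two boundary conventions are fixed for determinism and documented rather
than left open: in rhythmic-template mode *equality counts as rhythmic*
($r \ge$ threshold → rhythmic), while in multitemplate mode arrhythmia
requires *strict* excess ($r_{\max} >$ threshold). Ties between templates
resolve to the first. A zero-variance beat is labelled `unclassifiable`
and always counts as a mismatch in evaluation — never silently rhythmic.
The two template modes are kept strictly separate; the rhythmic template is
not consulted as a fallback in multitemplate mode.

## The adaptive valley detector

The source method names "valley detection by the adaptive threshold
algorithm" without an algorithm, so the detector here is specified in full:

* candidate valleys are strict local minima (plateaus count once, at their
  earliest index);
* over a rolling window (`baseline_window`, default 5 s) the local minimum
  $m$ and local amplitude $a$ are computed; a candidate survives only if it
  lies in the bottom band $v \le m + d\,a$ with `depth_fraction`
  $d = 0.25$;
* survivors must be separated by at least `refractory_fraction` (0.4) of
  the running median inter-valley interval; of two conflicting minima the
  deeper one is kept, ties keeping the earlier.

Because every quantity is relative to the local baseline and amplitude,
detection is exactly invariant under positive affine transforms of the
trace and tolerant of slow baseline drift. The pipeline applies it after
smoothing and upsampling, following the stated order of the processing
chain; this is a choice, not an established fact about the original
implementation.

## The synthetic-signal generator

No recordings are deposited, so validation uses a simulator
(`synth_trace()`) whose *statistical conditions are fixed defaults*: beat
period 1.563 s, peak level 6.758 and valley level 6.687 (arbitrary
impedance units — the unit of the magnitude axis is not specified by the
instrument convention, so the package treats it as a.u.), period jitter CV
0.01 (truncated normal, ±3 SD), additive white noise with SD 0.5% of the
beat amplitude (truncated at 5 SD), and a sinusoidal baseline drift of
0.002 a.u. over 60 s. Half a period of partial beat is prepended and
appended so recordings begin and end mid-beat, as real acquisitions do.

### Waveform shape

One beat on phase $\varphi \in [0,1]$ is a fixed composite, renormalised to
span exactly `[valley_level, peak_level]`:

* a **diastolic notch**: a raised-cosine well of depth 0.35 (relative) and
  full width 0.06 of the period, centred on the shared valley;
* a **systolic dome**: $0.15\,\sin(\pi\varphi)$;
* **contraction bumps**: a raised-cosine bump of width 0.35 centred at
  `rise_fraction` (0.40) carrying the main contraction, plus, for
  arrhythmic classes, one or two narrower (0.20) secondary bumps at the
  configured phase delays and relative amplitudes — the EAD-like extra
  peaks.

The notch deserves explanation, because a more obvious pulse shape (fast
upstroke, exponential relaxation) fails quantitatively. The relaxation tail
of such a pulse meets the next upstroke in an asymmetric corner; the
mandatory 5-point smoother then *shifts the trace minimum* by roughly 1.8
original samples (~23 ms), and under realistic noise the flat tail leaves
the minimum's position essentially unconstrained. Any detector restricted
to returning genuine local minima of the smoothed trace — which the
segmentation contract requires — would misplace valleys by tens of
milliseconds. A deep, narrow, *symmetric* well at the valley fixes both
problems at once: a moving average preserves the vertex of a locally
quadratic minimum exactly, and cubic splines reproduce it faithfully, so
valley localization stays within ±6.4 ms (half an original sample) across
noise levels from 0 to 2% of the beat amplitude. Physiologically the notch
reads as a stylized sharp diastolic dip; since the reference recordings
modulate impedance by only ~1% and their fine shape is not published, this
is an admitted stylization chosen for its measurement properties.

### Morphology set and what it emulates

`atm_morphologies()` provides five classes: rhythmic; canonical two-peak
(delay 0.72, relative amplitude 0.80) and three-peak (delays 0.60/0.80,
amplitudes 0.75/0.60); and *peak-shifted variants* of each (2-peak at 0.65,
3-peak at 0.55/0.76). The variants model the observed across-segment
variability of arrhythmic profiles — secondary peaks drifting in phase —
which is precisely what defeats arrhythmic multitemplate matching: a
shifted variant correlates below 0.90 with both canonical arrhythmic
templates, yet still below 0.94 with the rhythmic template, so the
rhythmic-template mode flags it while the multitemplate mode misses it.
With these defaults the class-correlation structure reproduces the regime
of the reference analysis: same-class beats correlate above 0.98,
rhythmic-vs-arrhythmic pairs fall in ≈0.78–0.89.

What the simulator does **not** emulate: dose–response pharmacodynamics,
electrode drift nonstationarity beyond a single sinusoid, beat-to-beat
morphology evolution within a class, missing/fused beats, measurement
dropouts, or the electrochemistry of the electrode–cell interface. Passing
the bundled tests therefore demonstrates correctness of the *algorithmic
chain* under controlled conditions, not clinical or assay-level validity on
real recordings.

## Numerical choices

* **Spline flavour**: `stats::splinefun(method = "fmm")` everywhere
  (upsampling, length matching). FMM end conditions reproduce cubic
  polynomials exactly, the property that matters for feature preservation;
  interior behaviour is identical to other standard cubic interpolants.
* **Smoothing edges**: the moving average shrinks its window at the trace
  edges instead of padding — no invented boundary values, no phase shift.
* **Demodulation windows**: non-overlapping and rectangular, with the
  carrier required to sit exactly on a DFT bin
  ($f_c \times T_{\mathrm{win}}$ integral). Misalignment raises an error
  instead of silently leaking power.
* **Threshold rounding**: calibration ceils to 2 decimals with a guard
  against binary-representation artifacts of `x * 100`.
* **Reported accuracies** round half *away from zero*
  (`round_half_away()`), the convention that matches printed rates such as
  74.25% from 60/233 mismatches; internal arithmetic stays at full
  precision.
* **Group summaries** use the sample SD ($n-1$), the convention for small
  numbers of segment replicates.
* **Degenerate inputs**: constant beats/templates raise errors (or
  `unclassifiable` labels at the classification layer); unequal-length
  correlation inputs are refused rather than silently truncated, since
  length matching is the method's point.

## Problem sizes and determinism

The bundled experiments run 240-beat mixed-morphology simulations (about
6.3 minutes of signal at 12.8 ms, upsampled tenfold), which complete in
about a second; the test suite uses 6–40-beat traces per property. All
randomness flows through explicit integer seeds (`sim_config(rng_seed=)`),
drawn-through deterministically: identical configurations are bit-identical,
and the pipeline writes provenance headers (package version, seed,
configuration hash) into every artifact.

## Known limitations

* The detector's valley-position accuracy is kernel-limited: after a
  64 ms moving average, sub-sample localization relies on the waveform
  having a sharp, symmetric diastolic feature. Signals whose valleys are
  genuinely flat (long diastolic rest at constant impedance) would
  localize less precisely, though classification — which depends on whole-
  beat correlation, not valley position to the millisecond — is barely
  affected.
* Length matching rescales duration linearly; beats whose internal timing
  is warped non-uniformly relative to the template (e.g. a late secondary
  peak in a short beat) lower the correlation by design. That behaviour is
  the method's stated mechanism, not a defect, but it means the arrhythmic
  multitemplate mode is fragile to peak-phase variability.
* Thresholds 0.94/0.90 are adopted as defaults from the reference
  calibration; for other cell lines or instruments they should be
  recalibrated with `calibrate_threshold()` on pilot segments.
* `evaluate_predictions()` treats ground truth as authoritative; with
  visual-inspection truth labels, label noise directly bounds attainable
  "accuracy".
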