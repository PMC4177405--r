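---
title: "popcal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popcal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcal)
```

# The problem

Population two-photon imaging with genetically encoded calcium indicators
(GECIs) reads out the activity of dozens to hundreds of layer-2/3 neurons
at once, but the somatic fluorescence one measures is not the cell's
signal alone: it is contaminated additively by the surrounding neuropil —
the out-of-focus mesh of axons and dendrites — and must be converted into
a fractional change (dF/F0) relative to a per-trial baseline before any
physiology can be claimed. `popcal` implements this analysis chain for the
standard visual-cortex experiment (blank / drifting-grating trials), the
downstream response statistics (responsiveness classification, preferred
direction, Fourier modulation, transient decay kinetics), the matching
histological quantification of indicator expression, and — centrally — a
forward simulator whose ground truth lets every stage be validated
quantitatively rather than by eye.

# Measurement model and correction

The measured somatic trace is modeled as

$$F_\mathrm{measured}(t) = F_\mathrm{cyto}(t) + r \cdot F_\mathrm{neuropil}(t) + \varepsilon(t),$$

and the analysis inverts it by subtraction:
`corrected = raw - r * neuropil` with a single global contamination ratio
`r = 0.7` (`correction_config()`). The neuropil trace for a cell is the
mean over all pixels within a 20 µm radius of the cell center, excluding
the full disk of every soma in the ROI set — not only the cell's own, so a
neighbor's transients cannot leak into the background estimate. `r` is
exposed as a flag because the optimal value varies across mouse lines and
optics; estimating `r` from data (e.g. by regression) is deliberately out
of scope.

Cells whose baseline fluorescence does not exceed the surrounding neuropil
baseline by more than 3% are excluded outright: for such cells F0 sits in
the noise of the subtraction and dF/F0 would be unreliable. The comparison
uses the *uncorrected* soma and neuropil means over the pre-stimulus
baseline windows of all trials (the rule must precede the correction it
gates, and the pre-stimulus window is the quantity F0 itself will use).
The margin is `>` (strictly more than 3%), so a cell at exactly 3% is
excluded.

dF/F0 is computed per trial: F0 is the mean corrected fluorescence over a
window immediately before grating onset — 2 s for fast (GCaMP6f-class)
indicators, 1 s for slow (GCaMP6s-class) — and `dff = (F - F0) / F0` over
that trial. All windows are half-open in frame start time
(`[onset - w, onset)`), which makes frame membership unambiguous at
window edges.

# Stimulus protocol and response statistics

The default `stimulus_protocol()` is the standard experiment: each trial
is a 4 s uniform-gray blank followed by a 4 s drifting sinusoidal grating
(1 Hz temporal frequency, 0.05 cycles/degree as metadata) in one of 8
directions; movies run at 15 Hz; 5 trials per direction. Trials are laid
end to end with directions cycling, so one session is 40 trials and 4800
frames.

**Responsiveness.** A cell is visually responsive when its trial-mean
dF/F0 exceeds 0.05 in at least one direction period *and* a one-way ANOVA
across the blank and the eight direction periods rejects at p < 0.01. The
ANOVA samples are per-trial period means — one scalar per trial per
period, giving 9 groups (the blank group pools all 40 trials; each
direction group has 5) — never per-frame values, which would inflate the
sample size by two orders of magnitude and invalidate the p-value. The
dF/F0 threshold is likewise evaluated on trial-mean period responses
rather than single-trial maxima, trading a little sensitivity for
robustness to single-trial noise. The ANOVA is computed directly from its
sums of squares with p from the F distribution; zero within-group variance
with unequal means maps to p = 0, and fully degenerate (all-identical)
input raises an error that the classifier converts to "non-responsive"
with a warning.

**Preferred direction** is the direction with maximal trial-mean
stimulus-period dF/F0; exact ties break toward the lowest direction index
so the result is deterministic.

**Population averages.** For display-grade averages of preferred
responses, cells with peak dF/F0 > 1 have their trial-averaged preferred
trace shifted by a whole number of frames so the maximum lands on the
nearest of the anchors 1, 2, 3 or 4 s after grating onset (cells respond
at different latencies depending on receptive-field structure); the
average is returned raw and with a centered 3-sample moving average.

**Modulation spectrum.** Per responsive cell, the mean-subtracted dF/F0
over the 4 s grating window is Fourier transformed with a rectangular
window and no zero padding, giving 0.25 Hz resolution; amplitudes are
one-sided and scaled so that the sum of squared amplitudes equals the
mean-subtracted signal energy (Parseval). The median across cells is
robust to a few outlier cells, and its largest non-DC bin is reported as
the modulation peak — at the grating's 1 Hz for drifting-grating-driven
populations.

**Fractions responsive** are computed per field of view and summarized as
mean ± sample (n−1) SD across fields, the convention behind "mean ± s.d."
population figures. The response distribution uses responsive cells only.

# Decay kinetics

Kinetics are estimated on trial-averaged responses (5 trials by default;
fewer is allowed but the averaging assumption weakens). Baseline mean and
SD come from the same pre-stimulus windows as F0; a cell enters the
kinetics pool only if its mean response during the last 1 s of the grating
exceeds baseline by at least 5 baseline SDs. With exactly zero baseline SD
(noise-free synthetic traces) the gate degenerates to "response above
baseline".

The half-decay time is the time for the baseline-subtracted trace to fall
from its last response peak to half that value, with the crossing located
by linear interpolation between the bracketing samples. Two
operationalizations needed fixing where the experiment's verbal
description is ambiguous:

* *"Last" peak.* When the response is modulated at the grating frequency,
  the peak is the maximum within the final grating cycle of the stimulus
  window; without modulation (fewer than 2 cycles per stimulus) it is the
  global stimulus-window maximum.
* *Reference time.* The decay is referenced from the peak itself. For
  fast indicators the trace falls below half peak *between* the last
  modulation peak (~0.75 s before grating offset) and the offset, so an
  offset-referenced definition would be negative or undefined exactly for
  the fastest cells — the cells of most interest. Referencing from the
  peak keeps the estimator well defined across kinetics regimes and
  coincides with the offset-referenced value whenever the response is
  sustained to the end of the grating.

Because each trial's decay tail extends into the next trial's blank
period, trial averaging for kinetics uses extended segments
(`direction_average_extended()`), dropping trials without a successor.
The estimator is invariant under affine brightness transforms
(`a * F + b`, a > 0), since the baseline is subtracted and both the gate
and the half-crossing are relative; the test suite verifies this and the
closed form `tau * ln 2` on synthetic exponentials across
`tau` in [0.1, 2] s against a 1 kHz dense-grid oracle, with bias shrinking
as the frame rate grows (15 → 30 → 60 Hz).

# The forward simulator

The simulator generates the study conditions end to end: spikes →
indicator fluorescence → neuropil contamination → noise → (optionally)
rendered movies, with every intermediate retained as ground truth.

* **Spiking** is an inhomogeneous Poisson process drawn by thinning. The
  rate is `baseline_rate` during blanks; during the grating it is
  `baseline + (peak - baseline) * g(direction - preferred) *
  (1 + m * sin(2 pi f t))`, clipped at zero, where `g` is a von
  Mises-shaped gain normalized to 1 at the preferred direction (the
  experiment constrains only that responses are direction tuned; the von
  Mises form is the field's standard circular tuning curve), `m` the
  modulation depth and `f` the grating temporal frequency. Defaults for
  tuned cells: baseline 1 spike/s, peak 20 spikes/s, concentration 4,
  modulation depth 0.6 — a strongly driven, clearly modulated visual
  neuron. Null (untuned) cells fire at baseline throughout.
* **Indicator kernel.** Each spike adds a difference-of-exponentials
  transient, peak-normalized and scaled by a per-spike dF/F amplitude;
  transients sum linearly and carry across trial boundaries as in a
  continuous recording. The decay time constant is solved numerically so
  the kernel's measured post-peak half-decay equals the model's
  `decay_half_time` exactly. Presets: fast (GCaMP6f-like) 0.14 s
  half-decay, 0.19 dF/F per spike; slow (GCaMP6s-like) 0.51 s, 0.25.
  These are simulator parameters chosen inside published in-tissue
  ranges, not claims about any preparation.
* **Neuropil** has baseline `neuropil_amplitude` (default 0.8) times the
  mean somatic baseline and fluctuates with half the population-mean
  dF/F, so contamination is correlated with the signal — the regime in
  which subtraction correction matters. Per-cell baselines are log-normal
  (CV 0.2) around 100 a.u.
* **Noise** is additive Gaussian with SD 5% of the soma baseline per
  frame by default; a photon-limited option scales the SD with the square
  root of the signal. The neuropil ROI measurement carries 1/5 of the
  somatic noise SD, reflecting its much larger pixel count.
* **Rendering** draws each soma as a bright ring with a dark (25%)
  nucleus, a spatially smooth neuropil texture everywhere (low-pass
  filtered spatial noise, mean 1, fluctuation 20%), and per-pixel noise.
  Somatic pixels are contaminated by `r_true` times the *mean-field*
  neuropil trace — physically, somatic contamination integrates
  out-of-focus neuropil over a wide volume, so it is smooth — which makes
  rendering invert exactly to the trace-level measurement model: mask-mean
  extraction reproduces the composed measured trace bit-for-bit at zero
  noise. Scene defaults are the standard acquisition: 512 × 512 pixels
  spanning 250 × 250 µm², somata of 6 µm radius with 3 µm nuclei, placed
  without overlap (bounded rejection sampling; impossible densities
  error out).

What the simulator does **not** emulate: brain motion, bleaching,
scattering/PSF optics, spatial receptive fields (spatial frequency is
carried as metadata only), spike-history dependence, and indicator
nonlinearity (supralinear summation of GCaMP at high rates). Passing
validation on simulated data therefore demonstrates correctness of the
*analysis* under the stated measurement model, not robustness to every
artifact of in vivo data.

The histology generator mirrors the fixed-tissue experiment: a red
channel with all somata (pan-neuronal counterstain), a green channel with
a labeled subset drawn as nucleus-excluded rings with log-normal
brightness (CV 0.5), and a separate bead field of 3.8 µm disks of known
brightness; a global `illumination` factor scales green and beads
together, emulating session-to-session excitation changes that bead
normalization must remove.

# Histology quantification

Somata are segmented by band-pass (difference-of-Gaussians) filtering at
the expected soma scale — the background Gaussian kept narrow (1.6 soma
radii) so a bright neighbor's negative side lobe cannot mask a dim cell —
followed by local-maxima detection above a robust (median + 3 MAD)
threshold, greedy suppression of maxima closer than 1.5 soma radii, and
center refinement by an iterated intensity-weighted centroid of the
background-subtracted smoothed image (symmetric for rings, hence
unbiased). Manual seed points bypass detection entirely, mimicking
analyst clicking. Brightness is the plain mean of the nucleus-excluded
ring mask; normalization divides by the mean brightness of detected
beads, which removes a global illumination scale exactly. Co-labeling is
greedy one-to-one nearest matching of green to red centers within one
soma radius (6 µm, exposed as a flag; the matching tolerance is an
analysis choice, not a measured quantity). Box-and-whisker summaries use
linear-interpolation quartiles (R type 7 — stated because the convention
changes values at small n) and whiskers of at most 1.5 IQR clamped to the
most extreme sample inside the fence.

# Numerical choices and conventions

* Times in seconds, lengths in µm, frame and trial indices 1-based in R
  code, pixel indices 0-based in serialized geometry; a pixel belongs to
  a mask when its center lies inside the region (half-open in radius).
* Movies are stored as multi-page 16-bit TIFF with a YAML sidecar
  carrying pixel size, frame rate and intensity scale; 16-bit integer
  data round trip losslessly. Tables (traces, results, ROI sets, ground
  truth) are CSV; configuration is YAML. Every pipeline run serializes
  its resolved configuration and a stage log next to its outputs.
* Kernel support is truncated where the transient falls below 1e-5 of
  its peak; the decay constant solver uses `uniroot` at 1e-12 tolerance.
* Seeds: every stochastic operation takes an explicit seed; a population
  simulation is bit-reproducible from one integer.

# Validation scale

The test suite validates the pipeline at sizes chosen to exercise the
statistics honestly on a desktop: the classifier's null calibration uses
2000 baseline-only cells under the full default protocol (the false-flag
fraction must stay within 3 Monte-Carlo standard errors of the 1%
nominal level); modulation-spectrum recovery uses 60 tuned cells;
parameter recovery uses 200 cells with a designed 30% tuned fraction
(binomial 95% interval, preferred direction within one 45° step for at
least 90% of tuned responsive cells); indicator ordering uses 20 seeded
paired simulations; histology uses 100-cell images. Headline numbers from
real preparations (percent-responsive fractions, in-tissue half-decay
means) are properties of animals and optics and are deliberately not
asserted — the package validates the estimators, not the biology.

# Known limitations

* The subtraction correction assumes a single global `r`; spatially
  varying contamination is not modeled or corrected.
* ROI selection on real movies is out of scope: ROIs come from the
  simulator truth, from files, or from the histology segmenter on fixed
  tissue; there is no automated in vivo soma detector.
* dF/F0 trials are normalized independently; slow drifts within a trial
  are not detrended.
* The exclusion rule's ~10% exclusion rate on real data is an empirical
  property of preparations and is not asserted anywhere; only the rule
  itself is.
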