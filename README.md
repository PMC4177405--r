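# popcal

Analysis of population two-photon calcium imaging in visual cortex, with
a ground-truth forward simulator.

Somatic fluorescence measured with genetically encoded calcium indicators
(GCaMP6-class) is contaminated by the surrounding neuropil and only
becomes interpretable as a fractional change against a per-trial
baseline. `popcal` implements the full analysis chain for the standard
blank / drifting-grating experiment, and a simulator that generates the
same experiment with known truth so every stage can be validated
quantitatively. It is aimed at imaging labs and methods developers who
need a tested, reproducible reference implementation of this pipeline.

## What it computes

Given measured somatic traces (extracted from a movie via ROI masks, or
simulated), for each cell:

- **Neuropil correction** — `F_corrected(t) = F_measured(t) − r·F_neuropil(t)`
  with a global contamination ratio `r = 0.7`; the neuropil trace is the
  mean over a 20 µm region around the cell excluding all somata. Cells
  whose baseline does not beat the neuropil baseline by >3% are excluded
  (their F0 is unreliable).
- **ΔF/F₀** — per trial, `(F − F₀)/F₀` with F₀ averaged over the 2 s
  (fast indicator) or 1 s (slow indicator) window before grating onset.
- **Responsiveness** — responsive iff trial-mean ΔF/F₀ > 0.05 in at
  least one direction period *and* one-way ANOVA across blank + 8
  direction periods gives p < 0.01 (samples are per-trial period means).
- **Tuning and modulation** — preferred direction (max trial-mean
  response, ties to lowest index), maxima-aligned population averages,
  and the median one-sided amplitude spectrum of preferred-stimulus
  responses (0.25 Hz resolution), whose non-DC peak sits at the grating
  temporal frequency for drifting-grating-driven cells.
- **Kinetics** — on 5-trial averages, cells whose response in the last
  1 s of the grating exceeds baseline by 5 baseline SDs get a half-decay
  time: time from the last response peak to the linearly interpolated
  half-peak crossing.
- **Histology** — soma segmentation (ring masks, nuclei excluded),
  somatic brightness, fluorescent-bead normalization, co-labeled
  fractions against a pan-neuronal counterstain, box/whisker summaries.

The simulator (`simulate_population`, `render_movie`,
`generate_histology_image`) produces inhomogeneous-Poisson spikes with
von Mises direction tuning and sinusoidal rate modulation,
difference-of-exponentials indicator kernels (fast/slow presets),
population-coupled neuropil, noise, rendered movies and two-channel
histology images — all with full ground truth.

## Worked example

```r
library(popcal)

protocol <- stimulus_protocol()   # 4 s blank / 4 s grating, 8 dirs, 15 Hz
sim <- simulate_population(40, protocol, scene = scene_model(n_cells = 40),
                           indicator = "fast", tuned_fraction = 0.5,
                           seed = 42)
proc <- process_traces(sim$measured, sim$neuropil_measured, protocol,
                       correction_config(indicator = "fast"))
results <- analyze_population(proc$dff, protocol, kept = proc$kept)
kin <- kinetics_analysis(proc$dff, results, protocol, "fast")
```

This prints (seed 42):

```
analyzable cells: 40 of 40
responsive: 20 (fraction 0.50)
median |preferred - true| = 12.3 deg
kinetics-gated cells: 20; half-decay 0.42 +/- 0.14 s
median-spectrum peak: 1.00 Hz
```

Half of the cells were simulated tuned and exactly those are classified
responsive; recovered preferred directions sit well within one 45° step
of the truth; and the median response spectrum peaks at the grating's
1 Hz, the signature of rate modulation at the drift frequency.

A command-line wrapper with `simulate`, `extract`, `analyze`,
`kinetics`, `histology` and `report` subcommands is installed at
`inst/cli/popcal` (run it with `Rscript`).

## The methods vignette

`vignettes/popcal-methods.Rmd` documents the measurement model and its
assumptions, every tunable parameter with units and defaults, what the
simulator does and does not emulate, the numerical conventions
(half-open windows, pixel-membership rules, tie-breaks, degenerate-case
conventions), and known limitations.
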