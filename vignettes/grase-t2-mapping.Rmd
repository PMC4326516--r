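---
title: "Methods: GraSE myocardial T2 mapping in graset2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GraSE myocardial T2 mapping in graset2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graset2)
```

This vignette explains the models behind `graset2`, the choices that were
genuinely open when the package was designed, and what its synthetic-data
experiments can and cannot say about real acquisitions.

## The acquisition and its timing arithmetic

A GraSE T2-mapping shot is an ECG-triggered turbo-spin-echo train in which
each of the `n_echoes` refocusing pulses produces one spin echo, read out
with a short EPI train (`epi_factor` k-space lines) and reconstructed into
its own image at effective echo time `first_te + (k-1) * delta_te`. One
shot runs per heartbeat, so a slice takes
`ceiling(matrix_phase / (sense_factor * epi_factor))` imaging heartbeats
plus one dummy, and the breath-hold is that count times the RR interval.
Four presets ship with the package (`grase_preset()`), read from a YAML
file: a nine-echo and a six-echo variant with one start-up echo, a
lower-resolution six-echo variant, and a seven-echo variant without
start-up echo. The six-echo variant is the clinical default.

Two timing quantities deserve a note:

* **Shot duration** is defined here as `(n_echoes + n_startup) * delta_te`
  — the span from excitation to the last acquired echo. For the nine-echo
  preset this gives 118 ms exactly; for the six-echo presets it gives
  82.6 ms, which vendor consoles round to 83 ms. We treat the printed 83
  as rounding rather than evidence of a different definition (e.g. one
  including the final readout tail), because the nine-echo value admits no
  such correction.
* **Black-blood inversion delay.** Dual-inversion nulling repeats every
  heartbeat, so the blood magnetization is in a cyclic steady state rather
  than fully relaxed. The delay at which inverted blood crosses zero is
  then `TI = T1 * log(2 / (1 + exp(-RR/T1)))` with blood T1 = 1200 ms at
  1.5 T; consoles compute this automatically from the heart rate. The
  closed form is the standard cyclic-steady-state null; it approaches
  `T1 * log(2)` (~832 ms) for slow hearts and is used here because no
  explicit formula is published for the sequence itself.

## Echo-train forward model (EPG)

`epg_echo_amplitudes()` implements the extended phase graph recursion over
configuration states `(F+(k), F-(k), Z(k))` with CPMG phase: excitation is
an ideal 90°, refocusing pulses are applied in quadrature, crushers are
assumed perfectly balanced, and each half echo-spacing applies T2/T1
relaxation (with equilibrium regrowth feeding only `Z(0)`) and a dephasing
shift of one state order. States are truncated at order `n_pulses + 2`,
which no pathway can reach, so the recursion is exact with finite memory.
The longitudinal states are kept complex for `k > 0`; forcing them real
silently removes the stimulated-echo pathway (a bug mode worth warning
about, caught during development by the isochromat cross-check below).

The test suite validates the recursion against an independent brute-force
isochromat simulation — explicit 3×3 Bloch rotation matrices over a
uniform grid of dephasing angles, for which the grid average of
`exp(i k theta)` vanishes exactly below the grid size — and the two agree
to better than 1e-6 relative error for constant flips between 45° and
180°.

**Slice profiles.** A slice-selective refocusing pulse flips the slice
centre by its nominal angle but the slice edges by much less. The train
signal is therefore the profile-weighted mixture of constant-flip EPG
trains (`slice_profile_echo_train()`). Because the vendor's pulse profiles
are unpublished, the two non-ideal profiles are declared stand-ins chosen
once for qualitative fidelity:

* `"slr_optimized"` — near-rectangular, `180 - 15 * x^12` over 33
  positions (about 95% of weight within 170–180°), emulating optimized
  Shinnar–Le-Roux refocusing;
* `"suboptimal"` — Gaussian, `60 + 120 * exp(-x^2 / (2 * 0.35^2))`,
  peaking at 180° with wings to ~60°.

With these defaults the package reproduces the qualitative phenomenology
that motivates careful protocol design: under the suboptimal profile a
least-squares fit of a seven-echo train without start-up echo
overestimates T2 = 52 ms by tens of percent; discarding the first train
echo (the start-up echo of the six-echo variant) removes most of the
bias; the optimized profile is accurate to well under 1 ms either way.
Only the direction and ordering of these effects is asserted — their
magnitudes depend on the invented profiles.

**EPI readout.** Static-field (T2') dephasing is refocused only at each
spin-echo centre, so off-centre EPI lines are attenuated by
`exp(-|tau|/T2')`. `epi_t2star_attenuation()` summarizes this as a
centre-profile amplitude factor applied equally to every echo — equal,
because each 180° pulse re-refocuses the dephasing, so the factor does not
compound along the train. In the noiseless limit this rescales S0 and
leaves fitted T2 unchanged; the in-vivo T2 underestimation attributed to
EPI readouts arises from B0 inhomogeneity interacting with the readout,
which this amplitude-level model deliberately does not simulate.

## Magnitude noise and the likelihood fit

Root-sum-of-squares combination of L coil channels with per-channel
Gaussian noise sigma makes the measured magnitude noncentral-chi
distributed (`dncchi()`, Rician at L = 1). Numerical choices:

* the density is evaluated in log space with exponentially scaled Bessel
  functions; beyond `x = 1e5` (where `besselI` loses precision) a uniform
  asymptotic expansion of `log I_nu` takes over;
* the exponent is combined analytically to `-(m-a)^2 / (2 sigma^2)` —
  keeping `-(m^2+a^2)/(2 sigma^2)` and `+ m a / sigma^2` separate
  cancels catastrophically at high SNR and makes the likelihood surface
  jagged enough to break optimizers;
* sigma is either supplied or estimated from a signal-free background via
  the second moment, `sigma = sqrt(mean(m^2) / (2 L))`;
* the effective channel count L is a user parameter (default 1): real
  parallel-imaging noise is spatially varying and correlated, which the
  model does not represent.

`t2_fit(method = "mle")` maximizes the summed log density over
`(S0, T2)` with `L-BFGS-B`, T2 bounded to [1, 1000] ms (1000 ms doubles as
the display ceiling; 0 is reserved for non-fitted pixels), S0 bounded to
twice the largest observed magnitude. The start is a log-linear fit with
magnitudes floored at `sigma / 2` — cheap and robust — and the optimum is
never allowed to fall below its initializer. Pixels where the optimizer
fails fall back to nonlinear least squares and are flagged, so maps stay
complete as on a scanner console. All-zero series are flagged, not
errors. Fitting involves no randomness, so maps are bit-reproducible.

The suite verifies the fitter against an exhaustive likelihood grid
search (0.25 ms / 0.25 amplitude-unit resolution) and, by Monte Carlo,
that the likelihood fit removes most of the noise-floor bias that makes
log-least-squares overestimate T2 on low-SNR magnitude data.

## Synthetic phantoms

`generate_stack()` renders a six-tube MnCl2-style phantom; doped water
has T1 about ten times T2 at 1.5 T, so tubes default to `t1_rule =
"10x_t2"`. The default tube set {40, 50, 55, 60, 80, 120} ms spans the
myocardially relevant range (healthy ~52 ms, acute injury ~75–90 ms); the
actual concentrations used on the bench are not published, so these are
stand-ins. `generate_cardiac()` renders an annular left ventricle with a
per-AHA-segment T2, a signal-free cavity (emulating black blood) and zero
background (emulating fat suppression).

The SNR knob is referenced to the brightest compartment's first-echo
amplitude — the image SNR one would measure — and sets
`sigma = amplitude / snr`. Noise is drawn independently per pixel and
echo from the declared noncentral-chi law (verified distributionally by a
KS test in the suite); a fixed seed gives bit-identical stacks. What the
phantoms do *not* emulate: anatomy beyond an annulus, cardiac or
respiratory motion, partial-volume mixing beyond pixel quantization, flow,
B0/B1 inhomogeneity, and spatially varying coil noise. Passing recovery
tests on these phantoms therefore demonstrates correctness of the
estimator chain under its own assumptions, not robustness to the
physiological confounders that dominate in vivo.

## Segmental analysis

Contours are 0-based pixel-coordinate polygons with pixel centres at
integers; membership is a point-in-polygon test on pixel centres
(`mgcv::in.out`). Angles are measured about the endocardial centroid from
the ray through the anterior RV insertion point, sweeping through the
septum — counterclockwise in a standard short-axis display (anterior up,
septum image-left). Basal and mid slices get six 60° sectors in the order
anterior, anteroseptal, inferoseptal, inferior, inferolateral,
anterolateral; apical slices get four 90° sectors with the septal sector
centred on the septum (boundaries offset −15°). A pixel exactly on a
boundary joins the lower-numbered segment (implemented with a 1e-9-radian
snap so the rule is deterministic in floating point). Segment 17, the
apical cap, is not used.

Two global aggregation rules exist in practice and are both reported:
the **segment-mean rule** (unweighted mean of segment means, population
SD of segment means) is the headline `global_mean`/`global_sd`, because it
exactly reproduces the worked example shipped with the package
(`example_segment_t2()`: 16 segment values aggregating to 51.6 ± 3.3 ms);
the pixel-weighted mean and SD are returned alongside, since some
published global values are consistent only with pixel weighting. The
report records which rule produced its headline numbers.

## Agreement statistics

`bland_altman()` uses the standard conventions: mean difference, 95%
limits of agreement at mean ± 1.96 × SD of differences, sample SD with
n − 1. `interstudy_experiment()` wires the whole pipeline into a
repeated-examination design: per synthetic subject, per-segment T2 is
drawn around a subject mean (defaults: population 52 ± 2 ms between
subjects, 1.5 ms between segments — values chosen once as typical of
healthy myocardium at 1.5 T), two visits are rendered with independent
noise, fitted, summarized by global T2, and the pairs fed to
Bland–Altman. The suite checks the contracts this design implies:
identical seeds give perfect agreement, independent visits are unbiased,
and the limits of agreement widen monotonically as SNR drops. Subject-
and segment-level pairing are both available, since reproducibility can
be quoted either way.

## Problem sizes and runtime

The test suite and acceptance script run on reduced grids chosen to keep
the whole suite under two minutes on one CPU while leaving every
statistical check well-powered: tube phantoms on 60×90 grids (~200 pixels
per tube), cardiac phantoms on 64×64 (~640 myocardial pixels), 500–1500
Monte-Carlo replicates for bias checks, and 8 synthetic subjects for the
reproducibility experiment. The phantom-agreement benchmark in
`scripts/acceptance.R` uses the full 176×168 acquisition matrix (~600
pixels per tube). Defaults in the package itself always use the full
acquisition geometry.

## Known limitations

* The refocusing profiles are qualitative stand-ins; only directions and
  orderings of profile effects are meaningful.
* Effective channel count L is global and constant; parallel-imaging
  g-factor noise is not modelled.
* No motion, flow, off-resonance or multi-exponential decay; the CPMG
  reference is itself simulated (ideal 180° refocusing, 32 × 10 ms).
* DICOM input is not supported; the on-disk interface is 4D NIfTI with a
  JSON sidecar for echo times and noise metadata.
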