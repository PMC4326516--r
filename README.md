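# graset2 — myocardial T2 mapping with gradient-spin-echo acquisitions

Quantitative myocardial T2 mapping detects myocardial edema — the common
signature of acute infarction, myocarditis and takotsubo cardiomyopathy —
by measuring the transverse relaxation time T2 pixel by pixel, instead of
relying on qualitative T2-weighted images. One fast way to acquire the
required multi-echo data in a single breath-hold per slice is a hybrid
gradient-and-spin-echo (GraSE) sequence: an ECG-triggered black-blood
turbo-spin-echo train in which every spin echo is read out with a short EPI
train and reconstructed into its own image at its effective echo time.

`graset2` is an R toolkit for working with such acquisitions. It is aimed
at MR physicists and image-analysis researchers who need to

* encode the protocol timing arithmetic (echo times, shot duration,
  heartbeats per slice, breath-hold length, dual-inversion blood-nulling
  delay),
* forward-simulate the echo train with an extended phase graph (EPG) model
  that captures the stimulated-echo contamination caused by imperfect
  slice profiles — the dominant source of T2 overestimation in multi-echo
  trains,
* estimate T2 maps by maximum likelihood under the correct magnitude noise
  law (Rician for one channel, noncentral chi for phased-array data),
* validate against a dense CPMG reference on synthetic tube phantoms, and
* report regional myocardial values on the AHA 16-segment model with
  Bland–Altman reproducibility statistics.

## The model

A pixel's magnitude series over the reconstructed echoes follows a
mono-exponential decay,

    S(TE_k) = S0 · exp(−TE_k / T2),   TE_k = TE_1 + (k−1) · ΔTE,

but the *measured* magnitude m_k of an L-channel root-sum-of-squares image
is noncentral-chi distributed around it:

    f(m | a, σ, L) = m^L / (σ² a^{L−1}) · exp(−(m−a)²/2σ²) · e^{−ma/σ²} I_{L−1}(ma/σ²),

with a = S(TE_k) and I_{L−1} the modified Bessel function (L = 1 is the
Rician law). At low SNR this density has a noise floor that least-squares
fitting mistakes for slow decay; `t2_fit()` therefore maximizes the exact
log-likelihood

    ℓ(S0, T2) = Σ_k log f(m_k | S0 e^{−TE_k/T2}, σ, L)

over (S0, T2), initialized from a log-linear fit and refined by bounded
quasi-Newton search (T2 ∈ [1, 1000] ms). Log-least-squares and nonlinear
least-squares fits are available as baselines, and `fit_map()` runs the
fitter over a masked image.

The forward model is an EPG recursion over configuration states
(F+, F−, Z): refocusing pulses below 180° store magnetization
longitudinally and return it as stimulated echoes, so a train acquired
with a poor slice profile decays *slower* than exp(−TE/T2) and its fitted
T2 is biased high. A start-up echo (acquired, then discarded) absorbs most
of that bias — the package reproduces both effects and their mitigation
by optimized refocusing profiles.

## Worked example

Simulate a mid-ventricular short-axis slice with known per-segment T2,
fit the map by maximum likelihood, and report the AHA segments:

```r
library(graset2)

protocol <- grase_preset("6Ec")     # the clinical six-echo variant
protocol
#> GraSE protocol '6Ec'
#>   echoes: 6 reconstructed (+1 start-up), delta TE 11.8 ms
#>   echo times: 23.6, 35.4, 47.2, 59.0, 70.8, 82.6 ms
#>   shot duration: 82.6 ms;  heartbeats/slice: 13 (incl. 1 dummy)
#>   matrix 176 x 168, voxel 2.0 mm, slice 10.0 mm, EPI 7, SENSE 2
#>   refocusing profile: slr_optimized

spec <- phantom_spec("cardiac", t1_rule = 1000, snr = 50, seed = 7)
phantom <- generate_cardiac(spec, protocol,
                            segment_t2 = c(55.5, 57.1, 50.2, 50.2, 54.6, 49.2),
                            slice_level = "mid")
map <- fit_map(phantom$stack, mask = phantom$labels > 0, method = "mle")
labels <- assign_segments(phantom$segment_model, dim(phantom$labels))
segment_report(map, labels)
#> global T2: 52.9 +/- 3.0 ms (segment-mean rule; pixelwise 52.9 +/- 3.7 ms)
#>  segment              name mean  sd n_pixels
#>        7      mid anterior 55.2 2.1      204
#>        8  mid anteroseptal 57.2 2.2      202
#>        9  mid inferoseptal 50.4 2.0      204
#>       10      mid inferior 50.2 1.9      198
#>       11 mid inferolateral 54.9 2.2      202
#>       12 mid anterolateral 49.2 2.0      199
```

The six per-segment means recover the simulated truth (55.5, 57.1, 50.2,
50.2, 54.6, 49.2 ms) to within a few tenths of a millisecond at SNR 50,
and the global value uses the segment-mean rule (unweighted mean of
segment means, population SD). A single pixel fits the same way:

```r
te <- echo_times(protocol)
t2_fit(phantom$stack$volumes[66, 88, ], te, noise = phantom$stack$noise)
#> T2 fit (mle): T2 = 50.37 ms, S0 = 97.41
```

`print`, `summary`, `coef`, `predict`, `residuals`, `logLik`, `plot` and
`simulate` methods are available on the fit object.

A thin command-line front end is installed with the package
(`exec/graset2`): `graset2 protocol show 6Ec`, `graset2 simulate phantom
--kind tubes --snr 50 --seed 1 --out ph`, `graset2 fit --input ph.nii
--method mle --out map.nii`, `graset2 agree --a a.csv --b b.csv`, and so
on.

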