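---
title: "Frequency-domain FLIM of NADH and PPIX: models, generator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain FLIM of NADH and PPIX: models, generator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fdflim)
```

## The measurement model

A continuous-wave laser, intensity-modulated at `f = 10 MHz`, excites the
tissue. Fluorophores respond at the same frequency, but the finite decay time
`τ` delays the emission by a phase `φ` and damps its relative amplitude by a
modulation factor `m`. For a mono-exponential decay at angular frequency
`ω = 2πf`:

$$\tan\varphi = \omega\tau, \qquad m = \frac{1}{\sqrt{1 + (\omega\tau)^2}}.$$

The camera integrates the emission at `K = 16` equally spaced detector phase
offsets `θ_k = 2πk/K`, so frame `k` has expectation

$$I_k = I_0\,\bigl(1 + m\,\cos(\theta_k - \varphi)\bigr).$$

`demodulate()` inverts this with the single-bin DFT estimator
(`C = (2/K)ΣI_k cosθ_k`, `S = (2/K)ΣI_k sinθ_k`), which is *exact* on
noiseless sinusoids for any `K ≥ 3` because of discrete orthogonality — one
of the package's property tests. We model each stored frame directly as the
homodyne intensity at offset `θ_k`; the camera's internal two-charge-bin tap
architecture is abstracted away, since no bin-level parameters are published
for it.

The instrument itself adds a phase offset and a modulation gain.
`calibrate()` separates these with a reference target of known lifetime
(default: an ideal scatterer, `τ_ref = 0`, since the actual reference
material of the instrument is unpublished); calibration is global — a single
offset/gain pair — rather than per-pixel. `reconstruct_map()` then converts
the calibrated phase to the **phase lifetime** `τ_φ = tan(φ)/ω`. The
modulation lifetime `τ_m = √(1/m² − 1)/ω` is exposed as a diagnostic but
never enters the pipeline, mirroring the instrument's published practice of
using the phase only. Calibrated phases outside `[0, π/2)` — slightly
negative values arise from shot noise around `τ ≈ 0` — are marked invalid
rather than wrapped: wrapping would alias them into enormous lifetimes.

The frequency is matched to PPIX: `τ_opt = 1/(2πf) = 15.9 ns` sits at the
apex of the phasor semicircle where lifetime resolution is best. NADH
lifetimes (0.4–4 ns) are far from the optimum, so NADH estimates carry more
variance by design; the phasor module therefore flags near-isotropic NADH
clouds as ill-conditioned instead of suppressing them.

## Phasor analysis

The phasor `(g, s) = (m cosφ, m sinφ)` maps every mono-exponential decay
onto the universal semicircle `(g − ½)² + s² = ¼`; a mixture maps to the
intensity-weighted average of its component phasors, i.e. onto the chord
between them. `fit_chord()` fits that chord by total least squares (the
principal axis of the `(g, s)` covariance — both coordinates are equally
noisy, so ordinary regression of `s` on `g` would be biased), intersects it
with the semicircle and reads off the two component lifetimes via
`τ = s/(gω)`. The analysis is quantitative where the original reading of the
phasor plots was qualitative; the outputs are labelled chord estimates, not
fitted decay amplitudes, and a cloud with principal-axis ratio below 1.5 is
declared ill-conditioned rather than decomposed.

`solve_long_fraction()` inverts the apparent phase lifetime of a
two-component mixture in closed form,

$$\alpha = \frac{t g_2 - s_2}{(s_1 - s_2) - t(g_1 - g_2)}, \qquad
t = \omega\,\tau_\text{target},$$

and the package tests verify `solve_long_fraction` ∘
`apparent_phase_lifetime` = identity to 1e−10.

## The synthetic cohort generator

No deposited raw data exist for this kind of study, so the generator *is*
the study design for every downstream stage. Its defaults encode the study
conditions:

* **Inventory** (`default_inventory()`): 42 samples from 21 patients;
  tissue counts NPL 2, REA 5, INF 12, NEC 7, TUM 16; 21 ALA+ / 21 ALA−;
  grade partition LGG 3 patients (7 samples), HGG 14 (24), MET 4 (11).
* **Decay components**: PPIX mixes 16 ns with 1.9 ns; NADH mixes bound
  4.0 ns with free 0.4 ns. The bound-NADH default sits at the top of the
  published 1–4 ns range so that every tissue-level NADH median (up to
  2.5 ns) is reachable as a free/bound mixture. Vessels exceed that bound
  and are therefore modelled as distinct mono-exponential emitters at
  5.5 ns; necrotic cores use 0.7 ns NADH and a 40% PPIX reduction.
* **Group lifetimes**: each sample draws one apparent lifetime per channel
  from a lognormal whose median equals the group target and whose quartile
  ratio matches the target interquartile range
  (`sdlog = log(q75/q25)/(2·z_{0.75})`). Published quartiles are mildly
  asymmetric around their medians, which a two-parameter lognormal cannot
  reproduce exactly; the law preserves the *median* (the quantity all
  recovery checks read) and the quartile ratio. Draws are clipped to the
  feasible mixture range `[τ_short + 0.05, τ_long − 0.05]` ns; clipping acts
  only in the tails, so medians are unchanged — with one documented
  exception: the non-pathological PPIX target (1.9 ns) coincides with the
  short PPIX component, so NPL PPIX medians land at ≈ 1.95 ns.
* **Conditioning modes**: the marginal summaries by tissue type and by ALA
  status cannot both be matched exactly by one generative law, so the
  generator has two explicit modes — `"tissue"` (PPIX and NADH follow the
  tissue class) and `"ala"` (PPIX follows the ALA status, NADH the tissue
  class). Non-pathological samples always use NPL parameters in both modes.
* **Within-sample structure**: the published analysis gives no
  within-sample variance, so pixels jitter around the sample lifetime with
  a lognormal CV of 0.05 (a free choice, exposed in the config). Samples
  occupy random ellipses smaller than the field of view; intensity is a
  per-channel photon budget (default 2000 counts/frame inside the sample,
  5 outside) standing in for the instrument's per-sample auto-exposure,
  whose saturation behavior is unpublished. Shot noise is Poisson.
* **Instrument**: phase offset 0.2 rad, modulation gain 0.9 (any values
  with gain ≤ 1 behave identically after calibration; gains above 1 would
  clip the homodyne intensities of short-lifetime emitters at zero).
* **Reproducibility**: every sample uses an RNG stream derived from
  `(seed, row index)`, so cohorts are independent of generation order.

What the generator does **not** emulate: realistic vasculature morphology,
optical scattering and absorption, spectral bleed-through (FAD), histology
co-registration, or any within-patient correlation of lifetimes. Passing
recovery tests therefore demonstrates that the *pipeline* is correct and
unbiased under the stated generative assumptions — not that the biological
effect sizes would replicate in new tissue.

## Post-processing and statistics

Masking keeps a pixel if it is inside the segmentation, reconstructs
validly, has `τ` below the channel threshold (NADH < 5 ns, PPIX < 17 ns —
just above the highest physically expected lifetimes, so vessels fall out
of NADH maps) and intensity at or above the noise floor (dark mean + 2 SD
when dark statistics exist, a fixed count level for synthetic data). From
the intersection of both channels' valid masks, 100 random pixels per sample
are drawn **once** and reused for both channels — the classifier consumes
colocalized pairs, which requires a shared coordinate set — making every
sample contribute equally regardless of physical size.

Statistics operate on per-sample means of the 100 sampled values (pixels
within a sample are strongly correlated; treating them as independent would
inflate significance). Group summaries report median and 25/75% quantiles
with the type-7 linear-interpolation rule. Two-tailed Mann–Whitney U tests
compare groups: exact p by full enumeration when `n₁ + n₂ ≤ 12` without ties
(the cutoff keeps enumeration sub-second), otherwise the normal
approximation with midranks, tie correction and continuity correction. No
multiple-testing correction is applied, matching the replicated procedure —
a real limitation when all tissue pairs are scanned. A pooled-pixel mode
(`summarize_groups(..., pooled = TRUE)`) exists for sensitivity analysis.

## Classification

`rusboost()` implements random-undersampling boosting in the AdaBoost.M2
pseudo-loss formulation: a mislabel weight distribution `D(i, y)` over
observation/wrong-label pairs; per iteration each non-minority class is
randomly undersampled to the minority size (weight-proportional draws);
a depth-limited CART tree (`rpart`, depth 4 ≈ ≤ 20 splits) is fitted with
the current weights; the pseudo-loss
`ε = ½ Σ D(i,y)(1 − h(x_i, y_i) + h(x_i, y))` updates the weights with a
learning rate of 0.1 (30 learners by default — the ensemble's common
configuration; the original analysis does not state its hyperparameters).
Iterations with `ε ≥ 0.5` are discarded and the weights reset.

Cross-validation is fivefold and **patient-unspecific**: folds are drawn
uniformly over observations, so pixels of one sample appear on both sides of
a split. This is the replicated — and acknowledged optimistic — choice;
grouped folds are available via `group_by_patient = TRUE`. Datasets drop the
two non-pathological samples (too few to learn a class), which resolves the
apparent bookkeeping tension between the 4200 sampled points and the 4000
classified observations. Accuracy is observation-level; confusion matrices
are reported as counts and row-normalized percentages.

## Numerical choices and problem sizes

* Lifetimes are ns and frequencies Hz throughout; angles radians.
* Demodulation flags `dc = 0` pixels invalid instead of raising.
* Quantile convention: type 7 everywhere.
* Chord/semicircle intersections must satisfy the circle equation to 1e−9;
  an intersection with `g ≤ 0` reports an unbounded lifetime.
* Tests and the acceptance script generate cohorts at 64 × 64 px (the
  elliptical sample regions then hold on the order of 10³ valid pixels,
  comfortably above the 100-pixel draw) with 25 seeded cohorts per recovery
  check; the package default of 256 × 256 matches a desk-scale instrument
  field. CSV outputs fix numbers to 6 significant digits so reruns are
  byte-identical.
* TIFF I/O uses plain multi-page baseline TIFF with JSON sidecars; lifetime
  maps are stored as scaled unsigned 16-bit integers (≈ 5 · 10⁻⁴ ns
  quantization) with an explicit validity-mask TIFF, because the available
  TIFF writer has no float sample format.

## Known limitations

Single modulation frequency only (no multi-frequency global fitting); chord
decomposition is limited to two components; patient clustering is ignored by
both the statistics and the default cross-validation, as in the replicated
procedure; the generator's within-sample variance and artifact geometry are
stylized; and classifier accuracies on synthetic cohorts characterize the
generator's class separation, not clinical performance.
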