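# fdflim

Frequency-domain fluorescence lifetime imaging (FLIM) analysis of NADH and
protoporphyrin IX (PPIX) autofluorescence in brain tumor tissue.

## The problem

During fluorescence-guided brain tumor resection, patients receive
5-aminolevulinic acid (5-ALA) and tumor cells accumulate the fluorescent heme
precursor PPIX. Visible PPIX fluorescence is a powerful but binary and
observer-dependent cue. Macroscopic frequency-domain FLIM adds a quantitative,
concentration-independent axis: the *fluorescence lifetime*. A sinusoidally
modulated laser (f = 10 MHz) excites the tissue; the emission returns at the
same frequency, delayed by a phase `φ` and demodulated by a factor `m`. From
K = 16 phase-stepped homodyne frames the phase lifetime is

```
τ_φ = tan(φ) / (2πf)
```

with the system optimized near `τ_opt = 1/(2πf) = 15.9 ns`, matching pure
PPIX (~16 ns). The measured PPIX decay in tissue is a two-component mixture
of that 16 ns component with short (~1.9 ns) autofluorescence; NADH mixes its
free (~0.4 ns) and protein-bound (1–4 ns) forms. On the phasor plot
(`g = m·cosφ`, `s = m·sinφ`) mono-exponential decays sit on the universal
semicircle and mixtures sit on the chord between their components, so a
total-least-squares chord fit recovers both lifetimes.

The package implements, for users of such instruments and for method
development without clinical data:

* the homodyne forward model, exact DFT demodulation, reference calibration
  and phase-lifetime map reconstruction;
* phasor algebra: mixture phasors, apparent lifetimes, the closed-form
  long-component fraction, chord fitting and decay classification;
* the post-processing chain: segmentation masks, lifetime thresholds
  (NADH < 5 ns, PPIX < 17 ns), intensity noise floor, and 100 random
  colocalized pixels per sample;
* group statistics on per-sample means (median, quartiles, two-tailed
  Mann–Whitney U with exact enumeration for small groups);
* RUS-boosted decision trees (AdaBoost.M2 pseudo-loss with per-iteration
  random undersampling) for tumor grade (LGG/HGG/MET) and tissue type
  (REA/INF/NEC/TUM) classification under heavy class imbalance, with
  fivefold patient-unspecific cross-validation;
* a synthetic cohort generator that reproduces the study design — 42 samples
  from 21 patients with the full tissue/ALA inventory, group lifetime
  distributions realized as physical two-component decays, shot noise,
  sub-field sample shapes, vessel streaks (> 5 ns NADH) and necrotic cores
  (< 1 ns NADH).

## Worked example

```r
library(fdflim)

coh <- generate_cohort(cohort_config(mode = "ala", image_size = 64), seed = 1)
print(coh)
#> Synthetic FLIM cohort: 42 samples / 21 patients (mode = ala, seed = 1)
#> INF NEC NPL REA TUM
#>  12   7   2   5  16

run <- run_pipeline(coh, seed = 1)
print(run)
#> FLIM pipeline run: 42 samples, 4200 table rows (seed 1)
#> Group medians by ALA status (ns):
#>     group n_samples nadh_median_ns ppix_median_ns
#> 1 ALA_NEG        21       1.721916        2.75264
#> 2 ALA_POS        21       1.822593       12.58727
#> PPIX phasor chord: tau_short = 1.91 ns, tau_long = 16.05 ns

tests <- run$tests$ala
tests[tests$channel == "ppix", c("group1", "group2", "U", "p_value")]
#>    group1  group2 U      p_value
#> 1 ALA_NEG ALA_POS 1 3.606584e-08
```

Reading the output: each of the 42 samples contributes 100 randomly sampled
colocalized NADH/PPIX lifetime pairs (4200 rows). Samples with
surgeon-visible PPIX fluorescence (ALA+) show a much longer PPIX phase
lifetime (here 12.6 ns vs 2.8 ns median of per-sample means) — the
Mann–Whitney U test separates the groups decisively — while the pooled PPIX
phasor chord recovers the underlying bi-exponential decay: a long component
at ~16 ns and a short component below 2 ns.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/fdflim.R simulate --out cohort_dir --seed 5 --mode ala
Rscript inst/cli/fdflim.R run --cohort cohort_dir --out results_dir --seed 5
```

## Documentation

The methods vignette (`vignettes/fdflim-methods.Rmd`) describes the homodyne
model, the generator's assumptions and defaults, the statistical conventions
and the known limitations in detail; every exported function carries roxygen
documentation.
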