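# nucpatterns

Nucleosome positioning patterns around regulatory elements, from
MNase-seq fragment midpoints.

## What it is for

MNase-seq fragment midpoints approximate nucleosome dyads, but at
typical mammalian depths (~20 M reads / 2.7 Gbp) the per-locus signal
is too sparse to read positioning directly: the chance that a 200 bp
window holds even one read is only ~77%. The workable signal is the
**average nucleosome density profile** — smoothed midpoint density over
offsets −500..+500 bp, averaged over all instances of an anchor class
(a TF's predicted binding sites, ChIP-seq peaks, TSSs). This package is
for epigenomics analysts who want to go from fragments + anchors to:

1. smoothed, RPM-normalized, strand-aware average profiles
   (`aggregate_profile`) and per-locus density matrices
   (`per_locus_matrix`);
2. a small principal-component basis of recurring positioning
   patterns across anchor classes (`extract_basis`), with each profile
   decomposed as `w1·P1 + … + wK·PK` (`decompose_profile`), squared
   weights reading as composition ratios;
3. shape characterization: Morlet-wavelet scalograms and dominant
   pseudo-periods (`scalogram`, `dominant_period`), and nucleosome
   co-positioning matrices — cosine similarity of per-locus density
   between every pair of offsets (`coposition_matrix`);
4. prediction of neighbouring gene expression from patterns, by
   principal-component regression (`pcr_fit`) and by ridge regression
   over positions, `β̂ = (XXᵀ + λI)⁻¹Xy` (`ridge_fit`, `ridge_path`),
   both yielding an "ideal" positioning shape for expression.

A synthetic-data module (`simulate_dataset`, `simulate_profile_matrix`)
generates fragments, anchors and expression tables with planted pattern
structure (five shape families, 164 ± 12 bp fragments, Poisson
midpoints, 30% background), so the whole pipeline is testable without
sequencing data. See the methods vignette
(`vignettes/nucleosome-positioning-patterns.Rmd`) for the model and all
numerical choices.

## Core statistics

For the `1001 × C` matrix `X` of profiles (columns centered, unit
Euclidean norm), the pattern basis is the top-K eigenvectors of
`XXᵀ/(C−1)` (via SVD). Unit normalization makes the squared scores over
the full spectrum sum to 1, so `Σ_{i≤K} wᵢ²` is the fraction of a
profile reconstructed by K patterns (`reconstruction_fraction`).
Wavelet coefficients are inner products with
`ψ_{a,b}(x) = π^(−1/4) a^(−1/2) e^{iω₀(x−b)/a} e^{−((x−b)/a)²/2}`,
ω₀ = 6, with pseudo-period `a·4π/(ω₀+√(2+ω₀²))`.

## Worked example

```r
library(nucpatterns)

# 1. simulate a fragment-level dataset with planted pattern structure
cfg <- synthetic_config(elements_per_class = 20, depth = 120, seed = 42)
sim <- simulate_dataset(cfg)
track <- fragment_midpoints(sim$fragments)
nrow(sim$fragments)
#> [1] 17219

# 2. average density profile of the phased-array (+) anchor class
sel <- sim$truth$family == "phased_array" & sim$truth$sign == "+"
prof <- aggregate_profile(track, sim$anchors[sel, ], smoothing_config(30),
                          genome = sim$genome, label = "phased_plus")
prof
#> DensityProfile 'phased_plus': 1001 offsets [-500, 500], 10 anchor(s), sigma=30, RPM

# 3. its dominant periodicity, via the Morlet scalogram
dominant_period(scalogram(prof$values, wavelet_config(n_scales = 32)))
#> [1] 193.3791     # planted nucleosome repeat length was 186 bp

# 4. extract a 5-pattern basis from 516 simulated profiles
mix <- simulate_profile_matrix(n_profiles = 516, noise_frac = 0.10, seed = 42)
X <- build_profile_matrix(mix$profiles)
basis <- fix_basis_signs(extract_basis(X, K = 5))
basis
#> PatternBasis: K=5 patterns over 1001 offsets; signs fixed
#>   top-5 cumulative contribution ratio: 0.990
round(basis_similarity(mix$basis, basis)$containment, 3)
#> pattern_1 pattern_2 pattern_3 pattern_4 pattern_5
#>         1         1         1         1         1
decompose_profile(X[, 1], basis, label = "profile_1")
#> Decomposition 'profile_1':
#>   weights: -0.937 +0.242 +0.188 -0.127 +0.044
#>   reconstructed: 99.0%, remainder: 1.0%

# 5. regress simulated expression on the patterns
expr <- simulate_expression(mix, b1 = 1, b5 = 1, snr = 10, seed = 43)
pcr_fit(X, basis, expr$y)
#> PCRResult: R^2 = 0.911, Pearson = 0.954, Spearman = 0.956
#>   pattern weights: -1.048 -0.015 -0.075 +0.059 +0.911
round(ridge_fit(X, expr$y, lambda = 1, basis = basis)$weights, 3)
#> pattern_1 pattern_2 pattern_3 pattern_4 pattern_5
#>    -1.039    -0.020    -0.074     0.055     0.890
```

Reading the output: the extracted basis contains each planted shape
essentially completely (containment 1.000) and five patterns explain
99% of profile variance at 10% noise. Expression was planted on
patterns 1 and 5; both regressions put nearly all weight there (the
signs reflect the basis sign convention), and PCR explains ~91% of
expression variance at the simulated signal-to-noise of 10.

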