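---
title: "Methods: nucleosome positioning patterns from MNase-seq midpoints"
author: "nucpatterns authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome positioning patterns from MNase-seq midpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

MNase digestion of cross-linked chromatin followed by sequencing yields
(approximately) mono-nucleosome fragments whose midpoints estimate
nucleosome dyad positions. At realistic depths for a mammalian genome
(~20 million reads on ~2.7 Gbp, i.e. ~0.006 reads/bp) the per-locus
signal is too sparse to read positioning directly — under uniform
placement the chance that a 200 bp window holds even one read is only
about 77% (`coverage_probability(2e7, 2.7e9, 200)`). The standard remedy
is aggregation: average the midpoint density over hundreds or thousands
of instances of an anchor class (a transcription factor's predicted
binding sites, ChIP-seq peaks, TSSs), producing an average nucleosome
density profile over offsets −500..+500 bp from the anchor center.
`nucpatterns` implements that aggregation, a principal-component
decomposition of profile shapes into a small set of recurring
positioning patterns, frequency-domain and co-positioning
characterization of those patterns, and regression of neighbouring gene
expression on them.

## Density estimation

Midpoints are `floor((start+end)/2)` of each fragment; all coordinates
are 0-based, half-open throughout. Per anchor, midpoint counts in
`[center − 500 − 4σ, center + 500 + 4σ]` are scaled to reads per million
(RPM, using the library's total mapped fragment count, not the window
count), convolved with a Gaussian kernel of bandwidth σ truncated at
±4σ, and cropped to ±500 bp. The kernel is evaluated at half-integer
offsets `m − 0.5`, a continuity correction for integer-binned counts,
and renormalized to unit sum so smoothing conserves RPM mass.

Numerical consequences worth knowing:

* The half-integer kernel makes a unit impulse smooth to two equal
  maxima at offsets 0 and +1; mirroring all midpoints about the anchor
  center and flipping the strand reproduces the profile shifted by
  exactly 1 bp (up to the ~1e−6 tail of the 4σ truncation). Strand flips
  themselves (reversal of the 1001-vector) are exact involutions.
* σ defaults to 30 bp. No bandwidth is canonical; 30 bp suppresses
  per-bp shot noise at ~0.006 reads/bp while attenuating a 186 bp
  periodicity by only exp(−(2πσ/186)²/2) ≈ 0.6, so ±1-nucleosome peaks
  survive. It is a plain parameter everywhere.
* Anchors whose padded window would leave the chromosome are skipped
  (and counted), not zero-padded: zero-padding biases averages downward.
* Unstranded (`.`) anchors are treated as plus strand; minus-strand
  windows are reversed before averaging when `strand_aware = TRUE`.

## Pattern basis

Profiles are assembled as columns of a `1001 × C` matrix, each column
centered to mean 0 and scaled to unit Euclidean norm. The patterns are
the leading eigenvectors of the offset covariance `XXᵀ/(C−1)`, computed
via the SVD of `X` (a test asserts equivalence with the dense
eigenproblem). The unit-norm normalization makes the squared scores of
any column over the full component spectrum sum to exactly 1, so a
profile's squared weights on the top K patterns read directly as
composition fractions and `1 − Σwᵢ²` as the unexplained remainder.

Eigenvector signs are arbitrary; `fix_basis_signs()` pins each pattern
so its largest-magnitude element is positive ("the dominant feature
reads as high nucleosome density"). The verbal convention it
operationalizes is not algorithmic, so the applied flips are recorded
and reversible. K defaults to 5 but is a parameter, and contribution
ratios are always reported for the full spectrum. Equal-eigenvalue ties
keep first-occurrence order and emit a message. Bases from different
datasets are compared by squared inner products; the row sums
("containment" of one pattern in the span of the other basis) are the
reproducibility statistic used throughout.

## Shape analysis

Scalograms use the Morlet wavelet
`ψ_{a,b}(x) = π^(−1/4) a^(−1/2) exp(iω₀(x−b)/a) exp(−((x−b)/a)²/2)`
with ω₀ = 6, the conventional admissibility choice (configurable and
recorded in output headers, since no single value is canonical here).
The default grid is 64 log-spaced scales over [64, 1024] against unit-
step positions. Coefficients are inner products with the conjugated
wavelet over the integer window; the displayed view is the real part,
the per-scale power sums squared real and imaginary parts. Pseudo-period
conversion is the standard `period = a·4π/(ω₀ + √(2+ω₀²))` (≈ 1.033·a at
ω₀ = 6).

Two deliberate choices: patterns are mean-centered before the transform
— inside a finite window the truncated wavelet does not integrate to
zero at large scales, so a constant offset would otherwise leak spurious
large-scale power (a flat pattern now has exactly zero power) — and no
cone-of-influence masking is applied; edge effects at scales comparable
to the window are left visible and documented rather than hidden.

Co-positioning matrices are cosine similarities between all pairs of
offset columns of the per-locus density matrix. A high entry `(i, j)`
means loci carrying density at offset i tend to be the same loci that
carry density at offset j — nucleosome pairs that co-occur at single
loci, which averaged profiles cannot distinguish from alternating
subpopulations. Zero-norm columns get similarity 0 by convention and are
flagged.

## Expression regression

Genes associate with an anchor when the anchor center lies within
2 kbp of the gene body (distance 0 inside the body; the bound is
inclusive, so 2000 bp is in and 2001 bp is out; zero-length gene records
are treated as points). "Within 2 kbp of a gene" is read as the gene
body rather than the TSS because that is what the phrase says; TSS-only
association would be a different, stricter choice. Expression is
`log2(level + 1)` before averaging by default (averaging over genes is
scale-sensitive; the transform is surfaced as a parameter, not hidden),
and per-element means are centered across elements, after which no
intercept is fitted.

Principal-component regression regresses centered `y` on the pattern
scores `S = XᵀP`. The score columns are centered across elements as
well — equivalent to fitting and absorbing an intercept — which is what
makes the no-intercept model internally consistent and the identity
`R² = Pearson(ŷ, y)²` exact rather than approximate. The fitted "ideal"
positioning shape is `Pβ̂`.

Ridge regression solves `β̂ = (XXᵀ + λI)⁻¹Xy` over the 1001 positions
directly. With C elements < 1001 positions the system is
under-determined (the motivating description of it as "over-determined"
has the inequality backwards; the printed dimensions imply
under-determined, and that is what is implemented), so λ = 0 is refused
when `XXᵀ` is rank-deficient, with an error directing to λ > 0. When
C < W the equivalent dual form `X(XᵀX + λI)⁻¹y` is solved in C×C; primal
and dual agree to 1e−8 in tests. The default sweep is λ = 10⁻²..10³.
Note the estimator is a function of `(XXᵀ, Xy)`: duplicating every
column and response entry doubles both, so β̂ is unchanged at λ = 0, or
in general when λ is doubled alongside — the test asserts those exact
identities. Spearman correlations use average ranks on ties. Linear
solves use symmetric factorizations; no silent jitter is added.

## Synthetic data: what it emulates, and what a green test means

The generator states a world and stays there:

* Five intensity families over offsets x (baseline 1, amplitude A,
  defaults A = 0.6, NRL = 186 bp, dip width τ = 100 bp, trend width
  250 bp, holding inner period 160 bp and outer period 400 bp — the
  spacings a mammalian chromatin scientist would call typical):
  occupancy trend `1 ± A·exp(−x²/2·250²)`; on-motif single nucleosome
  `1 ∓ A·exp(−x²/2τ²)`; one-sided asymmetric array
  `1 + A·cos(2πx/NRL)·1[x>0]` (mirrored for the minus sign); holding
  `1 ± [A/2·cos(2πx/160)·exp(−x²/2·250²) + A/2·cos(2πx/400)]`; phased
  array `1 ∓ A·cos(2πx/NRL)`. These functional forms are this package's
  concretization of verbal/scalogram shape descriptions; no generative
  model is canonical.
* Fragment-level simulation: a 2 Mb genome, 104 anchors per family
  (520 total; the real-data analogue of ~516 element×condition profiles
  is not divisible by 5), non-overlapping padded windows, random
  strands, midpoints from an inhomogeneous Poisson process (expected
  depth 100 per window) with the pattern mirrored on minus-strand
  anchors, 30% uniform background fragments to exercise RPM
  normalization, and fragment lengths `round(N(164, 12))` clipped at
  ≥ 50 bp, matching mono-nucleosome sizing. One gene is placed within
  2 kbp of each anchor with
  `log2(expr+1) = 8 + 2·c1 + 2·c5 + N(0, 0.5)`, where c1/c5 are the
  anchor's signed trend/phasing amplitudes.
* Profile-level simulation (used for basis and regression recovery):
  C = 516 profiles as `Bw + e`, planted-basis mixtures with per-pattern
  weight sds (1, 0.8, 0.65, 0.5, 0.4) and noise scaled to 10% of each
  profile's signal norm. The distinct variances order the extracted
  components and align them with the planted axes; with equal variances
  PCA would only recover the span up to rotation and per-pattern
  statements would be meaningless. Expression is linear in the planted
  pattern-1 and pattern-5 *scores* of the normalized profiles plus noise
  at a signal-to-noise variance ratio of 10.

A green recovery test therefore establishes that the pipeline recovers
structure *of this stated kind* — linear pattern mixtures, Poisson
midpoint sampling, Gaussian fragment lengths, strand symmetry. It does
not establish robustness to MNase sequence bias (the known A/T digestion
preference is deliberately not simulated), histone-variant heterogeneity,
unmappable regions, or anchor-position error, all of which shape real
profiles.

All stochastic outputs are pure functions of (config, seed); the same
seed reproduces byte-identical files.

## Known limitations

* SAM input support is minimal (proper pairs via TLEN; single-end reads
  extended to a fixed length); BAM is out of scope.
* Wavelet output is labeled in scale (bp-domain) with the pseudo-period
  conversion documented; no frequency-axis interpretation is imposed.
* No cross-validated λ selection, no varimax/ICA rotation, no automatic
  choice of K, no single-locus nucleosome reconstruction.
* The co-positioning matrix is O(N²) in the window and is written as a
  ~10 MB TSV at N = 1001; that is intentional (plain-text outputs).
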