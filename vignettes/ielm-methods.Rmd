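---
title: "Methods: imbalance-aware ELM ensembles for EEG stress classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware ELM ensembles for EEG stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ielm)
```

## The problem

Stress assessment from EEG is a three-class task (low / moderate /
high) whose class distribution is strongly skewed: the high-stress
group that matters most is a small minority (around 12% of segments in
the populations this package targets, against roughly 46% moderate and
42% low). A classifier optimised for overall accuracy can ignore the
minority almost entirely and still look good, so the centre of this
package is an ensemble built to protect minority-class recall, and the
evaluation layer reports per-class and macro recall rather than
accuracy alone.

## Band decomposition

Segments are detrended (mean and linear drift removed by least
squares) and clipped at `clip_sd = 5` standard deviations as a crude
artifact guard, then split into the five rhythm bands δ [0.5, 4), θ
[4, 7], α [8, 15], β [16, 31], γ [32, 45] Hz. The small gaps between
the printed band edges (7–8, 15–16, 31–32 Hz) are left unassigned on
purpose: every feature is computed within one band, so no statement
about inter-band energy is needed.

The band filter is an exactly zero-phase spectral filter: the FFT of
the segment is multiplied by a real amplitude response that is 1 in
the passband and falls as a cosine taper of half-width 0.15 Hz around
each edge, with the *power* response of bands sharing an edge (δ/θ at
4 Hz) summing to 1 across the crossover. Zero phase matters because
permutation entropy reads ordinal patterns, which phase distortion
would scramble. A forward–backward IIR filter was evaluated first and
rejected on measurement: transfer-function Butterworth designs of
order ≥ 6 are numerically unstable for the δ band at 256 Hz, and an
order-4 design applied forward–backward loses roughly 15% of broadband
energy in its transition bands, which breaks the conservation property
the tests demand (the five band variances of white noise must sum to
the spectral variance of the 0.5–45 Hz range within 10%; the spectral
filter achieves ≈ 93%, the ≈ 7% deficit being exactly the deliberate
gap exclusion). The 0.15 Hz taper width also keeps refiltering nearly
idempotent: filtering a band signal again changes its variance by
under 5% even for the narrowest band.

Sampling rate, duration and montage are not prescribed by the method;
defaults are 256 Hz, 10 s, single channel. The constructor enforces at
least 2 s of signal and a sampling rate of at least 90 Hz (twice the γ
upper edge).

## The four band features

* **Hurst exponent** — rescaled-range (R/S) analysis: mean R/S over
  blocks at ≥ 8 logarithmically spaced block sizes (16 … n/2), slope
  of log R/S vs log size. The classical estimator is kept without
  small-sample bias correction; its known upward bias on white noise
  (≈ 0.55 at n = 4096) is well inside the ±0.1 band the tests and
  acceptance checks use, and it recovers fractional Gaussian noise
  with H = 0.8 to within a few hundredths.
* **Fluctuation index** — the mean absolute first difference
  `(1/(N−1)) Σ |x[i+1] − x[i]|`. This is the common volatility proxy
  in EEG affect work; it is deliberately isolated in one small
  function so an alternative definition can be swapped in.
* **Sample entropy** — `−ln(A/B)` with template counts under Chebyshev
  distance ≤ r·SD, self-matches excluded, the first `n − m` points
  indexing both template lengths. Defaults m = 2, r = 0.2·SD (the
  field's convention). A constant sequence returns 0 (every template
  matches); A = 0 returns `Inf`, which the table extractor treats as a
  failed segment. The counting loop is compiled (Rcpp); an independent
  R brute-force oracle in the tests pins the convention to 1e-12.
* **Permutation entropy** — Shannon entropy of ordinal patterns,
  normalised by `ln(order!)` into [0, 1]; defaults order 3, delay 1;
  ties broken by temporal position. Invariant under any strictly
  increasing transform of the signal.

Feature tables are scaled per column to [0, 1] with ranges fitted on
the training split only; sigmoid ELMs are scale-sensitive and fitting
ranges on all data would leak.

## ELM family

An ELM fixes a random hidden layer (weights and biases uniform on
[−1, 1] from a seed, sigmoid activation) and solves only the output
weights in closed form, `β = (I/γ + HᵀWH)⁻¹ HᵀW Tᵀ`, with `W` a
diagonal sample-cost matrix (identity for the plain solve). The ridge
penalty γ defaults to 1; γ → ∞ approaches the pseudo-inverse
interpolation limit, so both the regularised and the pure
least-squares readings of the model are available on one axis. The
hidden width defaults to L = 100.

Two complementary imbalance devices are provided and composed by the
ensemble rather than conflated:

* **sample weighting** — the diagonal `W` above;
* **label weighting** — the target matrix codes class c's positive
  entries as `n_major / n_c` (scheme `ratio`) or its square
  (`ratio_squared`) instead of +1, with −1 elsewhere. On balanced data
  both schemes reduce exactly to ±1 coding. Inflating the minority
  target makes minority training errors costlier without touching the
  solve, so the time complexity stays that of the standard ELM.

Prediction decodes the row-wise argmax of `(Hβ)ᵀ`; exact ties go to
the lowest class index (documented and tested).

## The IELM ensemble

The c-class task is recast as q = c one-hot labels so that every class
contributes a binary label with positive (member) and negative
(non-member) sides, and within-label imbalance is measurable as
`R_j = max(S⁺, S⁻) / min(S⁺, S⁻)`.

**Initial distribution.** The boosting weights form an n × q matrix
split into 2q (label, class) blocks. The minority side of each label
receives raw weight √R_j (majority 1); each block is then normalised
to mass 1/(2q), making the grand total 1. The square root damps the
raw ratio, which would otherwise hand nearly all mass to the minority
side. Because normalisation is per block, the practical effect at
initialisation is that minority blocks spread the same mass over fewer
samples — each minority sample individually outweighs each majority
sample by R_j. The raw ratio (no square root) is available behind
`sqrt_ratio = FALSE`.

**Rounds.** Each round draws a fresh hidden layer from `seed + t` (one
knob reproduces everything) shared across labels, and solves each
label's output column by the weighted ridge solve above, using that
label's current weight column as the diagonal costs and the
label-weighted (`ratio`) targets. The weight column is rescaled to
mean 1 before entering the solve — a pure normalisation that keeps the
ridge penalty's meaning independent of n and q and makes the balanced
case collapse *exactly* onto the plain ELM solve (the degeneracy the
tests assert: balanced counts, one round ⇒ identical β and identical
decisions).

**Coefficients and update.** With signed per-label predictions
(`sign(Hβ)`), each block gets `ς^{lj} = ½ ln(correct mass / wrong
mass)` and the round gets the same statistic over all labels; masses
are clipped below at 1e-10, so perfect or hopeless blocks produce
large finite values rather than infinities. The update multiplies
correct samples by `e^{−ς}` and wrong ones by `e^{+ς}` (mistakes gain
weight, the boosting convention) and renormalises every block back to
1/(2q), so the distribution is conserved after every round — the
block-mass invariant is asserted to 1e-12 across full training runs.
When q = 1 the machinery reduces to classic AdaBoost: the ensemble
coefficient equals `½ ln((1−ε)/ε)` computed from the marginal weighted
error, and the block update reproduces the classic multiplicative
rule up to block normalisation (both identities are tested).

**Decoding.** The ensemble score of label l is `Σ_t ς_t ·
sign(H_t(x) β_t)_l`; the predicted class is the argmax, ties to the
lowest class index. The sign vote makes rounds commensurable
regardless of their output scale; the cost is that relabelling classes
can flip tie cases (scores are exactly permutation-equivariant, tied
decisions follow the class ordering — the tests check equivariance on
untied rows). Training stops early if a round classifies every block
perfectly, since the update would then be a no-op.

Defaults: 10 rounds, L = 100, γ = 1, all CLI-configurable.

## Classic AdaBoost

Provided both as a baseline and as the reduction target of the q = 1
identities: weighted error `Σ w_j 1[pred ≠ truth]` on normalised
weights, coefficient `½ ln((1−ε)/ε)` (for K > 2 classes the SAMME form
`ln((1−ε)/ε) + ln(K−1)`; the IELM path never uses this), and the
standard weight update, after which the misclassified mass is exactly
½. Base learners: a weighted decision stump (exhaustive thresholds for
small n) or a weighted ELM. Training stops at chance-level rounds or
when a stump degenerates to a constant prediction.

## Accuracy-weighted fusion

Given the per-band single-feature accuracies f₁…f₄ (Hurst,
fluctuation, sample entropy, permutation entropy), the band's weights
are `w_i = f_i / Σ f`, convex by construction, ordered like the
accuracies, and invariant to rescaling the accuracy column. Full
precision is used in computation; a half-up 4-decimal rounding is
attached for display because that is how such tables are printed
(base `round()` is half-to-even and would disagree on boundary cases).
The shipped accuracy table reproduces its published weight table
exactly at 4 decimals, including the one cell where the published
weight table and the published combination formulas disagree by 1e-4
(β-band sample entropy, 0.2213 vs 0.2212): recomputation gives
0.22119…, so the 0.2212 printing is taken as correct.

Two fusion outputs are provided because a single scalar per band
(`F_band = Σ w_i P_i`) discards within-band structure: the default
classifier input is the element-wise weighted 20-vector `w_i·P_i`,
with the 5 band scalars available behind a flag.

## Synthetic data: what it does and does not emulate

No public recording of the target kind exists, so the generator
stands in. Each segment is a sum of five band-limited unit-variance
noise processes scaled to per-class RMS amplitudes, plus fractional
Gaussian noise (exact circulant embedding) with a per-class Hurst
target. The class mix defaults to the 12/46/42% high/moderate/low
imbalance. Amplitude defaults encode the arousal signature the
features are meant to detect — high stress raises β (6→13 µV RMS
across low→high) and γ (3→7 µV) and suppresses α (18→10 µV), slow
bands class-neutral — and Hurst targets fall with stress (0.78 / 0.70
/ 0.62), giving all four features a class gradient. Labels are drawn
independently per segment; subject ids group each consecutive four
segments (used by the grouped splitter), which mirrors a protocol of
several fragments per subject while keeping segment counts binomial.

The generator reproduces the *statistical* structure the pipeline
consumes — band power, long-range dependence, imbalance — and none of
the physiology: no eye blinks, spindles, mains hum, non-stationarity
or inter-subject variability. Green tests therefore demonstrate the
correctness of the algorithms and the claimed imbalance behaviour
under controlled conditions, not field performance on recorded EEG.

Feature-space fixtures (`generate_feature_dataset`) skip signal
synthesis entirely: 20-dim unit-variance Gaussian clusters whose means
have expected norm `separation` (drawn per seed). `separation = 0` is
the null configuration; 2 is the "moderate overlap" working point at
which the plain ELM visibly under-recalls the minority; 5 is
near-separable. Problem sizes in the tests and the acceptance script —
n = 500 rows, 10 paired seeds, 10 boosting rounds, L = 100; n = 4096
and 20 seeds for Hurst recovery — were chosen as the smallest sizes at
which the statistical assertions are stable across seeds.

## Numerical choices, in one place

* Log-ratio clipping at 1e-10 (boosting error rates and all block
  masses) — large finite coefficients instead of ±Inf.
* Argmax tie-break: lowest class index, everywhere.
* Per-round hidden seeds `seed + t`; every generator and split takes
  an explicit seed; RNG state is restored after internal draws.
* Min-max scaling spans of zero width are treated as 1 (constant
  columns map to 0).
* Sample entropy of a constant sequence is 0 by convention; an
  unmatchable extension (A = 0) is `Inf` and excluded upstream.
* Display rounding is half-up; computation is full precision.

## Known limitations

* The R/S Hurst estimator keeps its classical small-sample bias
  (≈ +0.05 on white noise at n = 4096); a bias-corrected variant would
  trade accuracy at H ≈ 0.5 against accuracy at high H.
* The spectral band filter assumes circularity; edge effects are
  negligible for detrended segments of ≥ 2 s but would matter for very
  short windows.
* The sign-vote decoding loses score magnitude within a round; on
  all-negative or multi-positive sign patterns the tie-break, not the
  evidence, decides.
* True multi-label tasks (overlapping label sets) are representable in
  the weight machinery but not exercised by the single-label stress
  task, and no threshold calibration is provided.
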