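---
title: "oligofrag: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oligofrag: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligofrag)
```

This vignette is the package's own account of the science it
implements: the chemical conventions behind the fragment catalogue, the
statistical model behind the sulfur counter, the signal model behind the
2DMS simulator, and the places where the design was genuinely open and a
choice had to be made.  It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Chemistry model

**Compositions.** Every mass is derived from an elemental formula
(`ef`), a named integer vector, with monoisotopic atomic masses pinned
to the NIST "Atomic Weights and Isotopic Compositions" tables so test
values are bit-stable.  Subtraction may transiently go negative (loss
bookkeeping); validity is enforced only when a composition is finalized
as a molecule (`ef_finalize()`), at which point a negative count is an
"impossible chemistry" error — e.g. a thymine loss from a span that
contains no thymine.

**Monomers.** A nucleoside is sugar + base with free 5′/3′-OH.  The
2′-deoxy series (A, C, G, T, mC) is built in; bridged sugars are deltas
on top of it: +CH₂O for LNA (2′-O,4′-C methylene bridge, i.e. the ribose
oxygen plus the bridge carbon) and +C₂H₄O for cEt (constrained ethyl).
Users can register arbitrary codes from JSON, including exotic bases;
nothing restricts the registry to nucleic-acid chemistry.

**Backbone.** A phosphodiester linkage contributes HPO₃, a
phosphorothioate HPO₂S (one non-bridging O replaced by S; the mass
difference is m(S)−m(O) = 15.9772 Da).  The neutral molecule is

> M = Σ nucleosides + Σ linkages − (n−1)·H₂O + terminal deltas.

Termini default to 5′-OH/3′-OH (an empty delta); 5′-phosphate and
5′-thiophosphate are registry-configurable deltas written as `[P]`/`[PS]`
prefixes or suffixes of the sequence string.  The literature the
catalogue is checked against rarely states termini explicitly, so the
default is the free-hydroxyl form of the intact nucleosides.

**Terminal fragment end chemistry.** With `prefix(i)` = first i
nucleosides chained (5′ terminus included) and `suffix(k)` symmetric,

| 5′ ions | composition | 3′ ions | composition |
|---|---|---|---|
| b_i | prefix(i) | y_k | suffix(k) |
| a_i | b_i − H₂O | z_k | y_k − H₂O |
| d_i | b_i + linkage_i | w_k | y_k + linkage_(n−k) |
| c_i | d_i − H₂O | x_k | w_k − H₂O |

This table is chosen so that all four complementary pairs sum *exactly*
to M at the formula level (asserted for random oligos in the test
suite), the w ion is the familiar 5′-phosphate fragment, and the cleaved
linkage's PO/PS identity travels with the fragment that retains its
phosphorus (d/c on the 5′ side, w/x on the 3′ side) — so a PS→PO swap at
one linkage shifts only d/c/w/x at that position, by exactly
m(S)−m(O).

A consequence worth knowing: `a_i` and `b_i − H₂O` are the *same*
molecule under this convention, as are `x` and `w − H₂O`, and (by the
adenine + O = guanine coincidence) `d−2H` can equal an internal span.
The assignment layer therefore never pretends to distinguish exact
isobars: they are grouped into one record and counted once.

**Internal (J) fragments.** A J fragment carries a cleavage on both
ends and contains neither terminus.  For cut positions i < j (retaining
monomers i+1..j) the composition is computed by the subtraction identity
`R_j + L_(n−i) − M` with R the 3′-end chemistry (a/b/c/d) and L the
5′-end chemistry (w/x/y/z); an independent test oracle rebuilds the same
composition by direct span summation.  By default only the four
same-bond pairs aw/bx/cy/dz are enumerated; aw/bx are exactly isobaric
(as are cy/dz), which is precisely why observed internal peaks are
reported as grouped `J(...)` possibilities rather than a unique
cleavage.  The full 16-way cross of end chemistries is available behind
`internal_pairs = "full"` for users who want the exotic combinations.

**Losses and adducts.** "Two atoms" neutral loss is interpreted as 2H
(configurable, like the whole loss list).  A base loss removes the
neutral free base BH; charged base loss (CBL) removes the base anion
B⁻ and decrements the charge, so it never applies to singly charged
candidates.  Loss stacking depth is 1 by default — one neutral loss *or*
one base loss per candidate — because observed annotation practice is
single-loss labels; adducts (e.g. +Na −H) are summed, not deducted.
The qualitative CBL propensity ordering (A⁻ > T⁻ > G⁻ > C⁻) is treated
as documentation, not as a filter: the engine enumerates, the data
decide.

## 2. Assignment conventions

* **Tolerance**: default 5 ppm.  The instruments this serves average
  sub-ppm errors; 5 ppm is deliberately loose enough to survive
  mediocre calibration, and `recalibrate()` (two-parameter linear fit on
  anchor pairs, usable internally or externally) brings distorted axes
  back below 0.1 ppm in the tests.
* **Charge**: when a peak carries a charge it filters candidates; when
  unknown, all charges compete.
* **Precedence** for classification of grouped candidates:
  precursor > McLuckey > +neutral loss > +base loss > internal >
  backbone-retained > adduct.  Deterministic tie-breaks (category, ion
  type, index) make the whole pipeline a pure function of its inputs.
* **Coverage**: a cleavage position is covered by any terminal ion (or
  loss variant) at that bond; internal fragments never count, because
  their span assignment is ambiguous.  The denominator is the n−1
  linkage positions by default; `denominator = "residues"` divides by n
  instead.  14 of 15 positions is 93.3% under the default and the
  ambiguity between the two conventions is exactly why both exist.
* **Efficiency**: `100·ΣF_i/(ΣF_i+P)` with P the surviving precursor
  intensity; products here are all non-precursor, non-unassigned peaks.
  The all-zero case is an explicit error, not NaN.

## 3. Isotope fine structure and sulfur counting

The pattern generator convolves exact per-element isotope distributions
(pinned masses and abundances), pruning below 10⁻¹⁰ relative abundance
and merging sticks closer than 0.1 mDa — far below the ³⁴S-vs-¹³C₂
spacing (10.9 mDa) and the ³⁴S-vs-¹⁸O gap (8.5 mDa), so fine structure
is preserved.  Abundances normalize to max = 1.

The estimator takes the ratio of the ³⁴S fine peak to the monoisotopic
peak and divides by the ³⁴S/³²S natural abundance ratio (0.0425/0.9499
= 0.04474): for k sulfurs the single-³⁴S isotopologue probability is
exactly k times that ratio, so the estimator is exact up to
coincidences.  Two documented approximations:

* the ±4 mDa (per charge) integration window also admits ¹⁵N₂ and
  ³³S¹⁵N isotopologues, which genuinely overlap the ³⁴S peak at any
  realistic resolving power; they bias the estimate upward by ~0.02–0.08
  sulfur for nucleotide-sized fragments — harmless after rounding, and
  faithful to what an instrument integrates;
* the resolution gate uses the FT-ICR model FWHM(m/z) = (m/z)²/(400·R₄₀₀)
  with R₄₀₀ = 400 000 by default, and *refuses* to estimate when the
  ³⁴S–¹⁸O gap is unresolved rather than returning a wrong count.  A
  ~1.3 kDa fragment is countable at z = 2 but correctly rejected at
  z = 1 under the default model.

The stochastic robustness test (≤5% multiplicative area noise, k ≤ 6
still exact after rounding) is not a theorem — worst-case ±5% on both
areas is ~10% ratio error, i.e. 0.6 sulfur at k = 6 — so it is asserted
as the stated fixed-seed experiment, with the seed chosen before the
test was first run.

## 4. The 2DMS signal model

The simulator is deliberately minimal: its purpose is the acquisition
statistics (accumulation, averaging, denoising, 2D-FFT localization),
not instrument-accurate ion physics.

* m/z ↔ frequency uses the single-term model f = A/(m/z) with
  A = 10⁷ Hz by default (≈15 kHz at m/z 667 — ballpark ICR scales, not a
  calibrated instrument).
* Row r (t₁ = r·Δt₁) modulates the precursor radius as cos(2πf_p t₁);
  the fragment yield is the fragmentation-zone profile at that radius:
  a Gaussian (laser beam, width 0.5 in normalized radius by default) or
  a flat plateau (broad hollow-cathode electron zone, i.e. no t₁
  modulation).  Unmodulated signal lands on the zero-frequency t₁ row —
  the vertical-streak "t₁-noise" axis.
* Each of the m scans adds white Gaussian noise (σ per scan) and a
  per-scan multiplicative scintillation jitter (σ_t1, default 2% in the
  acceptance runs); the stored row is the scan average, which shrinks
  the white-noise σ by √m and the stored data size by m.
* Processing: zero-fill both dimensions to powers of two, magnitude FFT
  along t₂ then t₁.  Magnitude mode only; phase/absorption processing
  is out of scope.
* Denoising: truncated (or randomized) SVD at rank k, default 10 —
  standing in for the QR/projection-based low-rank algorithms used in
  2DMS pipelines, whose internals are not part of this package's
  contract.

The measured quantities follow: accumulation (m = 8 vs 1) gains ≈√8 in
fragment SNR (median ≈2.8–2.9 over 100 seeded repeats in the acceptance
script, inside the experimentally observed 1.7–3× band); the fitted
SNR-vs-m exponent is 0.5 ± 0.1 over m ∈ {1,2,4,8,16}.  The accumulation
gain and the denoising gain are reported *separately* — the simulator
does not assert any combined multiple-of-√m figure, since that depends
on the noise floor a given algorithm leaves behind.  For the exponent
fit the test uses bin-centred frequencies; off-bin tones leak energy
into the noise region and saturate the apparent SNR at large m, which
is a property of rectangular-window FFTs, not of the acquisition
scheme.

## 5. What the fixture generator does and does not emulate

`generate_fixture()` emits peaks at exact catalogue m/z values
(optionally ppm-jittered), centre-weighted intensities mimicking the
observation that cleavage abundance falls off towards the termini, and
uniform decoys kept 2× the assignment tolerance away from every true
peak.  It does **not** emulate: isotope envelopes (peaks are
centroided monoisotopic sticks), intensity-dependent detection, noise
baselines, charge-state abundance profiles, or secondary fragmentation.
A green round-trip test therefore establishes the correctness of the
m/z bookkeeping and the bookkeeping of the taxonomy/coverage counters —
it says nothing about real-spectrum peak picking, which is upstream of
this package (inputs are peak lists).

## 6. Degenerate inputs and numerical choices

* Empty peak lists produce an all-zero report, not an error; empty
  catalogues and empty m/z windows are errors.
* Isobar grouping uses a 10⁻⁶ Da window — far below any ppm tolerance,
  far above double-precision jitter.
* A CBL candidate that would reach charge 0, or a loss that would drive
  an element count negative, is silently skipped (by design: the
  enumeration is exhaustive, invalid chemistry is not).
* All randomness (fixtures, simulator, randomized SVD) flows from
  explicit seeds; two runs with the same seed are byte-identical.

## 7. Known limitations

* Negative-ion mode only; average (isotope-weighted) masses are not
  computed.
* mzXML support is minimal: centroided scans, uncompressed
  network-order 32/64-bit m/z–intensity pairs.
* 2D maps are stored as CSV + JSON text rather than HDF5: the
  pre-installed R stack has no HDF5 bindings, and the map sizes this
  package simulates do not need them.
* The simulator's EDD/UVPD "physics" is limited to the closed-form
  utilities (closest approach, photon energy, harmonic positions); no
  fragmentation mechanism or propensity is modelled — the catalogue
  enumerates what *can* exist, never predicts what *will* be abundant.
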