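---
title: "Methods: multi-block fusion chemometrics for LIBS and Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-block fusion chemometrics for LIBS and Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfuse)
```

## The problem

Marine zooplankton taxa differ in elemental and molecular composition:
calanoid copepods accumulate lithium and carotenoid pigments, krill
(*Euphausiacea*) carry more mineralised exoskeletons with strontium and
phosphate, arrow worms (*Parasagitta*) are barely mineralised but rich in
amino-acid signatures, and the sea snail *Limacina helicina* has an
aragonite shell that dominates its emission spectrum. Laser-induced
breakdown spectroscopy (LIBS) reads the elemental side of this contrast;
Raman spectroscopy reads the molecular side. `specfuse` implements an
unsupervised classification workflow over both: spot spectra are
filtered, averaged, normalised, masked and chained into per-sample
feature vectors, the two modalities are fused at low level, the fused and
single-modality matrices are decomposed (PCA, NMF, JADE-ICA,
ComDim/CCSWA), and cluster separation of the taxon-labelled scores is
quantified by a silhouette statistic scanned over component planes.

Because no machine-readable spectra are published for the original
29-pellet study, the package carries a first-class synthetic generator
that reproduces the study's *design geometry* and its *qualitative
spectral narrative*, giving every pipeline stage known ground truth.

## The synthetic generator

`study_design()` defaults encode the study geometry: 29 samples
(14 Calanoida, 11 Euphausiacea, 2 Parasagitta, 1 Limacina, 1 mixed),
three visually distinct spot colours per pellet, 3 spots per colour per
modality (18 interrogated spots per sample), a 12,275-point LIBS grid
over 186–1049 nm and a 2,801-point Raman grid over 450–3150 cm⁻¹.

`default_templates()` encodes, per taxon, the line/band inventory
described above. Line profiles are Gaussian; LIBS line widths default to
3 grid steps (the detector's ~3-pixel FWHM); Voigt shapes were considered
and omitted — nothing downstream is sensitive to the far wings. The
10-shots-per-spot acquisition is collapsed to spot-level replicates,
since shots are averaged before any other processing; the spot is the
atomic unit.

Variance structure, chosen once and held fixed:

* **Sample-level log-normal multipliers** per feature (σ = 0.2 for LIBS,
  0.6 for Raman) create between-sample biological variability. The Raman
  σ is deliberately larger: pigment and amino-acid band intensities vary
  strongly between individuals, which is what limits Raman's
  discriminative power relative to LIBS in this system.
* **Resonance-line jitter** (log-normal, σ = 0.8 per spot) on
  resonance-flagged Na, K, Mg and Ca lines. Strongly self-absorbed lines
  saturate erratically with plasma conditions, so their (large)
  intensities carry little compositional information; they dominate raw
  variance and degrade clustering until masked. This is the mechanism
  behind the raw-versus-shortened silhouette gap the pipeline reproduces.
* **Raman background**: a smooth positive 6th-order polynomial with a
  per-spot log-normal amplitude (σ = 0.5), standing for residual
  fluorescence after instrument correction. The LIBS background is
  instrument-corrected and kept near zero.
* **Heteroscedastic noise** with relative scale `noise_sd = 0.02`,
  clipped so intensities stay non-negative (Raman normalisation and NMF
  require this).
* **Planted anomalies**: a fraction `outlier_rate = 0.05` of spots is
  scaled by `outlier_scale = 5` and flagged, giving the Grubbs filter
  unambiguous targets.

Template relative intensities are free parameters of the generator, not
measurements — the source narrative is qualitative. What the generator
does **not** emulate: physical plasma modelling, self-absorption line
*shapes* (only the intensity erraticism), instrument response functions,
wavelength-calibration error, cosmic rays. Tests passing on this
generator therefore demonstrate the correctness and the qualitative
behaviour of the workflow, not quantitative performance on real spectra.

## Preprocessing decisions

* **Grubbs filtering** is applied to LIBS spot replicates, sequentially
  over the net integrated intensities of Li I 610.3, C I 247.8,
  Na I 568.3, Ca II 396.8 nm and the C₂ band head at 473.6 nm, with
  α = 0.05, two-sided, iterative single-point removal and critical
  values from the standard t-based formula. "Peak intensity" is the
  ±0.5 nm (LIBS) net trapezoidal integral above the straight line joining
  the window's endpoints: integrals are robust to one-pixel jitter,
  whereas raw heights are not. The test is undefined below n = 3, so
  removal stops once fewer than 3 values remain; a 3-spot group may
  therefore lose one outlier (leaving 2 spots for averaging), which is
  what makes the filter useful under the default 3-spots-per-colour
  design.
* **Raman spots** are normalised to unit total intensity *before*
  averaging (the varying per-spot fluorescence and acquisition settings
  make absolute Raman intensities meaningless); LIBS spectra are not
  normalised — their scaling happens only at block fusion.
* **Masking** defaults to ±0.5 nm regions around the Na I 588.995/589.592,
  K I 766.49/769.90, Ca II 393.37/396.85 and Mg II 279.55/280.27 nm
  resonance lines. This list is a configurable stand-in, not a
  reconstruction of the original (unpublished) discard list. Each region
  carries a modality tag so a wavelength region cannot delete Raman
  features at numerically equal shift values in a fused block. Masking a
  Frobenius-scaled fused block re-normalises each sub-block, so masking
  and fusion commute.
* **Colour chaining** uses the fixed order dark ‖ medium ‖ light (the
  order is a convention; it is recorded per feature so it is auditable).
  A chained LIBS vector has 3 × 12,275 = 36,825 entries, a Raman vector
  3 × 2,801 = 8,403, and the fused 29-sample matrix is 29 × 45,228.
* **Fusion** divides each block by its Frobenius norm and concatenates
  columns — low-level fusion; PCA of the fused block is SUM-PCA.

## Decompositions

* **PCA** mean-centres columns (the behaviour of the reference
  `princomp`-style implementations; recorded in the output) and uses the
  SVD, with the Gram-matrix shortcut for wide blocks. Sign convention
  everywhere: each loading's largest-magnitude element is positive.
  Component counts can be suggested by `scree_select()` — the index
  before the largest relative eigenvalue drop, ties to the smallest
  index, flat screes warn.
* **NMF** uses Lee–Seung multiplicative updates with 20 seeded random
  restarts (tolerance 1e-6 on the explained-variance change, 500
  iterations cap), keeping the restart with the highest explained
  variance — the standard answer to rotational ambiguity. The factor
  dimensions follow the scores-times-loadings convention
  `X (n × f) ≈ W (n × p) · H (p × f)`, with `W` the plotted scores.
  Negative cells (possible after background correction) must be clipped
  first; `clip_negatives()` logs the count. NMF explained variance is
  reported against the raw matrix norm, PCA's against the centred norm —
  the two are not directly comparable and the convention is recorded in
  the output.
* **JADE-ICA** whitens to `p` dimensions by PCA and jointly diagonalises
  the fourth-order cumulant matrices by Jacobi rotations. Components are
  ordered by descending kurtosis magnitude. If every component's excess
  kurtosis is within two standard errors (√(24/n)) of zero the data look
  Gaussian and ICA is unidentifiable; the fit carries a
  `gaussian_warning` flag but still returns components.
* **ComDim/CCSWA** column-centres each block, scales it to unit
  Frobenius norm, forms Wₖ = Xₖ Xₖᵀ and extracts common components one
  at a time: saliences initialise at 1, then q ← dominant eigenvector of
  Σₖ λₖ Wₖ and λₖ ← qᵀ Wₖ q alternate until ‖Δq‖ < 1e-10 (100-iteration
  cap), followed by deflation Xₖ ← (I − qqᵀ)Xₖ. Centring is standard
  CCSWA practice and gives the conservation property that with p = N − 1
  the saliences of a block sum to the trace of its unit-norm Wₖ. The
  iteration counts and tolerances are this package's contract — the
  model equation alone does not fix them. With `inner_method = "ica"`
  the dominant-eigenvector step is replaced by the leading JADE component
  of the salience-weighted block concatenation; published descriptions
  leave the ICA/deflation interleaving open, and this is one defensible
  reading (flagged here deliberately). A single-block ComDim reduces
  exactly to the eigendecomposition of W, which is the oracle the tests
  use.
* **Oblique scores**: non-orthogonal latent pairs (NMF, ICA) are plotted
  in scalene coordinates `(s₁ + s₂ cos α, s₂ sin α)` with
  cos α = ⟨u,v⟩/(‖u‖‖v‖), so plotted Euclidean distances equal the
  oblique-metric distances. `loading_signature()` condenses crowded
  loadings into per-window net integrals normalised per window to the
  largest magnitude across components (spider diagrams); the
  per-colour breakdown is kept as an attribute.

## Silhouettes

`silhouette_report()` uses the *all-outside-points* bᵢ: the mean
distance from point i to every point outside its cluster, not the
classical nearest-other-cluster minimum (a `classical = TRUE` mode exists
for comparison). The overall statistic divides the summed per-cluster
means by the number of clusters (macro average) — the printed source
formula omits that division, which would push values past 1 and
contradict the statistic's own [−1, 1] range, so the macro reading is
adopted; a micro (per-point) variant is available and both are stored.
Distances are Euclidean on the selected score columns. Singleton
clusters get aᵢ = 0; coincident points give sᵢ = 0.

Cluster labels come from known taxa (no unsupervised discovery). Because
the Calanoida/Euphausiacea split is not resolvable from Raman spectra,
the default label schemes mirror the study: Raman silhouettes use the
merged *Crustacea* cluster (against arrow worms and sea snails), LIBS
and fused silhouettes compare Calanoida against Euphausiacea only; the
mixed sample is always excluded. Schemes are explicit configuration.

## The pipeline and the multi-seed study

`run_pipeline()` executes generate → filter/average/normalise → mask →
chain → assemble → fuse → decompose → silhouette over the full grid of
methods × datasets × masking strata, emitting one report row per cell
(total EV, best plane, best-plane and subspace silhouettes). All
randomness flows from one root seed through `derive_seed()` per-stage
offsets, so any stage can be reproduced in isolation and identical seeds
give byte-identical reports.

`fusion_ordering_study()` repeats the PCA route over independently
seeded synthetic datasets (50 seeds by default, full instrument grids)
and compares median best-plane silhouettes. On the shortened stratum the
fused data match or beat LIBS, LIBS beats Raman, and masking raises the
LIBS and fused medians substantially — the directional behaviour the
workflow is designed to exhibit. The fused-versus-LIBS margin is small
(most of the discriminating signal is elemental), so the ordering is
reported as medians over seeds rather than a per-seed claim. The study
uses the PCA route only because the ordering is defined on best-plane
PCA silhouettes; the full four-method grid is exercised separately.
`mask_li_experiment()` adds Li-line regions to the mask and reports the
silhouette change — the package's version of the check that lithium,
despite its visual prominence in Calanoida spectra, does not drive the
classification.

## Numerical choices and degenerate inputs

Zero-variance input keeps all points in the Grubbs test; masks covering
an entire axis error; fusing a zero-norm block errors; PCA on a constant
matrix errors; `p` beyond the numerical rank errors; degenerate
(collinear) confidence ellipses return a flagged line-segment fallback;
silhouettes with a single cluster error. NMF restarts are seeded
deterministically, so every stochastic result in the package is
bit-reproducible.

## Known limitations

* Template intensities are invented (only the qualitative inventory is
  sourced); absolute silhouette values on synthetic data are not
  comparable to values on real spectra.
* The Grubbs filter assumes approximately normal replicate intensities;
  heavy-tailed spot heterogeneity (e.g. the erratic resonance lines)
  inflates its removal rate, which is why the filter precedes masking in
  the chain but its windows deliberately include only one resonance
  line.
* The ComDim–ICA inner step is one reading of an under-specified
  algorithm; saliences from that route should be compared against the
  PCA route before interpretation.
* NMF explained variance is not comparable to PCA explained variance
  (different reference norms).
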