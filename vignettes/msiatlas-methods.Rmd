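---
title: "Building computational atlases from mass spectrometry imaging data"
author: "msiatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building computational atlases from mass spectrometry imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiatlas)
```

# Scope and data model

An MSI experiment yields one sparse centroided spectrum per tissue
pixel. `msiatlas` carries these as a `SpectraDataset` (pixel grid
coordinates plus per-pixel (m/z, intensity) lists) and, after
quantization, as a `BinnedCube` — a `SummarizedExperiment` with one
`intensity` assay of bins × pixels, bin centers in `rowData` and pixel
coordinates in `colData`. Polygon annotations (`AnnotationSet`,
readable from VGG Image Annotator JSON) rasterize to a per-pixel
`LabelMask`; category labels carry their gross anatomical region as a
leading prefix (CTX, CNU, BST, WM, PLX, PLQ, BG) and optional
`sub<k>` suffixes for subannotations.

# Fixed-bin extraction

Peaks are assigned to the single nearest center of a uniform grid
anchored at the lower end of the mass range, with centers
`mz_min + k/b` for `b` bins per m/z. Two resolutions matter in
practice: `b = 5` (0.2 Da) for fast visualization and `b = 20`
(0.05 Da) for all quantitative steps; the package defaults every
quantitative path to 20. Numerical choices worth knowing:

* a peak exactly midway between two centers goes to the lower-index
  bin, with a `1e-9` m/z epsilon absorbing floating-point error in the
  tie position — deterministic across platforms;
* out-of-range peaks are dropped and counted in the cube metadata,
  never clamped into the edge bins;
* binning conserves total in-range intensity exactly (tested against a
  brute-force summation oracle);
* pixels with zero total ion current survive TIC normalization as
  all-zero vectors and are recorded in a mask rather than dropped, so
  image geometry is preserved.

The interchange format is imzML (processed mode, 64-bit floats; the
reader also accepts continuous-mode and 32-bit files). The internal
binned container is R-native serialization with a JSON metadata
sidecar.

# High-precision m/z refinement

Fixed-bin centers are only 0.05 Da statements about where an ion
lives. The four-stage refinement recovers better centers: collect all
raw pairs within `candidate ± 0.01` Da (the half-window is exposed);
fit an intensity-weighted 1-D Gaussian mixture with three components
by EM; discard components below 5% and keep the remaining means as
refined centers; re-extract images around those centers and verify
with intensity-weighted moments.

Design choices: samples are weighted by intensity because
high-intensity ions carry the mass evidence; the weighting is the
natural case-weight generalization of EM and reduces to ordinary EM
for constant intensities (cross-checked against `mclust` on unweighted
draws). Each fit runs one deterministic weighted-quantile
initialization plus two seeded random restarts and keeps the best
weighted log-likelihood, so results are reproducible given the seed.
Variances are floored at `1e-8` Da² to prevent collapse onto repeated
sample values; when fewer distinct m/z values than components exist,
the component count is reduced. Discarding is by mixture weight by
default; the alternative reading — fraction of (intensity-weighted)
samples assigned to the component — is available via `discardBy =
"assigned"`.

One validation subtlety: the twin-peak phantom plants components at
700.100 and 700.115. A 0.01 Da window around a between-peak candidate
would truncate the upper component exactly at its mean and bias its
fitted center by roughly 0.8 σ, so the refinement tests collect with a
0.02 Da half-window around candidate 700.105; with Δ = 0.015 and σ =
0.002 both components then sit > 5 σ inside the window.

# Bayesian classification and worst-case confusion

The classifier is a multinomial logistic model whose weights and
biases carry independent `N(0, priorSd²)` priors, fitted by mean-field
Gaussian variational inference: single-draw reparameterized gradients
of the evidence lower bound, Adam updates, 400 steps at learning rate
0.05 by default. Features are z-scored internally and the
standardization is stored in the model. A multinomial head (one shared
softmax) is used here; one-vs-rest models are reserved for stability
selection, where per-category weight signs matter. Training is
bit-deterministic given (data, seed); divergence triggers one retry at
a fifth of the learning rate.

Soft confusion row `i` is the mean predicted probability vector over
pixels truly labeled `i` — row-stochastic by construction. For an
ensemble (10 models by default), per-model means and standard
deviations are taken across the posterior draws (the axis the
"mean + 2·std" summary needs), and the pair score is the maximum of
mean + 2·std over models, symmetrized by the elementwise maximum for
graph use. No class reweighting is applied by default; a balanced
subsampling flag exists.

# Marker mining

**Stability selection.** 200 one-vs-rest ridge logistic models, each
on a random 50% row subsample augmented with 50 noise columns built by
sampling real columns with replacement and permuting their rows
independently (per-model RNG derived from (seed, model index)). Per
model and category the threshold is the maximum absolute noise weight;
real features with positive weight above it are marked, and features
marked in ≥ 80% of valid models are retained. A category with fewer
than two subsampled pixels on either side skips that model and the
denominator adjusts. With no noise columns the rule degenerates to
"positive weight in ≥ 80% of models", which the tests assert. The
inner solver is exact IRLS with an L2 penalty on the slopes
(λ = 1 by default) and per-subsample standardization; it matches
`glmnet` ridge coefficients to < 1e-3 in the cross-check test and is
batched across categories for throughput.

**mPAUC.** For feature `m` and category `i`, round 1 sums
`AUC(values in i vs values in j)` over the other categories `j`,
restricted to pairs whose two-sided rank-sum p-value is below 0.05
(uncorrected, as a raw gate; a Benjamini–Hochberg option exists but is
off by default). Round 2 keeps the `k = 20` top-scoring categories per
feature and recomputes the score within that set, so irrelevant
categories cannot dilute the ranking — and, by construction, round 2
never adds score for categories outside the round-1 set. AUCs are
rank-based (`P(a > b) + ½ P(tie)`), exact against an exhaustive
pair-count oracle; p-values use exact enumeration for untied groups of
≤ 10 and otherwise a tie-corrected normal approximation with
continuity correction. Category samples are capped at 2000 pixels
(seeded uniform subsample) to bound the quadratic pair cost.

The two procedures disagree by design: stability selection keeps any
feature that helps predict the category, including features shared
with other regions, while mPAUC favors features exclusive to it. The
intersection of both is therefore a high-specificity marker set, and
the test suite asserts this divergence on a constructed fixture.

Per-category association lists derive from the per-feature category
ranking. The original setting reports the top 10 of 124 categories
(roughly the top 8%); at phantom scale (≤ 10 categories) a rank-10
cutoff is vacuous, so lists here use round-2 rank ≤ 2 (`assocRank`,
configurable). Putative annotation matches query m/z against a local
reference table of neutral monoisotopic masses under the [M−H]⁻
adduct (proton mass 1.00728 Da subtracted) within 0.01 Da; all matches
within tolerance are reported and multiplicity is flagged ambiguous.

# The atlas graph

Node representations are per-category mean feature vectors ("average
spectra"; `categoryProfiles`), or per-category posterior-mean weight
vectors for the model-explanation variant (`modelAtlas`). The 2-D
embedding is classical multidimensional scaling of cosine distances
between representations — cosine because TIC spectra are
compositional; the metric is configurable. MDS is deterministic, which
the reproducibility contract (identical inputs ⇒ identical graphs)
exploits; a seeded jitter of 1e-4 of the coordinate span separates
exactly coincident rows such as planted duplicates. Edges join pairs
whose symmetrized pair score reaches the threshold — by default the
90th percentile of off-diagonal scores, since no absolute cutoff is
canonical — and are "intra" when both categories share a gross region
(likely annotation ambiguity or true biological similarity) and
"inter" otherwise (potential cross-regional molecular links). Node
size is `sMin + sScale · degree`. `flagAnnotationIssues` intersects
"embedding distance below the 25th percentile of node-pair distances"
with "edge weight above the 75th percentile of edge weights" and ranks
by weight; on the duplicate phantom the planted pair ranks first.

For cohort comparison, every cube is segmented by majority vote of the
ensemble's posterior-mean predictions (ties break toward the highest
mean probability), so categories missing from a scan's annotations
still receive profiles; per-category means are then taken on raw
(non-TIC) intensities to keep absolute abundance differences visible,
and categories predicted in only one cohort are flagged undefined.

# Rendering

The landscape field at grid point `p` is `Σ_i w_i(p) v_i` with
`w_i(p) ∝ exp(−d_i(p)/τ)` on Euclidean embedding distances — a convex
combination, hence bounded by the node-value range, and converging to
the nearest-node (Voronoi) map as τ → 0, which the tests assert
against a brute-force oracle at τ = 1e-6. The temperature default is
5% of the embedding bounding-box diagonal — a reconstruction, exposed
as a parameter. Histogram normalization rank-transforms the field to
uniform [0, 1] with average ranks for ties. The pathology stain maps
0–1 normalized intensity linearly between white (255, 255, 255) and
dark brown (139, 69, 19); log mode applies
`log(1 + g·x)/log(1 + g)` with gain 99 by default (x = 0.01 maps near
mid-range). Gross-region RGB composites sum each region's associated
feature images into one channel after removing features shared with
any other channel's set, then normalize each channel to [0, 1].
Rendering involves no randomness.

# The synthetic phantoms

`generatePhantom` draws, per pixel, one peak per signature feature of
the pixel's category with LogNormal intensity matching the configured
(mean, cv) and observed m/z ~ Normal(true m/z, massSigma), plus
Poisson-count uniform-m/z noise peaks with exponential intensities.
Circular spots blend a remote category's signature into a host region
as a convex mixture — the plaque-like lesion model. Defaults chosen
once for all presets: 48×48 pixels, m/z 700–800 (a compact window
standing in for the full 300–1350 Da negative-mode lipid range),
abundance cv 0.25, mass error σ = 0.002 Da, 3 noise peaks per pixel of
mean intensity 2 — signal-to-floor ratios comparable to well-behaved
MALDI tissue data. The presets: `separable8` (8 categories, 3 gross
regions, one exclusive marker each at fold-change ≥ 8 over the noise
floor), `duplicates` (adds an exact signature copy of CNUcp),
`index` (one feature shared along a CTXL2–CNUcp–BSTsn chain with
graded abundance), `plaque` (PLQ spots inside CTXL2 mixing 60% plaque
with 40% host signature; three features shared with the remote donor
WMcc and one with the host), and `twin_peaks` (two peaks 0.015 Da
apart at abundance ratio 7:3).

What the phantoms do *not* emulate: isotope envelopes, adduct
families, chemical/matrix noise structure, intensity drift across the
slide, and registration error between serial sections. Passing tests
therefore demonstrate algorithmic correctness under a known generative
model, not robustness to every artifact of real acquisitions.

# Problem sizes and runtime choices

The test suite and the acceptance script run the study conditions at
phantom scale: 48×48 pixels, 20 bins per m/z, mining tables capped at
the 60 most intense features with background pixels excluded
(classification and confusion keep background), ensembles of 10 models
× 100 posterior draws, stability selection at its full 200 models
with a 20-seed permuted-label null, and twin-peak refinement over 100
seeds at 5000 samples each. Unit tests use further-scaled variants of
the same constructions (documented inline) so the default suite stays
fast.

# Known limitations

* The embedding is metric MDS, not a local-structure-preserving
  method; with many categories, fine neighborhood structure may
  differ from nonlinear embeddings, though all ordering properties
  validated here (duplicates adjacent, within-gross < between-gross)
  are metric statements that MDS preserves well.
* Variational posteriors are mean-field and typically underestimate
  posterior variance; the +2·std term in the pair score inherits
  that conservatism only partially.
* mPAUC p-values are uncorrected by design (raw 0.05 gate); enable
  the Benjamini–Hochberg flag for stricter gating.
* The imzML writer emits processed-mode files only, and putative
  annotation handles the [M−H]⁻ adduct only.
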