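---
title: "punctafiber: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{punctafiber: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cutaneous nociception studies quantify punctate TRPV1 immunoreactivity
specifically on PGP9.5-labeled nerve fibers in skin sections. The
measurement has three coupled parts: (i) segmenting the curvilinear,
low-contrast fiber structures in the PGP9.5 channel; (ii) counting
TRPV1-immunopositive puncta, defined as local intensity maxima above a
fixed threshold (200 AU in 16-bit images), restricted to the fiber
region; and (iii) validating that different analysis routes (manual
counting, a trainable-classifier route, a deep-learning route) agree.
`punctafiber` implements this pipeline so that every stage can be
validated on synthetic images with exact ground truth.

All quantification runs on maximum-intensity projections of the
acquired z-stacks; the package never analyses raw 3-D stacks
downstream of `max_project()`. Coordinates are 0-based `(y, x)`; the
default pixel size is 0.16 µm (160 nm/pixel) and the default z-step is
1 µm, both overridable per file.

# Fiber segmentation

The trainable backend is a classic pixel-classification design:
a multi-scale filter bank feeding a bagged decision-tree ensemble.

**Feature bank.** For each scale σ ∈ {1, 2, 4, 8, 16} px: Gaussian
smoothing, gradient magnitude of the smoothed image, Laplacian of
Gaussian, both Hessian eigenvalues (the principal curvatures that make
ridge-like fibers separable), and a difference of Gaussians (σ vs 2σ);
plus the raw intensity — 31 features. Derivatives are central
differences of the Gaussian-smoothed image with reflecting boundary
conditions, so derivative features of a constant image are exactly
zero and features are translation-equivariant away from borders.

**Classifier.** 100 bagged CART trees with Gini splits,
`floor(sqrt(p))` candidate features per split, unlimited leaf size
(min 1), depth cap 25, fixed seed 0. The per-pixel fiber probability
is the fraction of trees voting fiber. These are Weka-comparable
defaults; the exact settings of the original plugin are not load-bearing
because the acceptance surface is segmentation quality (IoU against
ground truth), not classifier internals. Training and prediction are
deterministic for a fixed seed: all classifier randomness comes from
per-tree Mersenne-Twister streams independent of R's RNG.

**Binarization.** Probability ≥ 0.5 (inclusive), then removal of
8-connected components below 64 px. Small-object removal suppresses
salt noise that would otherwise contribute spurious ROI pixels to
puncta counting.

**Training labels.** Strokes are just sparse masks: the trainer
accepts any pair of disjoint fiber/background label rasters, from
single-fiber scribbles to full masks. When the pipeline derives
strokes from synthetic ground truth it uses the truth eroded by 1 px
as fiber strokes and everything beyond a 2-px band around the truth as
background strokes; the thin unlabeled band keeps the learned decision
boundary centered on the true fiber edge (with a wider band the
classifier systematically dilates fibers, which costs IoU on thin
structures).

**Deep-learning branch.** Deep segmentation models are out of scope;
the `external_mask_backend()` contract accepts any externally produced
mask, after which quantification is identical for both branches — this
mirrors how the two automated routes in the motivating workflow share
one quantification core.

# Consensus of expert annotations (STAPLE)

Multiple annotators' binary masks are fused by the canonical binary
STAPLE EM algorithm. Writing `d_ij` for rater j's call at pixel i,
sensitivity `p_j` and specificity `q_j`:

- E-step: `W_i = a_i / (a_i + b_i)` with
  `a_i = π prod_j p_j^d_ij (1 - p_j)^(1 - d_ij)` and
  `b_i = (1 - π) prod_j (1 - q_j)^d_ij q_j^(1 - d_ij)`;
- M-step: `p_j = Σ W_i d_ij / Σ W_i`,
  `q_j = Σ (1 - W_i)(1 - d_ij) / Σ (1 - W_i)`.

Defaults: `p = q = 0.99999` at start (the standard near-perfect-rater
initialization), scalar prior π = mean annotation fraction, tolerance
1e-6 on the largest parameter change, at most 100 iterations,
consensus mask at `W ≥ 0.5`. Parameters are clamped to
`[1e-6, 1 - 1e-6]`; clamping (inevitable at unanimity, where the
M-step is degenerate) is flagged in the result. The E-step is computed
in log space with a log-sum-exp likelihood, and the per-iteration
observed-data log-likelihood is returned so EM monotonicity is
checkable.

**A caveat worth knowing.** With a *fixed scalar* prior far from the
true foreground prevalence, EM can converge to a union- or
intersection-like fixed point: e.g. three symmetric raters
(sensitivity = specificity = 0.9) on a mask with 20 % foreground and a
forced prior of 0.5 yield a consensus close to the union of
annotations, with sensitivities estimated near 0.63. This is a
property of the model, not a bug — the default prior (mean annotation
fraction) avoids it, and the majority-vote equivalence property holds
when prior and prevalence agree. `majority_vote()` is provided as the
model-free baseline.

# Punctum detection

A punctum is a strict local maximum of the puncta channel: a pixel
strictly greater than all neighbors (8-connectivity by default, the
ImageJ convention), or a connected plateau of equal values strictly
greater than all plateau neighbors, reported once at the plateau's
rounded centroid (top-left plateau member if the rounded centroid
falls off the plateau). Borders compare only existing neighbors.

Retention rule: intensity strictly greater than the threshold
(default 200 AU — "above"/"exceeding" are read as the same strict
rule) *and* the reported pixel inside the fiber mask. Mask membership
is tested at the reported pixel only, which keeps the rule local and
matches ROI-restricted find-maxima behavior. Thresholding applies to
raw stored intensities of the projection; the package never rescales
intensities in I/O.

No prominence/noise-tolerance parameter is applied by default (the
reference workflows do not document one); `spot_filter()` offers
optional greedy de-duplication by minimum separation for dense signal,
with a stable (intensity desc, y, x) tie-break.

`brute_force_maxima()` implements the identical contract by per-pixel
exhaustive comparison and plateau flooding in plain R. It is the
independent oracle: the fast detector must reproduce it exactly on
randomized instances, including plateau and border cases. The two
share no traversal code.

# Quantification conventions

Per image and method: punctum count, mean fluorescence intensity
(MFI, AU) and fiber area (µm²). MFI is averaged over **all**
fiber-mask pixels of the puncta channel, not only punctum pixels —
the fiber mask is the only defined region, and this convention is the
natural reading of "intensity on nerve fibers"; it is isolated in
`measure_mfi()` so the alternative is a one-line change. Area is
`true-pixel count × pixel_size_um²`. Manual counts cannot be
re-implemented; they enter as an external per-image/per-rater CSV and
are collapsed to the per-image mean as a "manual" method that joins
only the rank-based comparisons (Spearman, Kruskal-Wallis/Dunn), not
the ICC between automated methods.

# Agreement statistics

- **IoU / Dice** with the both-empty convention = 1; the algebraic
  identity `dice = 2·iou/(1 + iou)` is used as a cross-check.
- **Spearman:** midranks for ties, Pearson correlation of ranks,
  two-tailed p from the t-approximation on n−2 df (the SPSS-style
  p-value); ρ = ±1 returns p = 0.
- **ICC:** two-way model, absolute agreement, single-measure
  (McGraw–Wong ICC(A,1)) by default — the row a typical SPSS report
  quotes; the average-measure form is an option. Estimate
  `(MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E))` from the
  two-way ANOVA mean squares; p from `F = MS_R/MS_E` on
  (n−1, (n−1)(k−1)) df. All-identical tables return 1 with a warning.
  Bands: < 0.5 poor, [0.5, 0.75) moderate, [0.75, 0.9) good, ≥ 0.9
  excellent (left-inclusive at each boundary).
- **Kruskal-Wallis** with the tie correction
  `1 − Σ(t³−t)/(N³−N)`; degenerate all-equal input returns H = 0,
  p = 1. **Dunn** post-hoc with the tie-corrected pooled variance and
  Bonferroni adjustment (raw and adjusted p both reported; the
  multiplicity rule in the reference workflow is unstated, Bonferroni
  is the conservative default).

Every statistic is tested against an independent direct-formula
oracle (base `rank` + `cor`, `stats::aov` mean squares, the
rank-variance identity for H) to 1e-10 on batches of random instances.

# The synthetic world

The generator states one simulated world and the tests live in it:

- image 128×128 px at 0.16 µm/px, 16-bit range;
- 3 curvilinear fibers (smooth random-walk splines spanning the
  image, dilated to 5 px thickness), fiber amplitude 1000 AU;
- 7 on-fiber and 5 off-fiber puncta, Gaussian profile σ = 1.5 px,
  peak 1000 AU;
- background 50 AU, Gaussian read noise sd 10 AU.

Amplitude 1000 over background 50 against threshold 200 reflects the
regime the threshold rule presumes: true puncta far above threshold,
background noise far below it. Spots are placed with center-to-center
separation ≥ max(3, ⌈4σ⌉) px so the planted count equals the
resolvable count and count-recovery tests can demand exactness rather
than statistics. Rater simulation flips pixels i.i.d. at the stated
sensitivity/specificity — deliberately matching STAPLE's
conditional-independence assumption so estimated parameters are
directly interpretable. All generation is a pure function of
`(spec, seed)`; child seeds derive from one master seed by a fixed
integer mixing scheme, kept below 2³¹.

What the generator does **not** emulate: epidermis/dermis texture,
PSF-accurate optics, Poisson photon statistics (Gaussian read noise
only), spatially correlated annotation errors, 3-D fiber geometry.
A green suite therefore establishes algorithmic correctness and
contract fidelity — not performance on real skin biopsies, which
depends on staining quality and contrast regimes the synthetic world
does not span.

# Numerical and degenerate-input choices

- Probability threshold 0.5 is inclusive; detection threshold is
  strict (>).
- TIFF I/O is a minimal baseline codec (uncompressed grayscale,
  8/16-bit, single- or multi-page, both byte orders on read) written
  in-package because no TIFF reader is otherwise available in the
  target environment; intensities round-trip bit-exactly and are
  never rescaled.
- Rendered synthetic images are rounded to integers and clipped to
  [0, 65535], emulating 16-bit storage, so disk round-trips are
  lossless.
- Empty fiber mask: MFI errors (undefined mean); area of an empty
  mask is 0; IoU/Dice of two empty masks is 1.
- `quantify_batch` logs per-image failures and continues; reruns
  write byte-identical CSV/JSON.

# Known limitations

No deep-learning training (by contract, external masks only); no
sub-pixel spot localization or Gaussian fitting; no dense-cluster
decomposition; no IENFD/branching morphometry; no compressed or tiled
TIFF variants; the Spearman p is an approximation (exact permutation
only advisable for very small n).
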