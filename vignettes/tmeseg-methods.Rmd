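---
title: "Methods: expert-in-the-loop tissue segmentation and TME quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expert-in-the-loop tissue segmentation and TME quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tmeseg)
```

# The problem

Non-small cell lung cancer develops inside a tumor microenvironment (TME)
— fibrosis, inflammatory infiltrates, vessels, necrosis and residual normal
lung — whose composition carries prognostic information but is laborious to
quantify by eye. `tmeseg` implements a pipeline that quantifies the TME from
ordinary H&E slide images: sparse expert annotations seed a fast random-forest
pixel classifier that is refined in an expert-in-the-loop (EITL) cycle; the
resulting dense labels train a multiclass U-Net; segmented slides are reduced
to area ratios inside the tumor border and compared across patient groups.

Ten fine annotation classes are distinguished: the two carcinomas (ADCA,
SCCA), three fibrosis subtypes (elastotic, dense, loose), vessels, two
inflammation subtypes (macrophage-rich, lymphoplasmacytic), necrosis and
normal lung ("background"). Stroma is defined as fibrosis + inflammation +
vessels. The TME metrics are component-vs-tumor percentages,

$$\mathrm{TSR} = \frac{Stroma}{Stroma + Tumor}\times 100,$$

and analogously TFR (fibrosis), TIR (inflammation), TVR (vessels), TNR
(necrosis) and TBR (background). A ratio whose numerator and tumor area are
both zero is *undefined* and flagged rather than reported as 0, so cohort
aggregation can exclude such slides explicitly.

# Synthetic pseudo-histology

No public slide cohort accompanies this problem, so the package ships a
seeded generator whose output every downstream stage is tested against.

A slide is built from three nested regions: a tissue blob on white glass
(a Fourier-perturbed circle), a smooth closed tumor border inside it, and —
inside the border — coarse-class regions carved as *quantile bands of a
smooth Gaussian random field*. The band construction gives two properties at
once: regions are spatially coherent blobs (level sets of a smooth field),
and realized area fractions equal the requested `target_fractions` to within
a pixel of rounding, so planted TME ratios are known essentially exactly.
Outside the border the tissue is normal lung. Fibrosis and inflammation
regions are subdivided into their subtypes by a second field.

Rendering is procedural: each class has a base color and a texture
(nuclei blobs for carcinoma, anisotropic streaks for fibrosis, punctate dots
for inflammation, rings with pale lumina for vessels, a homogeneous pale
smudge for necrosis, a bright-airspace lattice for normal lung), followed by
hue-preserving highlight compression and global luminance noise
(`noise_sd`, default 6 intensity units), with milder chroma noise on tissue
only. Two rendering constraints matter:

* **Saturation band.** Texture modulations are multiplicative and therefore
  preserve HSV saturation, so each class's saturation is essentially its
  base color's. The palette keeps all classes in a narrow saturation band
  (≈0.35–0.55) with *hue* carrying the class identity. If one class sits
  near the glass saturation (≈0.01) or far above the rest, Otsu's threshold
  on the saturation channel splits within tissue rather than at the glass
  boundary and foreground segmentation fails — exactly the behaviour the
  narrow band avoids.
* **Glass stays gray.** Noise on glass is luminance-only; independent
  per-channel noise would give glass spurious saturation comparable to pale
  tissue.

What the generator does *not* emulate: nucleus-level morphology, scanner
artifacts, stain batch variation beyond global tints, pyramidal formats, or
class textures that are genuinely ambiguous to a human. Passing tests on
synthetic slides therefore demonstrate the pipeline's mechanics (geometry,
bookkeeping, learning dynamics, statistics), not clinical-grade
segmentation of real H&E.

The cohort generator (`generate_cohort()`) mirrors a 76-case study: 28/25
ADCA and 19/4 SCCA in fibrotic/non-fibrotic lung. Per slide, only the
fibrosis fraction is drawn randomly (normal with arm mean 0.45 in fibrotic
arms, 0.15 in non-fibrotic, SD 0.05, clipped to [0.02, 0.75]); the remaining
mass is split with fixed weights (tumor 0.62 of the remainder, then
inflammation, vessels, necrosis, background). These defaults are explicitly
*not* calibrated to any real cohort; they plant a recoverable fibrosis
effect of known size.

# Preprocessing

`segment_foreground()` converts to HSV, median-filters the saturation
channel (half-width 2), thresholds by Otsu (a fixed threshold is available
for strict reproducibility), closes with a 5 px disc and drops components
below 64 px. `tile_grid()` lays a non-overlapping grid anchored at the
origin, in half-open 0-based coordinates; partial edge tiles are discarded
so tensors stay uniform. `extract_tiles()` keeps tiles whose tissue
fraction is at least the glass threshold (0.30, inclusive: "meets" the
threshold) and area-averages retained pixels by the integer downsample
factor (512 px at 0.25 µm/px → 256 px at 0.5 µm/px).

Optical density is the base-10 absorbance with white point 255 and
intensities clamped to ≥1, making the transform finite and exactly
invertible on the clamped domain. Stain normalization is a per-channel
affine map in OD space onto a reference mean/SD, computed over foreground
pixels only; background passes through untouched. The normalized image is
kept on a *continuous* intensity scale — quantizing back to 8-bit would
perturb the matched OD statistics by more than the 1e-3 guarantee — and is
clipped/rounded only when written to disk.

# The expert-in-the-loop random-forest stage

Pixel features are a compact QuPath-like texture basis: for each of six
channels (RGB + their ODs) and scales σ ∈ {1, 2, 4} px, the
Gaussian-smoothed channel, its gradient magnitude, and the local standard
deviation — 54 features. The classifier is a 50-tree random forest trained
*only* on annotated pixels. Two implementation choices matter:

* **Balanced stratified bootstrap.** Annotation workloads are very uneven
  across classes, and the review-revise step piles corrective strokes onto
  a few weak classes. With an unbalanced bootstrap those classes dominate
  the vote and retraining after review can *reduce* accuracy; sampling an
  equal number of pixels per class (the minimum class count) per tree
  restores the expected monotone improvement.
* **Deterministic ties.** Per-pixel argmax over tree votes breaks ties
  toward the lowest class index.

The EITL loop alternates fit → whole-slide segmentation → scoring → oracle
review. The stopping rule is: accuracy above the target (default 0.80),
or the iteration cap (default 5), or an improvement below 0.5 percentage
points ("no notable improvement"). The target is *pixel accuracy on tissue
pixels against the synthetic ground truth* — a measurable substitute for a
pathologist's visual judgement, documented as such rather than claimed
equivalent. The programmatic oracle emulates the pathologist: it ranks
classes by accuracy, takes the two worst, and stamps correct disc strokes
centred on mispredicted pixels. Oracle labels always agree with the truth;
conflicting labels abort the run.

In the packaged experiments the *initial* annotation is deliberately sparse
(2 strokes per class, radius 1 on 128 px slides). The dense default
(21 strokes/class, the per-WSI workload scaled from ≈211 annotations per
slide) already exceeds the 80 % stopping target on first fit for these
synthetic textures, which would end the loop at iteration 1; the sparse
setting reproduces the characteristic 2–4 iteration review-revise dynamic.

The tumor border collapses fine classes to tumor vs non-tumor, closes with
a 7 px disc, fills holes, drops components under `min_area`, and traces the
0.5-level contour (zero-padded, so edge-touching regions still close).

# The U-Net

The architecture is the classic encoder–decoder with skip connections:
per level two 3×3 convolution blocks (conv → batch norm → LeakyReLU,
negative slope 0.01), 2× max pooling down, nearest-neighbour upsampling,
skip concatenation and two more blocks up, closed by a 1×1 convolution;
default widths 32–512 over 4 levels for 256 px inputs. Because no deep
learning backend is available to R in this toolchain, the network —
im2col convolutions on BLAS matrix products, batch norm with running
statistics, pooling with argmax routing, Adam, class-weighted softmax
cross-entropy with an ignore label — is implemented in the package itself
and validated against finite-difference gradients (worst relative error
≈3e-9 across layer types).

Training minimizes inverse-frequency-weighted cross-entropy (weights
normalized to mean 1, capped at 20; `ignore_index` pixels contribute
nothing), with the best-validation-loss weights retained. The tile split
is the two-stage floor rule — `floor(2n/3)` train+validation, of which
`floor(0.7·…)` train — which reproduces 19 423/13 596/5 827/9 712 at
n = 29 135 exactly; assignment is a seeded permutation at tile level.

**Demo scale.** The packaged demonstration problem uses 4 synthetic slides
of 640 px, 64 px tiles downsampled ×2 (32 px inputs), widths (16, 32, 64)
over 2 levels, 5 epochs, Adam at 2e-3, batch 2. These sizes were chosen as
the smallest configuration at which 5 epochs reliably converge on the
synthetic textures (~500 gradient steps); at the spec-era default of 1e-3
the same budget underfits, which is why the learning rate is exposed and
the demo default is 2e-3. Label tiles are downsampled by nearest neighbour
(labels stay hard).

# Evaluation

Pixel-level overlap scores (Dice) punish annotation-scale mismatch between
cluster-level ground truth and cell-level predictions, so evaluation is
tile-based: square tiles (default edge 100 µm; a literal 100 µm² area
reading — 10 µm edge — is available via `literal_area`) are laid over the
annotated regions, each tile takes the majority ("greatest coverage") truth
and prediction labels, ties break to the lowest class index, and the pairs
feed a confusion matrix with one-vs-rest precision, recall and
F1 = 2PR/(P+R). Undefined per-class metrics (empty row/column) are reported
as 0 with an explicit flag. Weighted averages are support-weighted, which
makes weighted recall equal overall accuracy — an identity the tests assert
on random matrices. F1 is kept at full precision internally and rounded to
2 d.p. only at the reporting boundary. Cross-validation is case-grouped
3-fold: every slide of a case shares a fold ("leaving out" one case group
per fold), per-fold confusion matrices are summed for the pooled report.

# Group statistics

`compare_groups()` screens both samples with Shapiro–Wilk at α = 0.05 and
then applies Welch's unpaired t-test (both compatible with normality) or
the Wilcoxon rank-sum test, two-sided, significance at 0.05. Welch rather
than Student because equal variances are not assumed for unequal-size arms.
A zero-variance sample is treated as non-normal (Shapiro–Wilk is undefined
there). Doubling time uses the Schwartz exponential-sphere form
DT = Δt·ln2 / (3·ln(d₂/d₁)); shrinking lesions return a flagged negative
DT, equal diameters (infinite DT) are an error.

# Numerical choices and degenerate inputs

* Pixel (i, j) has center (j − 0.5, i − 0.5); polygon membership is
  even-odd on pixel centers, used identically by the generator's
  bookkeeping and `class_areas()`, so truth-mask areas reconcile exactly.
* Glass-threshold comparison is inclusive (≥ 0.30 keeps the tile).
* All argmax tie-breaks go to the lowest class index.
* OD clamps intensities at 1; round trips move intensities by ≤1 unit.
* Blank images, all-glass slides, empty borders, single-class training
  labels, conflicting oracle strokes and 0/0 ratios all have defined
  behaviour (empty results, warnings or errors — never silent zeros).
* Every stochastic step (generation, stroke sampling, forest bootstrap,
  weight init, shuffling, fold assignment) derives from one seed via a
  child-seed splitter; fixed seeds reproduce results bit for bit.

# Problem sizes in the packaged experiments

Unit and acceptance experiments run on one CPU: 128 px slides for the
RF/EITL studies (10 slides, ≤5 iterations each), a 20-slide 128 px cohort
for TME parameter recovery, and the 4×640 px demo for U-Net training.
These sizes are the package's demonstration scale; all components accept
full-size inputs.

# Known limitations

* The synthetic textures are color-dominated; real H&E class boundaries
  are far harder, and reported synthetic scores should not be read as
  expected clinical performance.
* The U-Net trains on CPU in R; it is suitable for the demonstration scale
  and for methodological testing, not for hundreds of full-resolution WSIs.
* Single-level images only (no pyramidal/OpenSlide I/O); stain
  normalization is global mean/variance OD, not deconvolution-based
  (Macenko/Vahadane are out of scope).
* The expert oracle consults ground truth; with real data the loop needs a
  human in its place.
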