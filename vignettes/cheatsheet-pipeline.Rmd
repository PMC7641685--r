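---
title: "Cheat-sheet encoding for mammogram CNNs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cheat-sheet encoding for mammogram CNNs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammocheat)
```

## The idea

Small labeled mammogram collections are the norm: the MIAS database holds
322 mediolateral-oblique (MLO) views (208 normal, 63 benign, 51 malignant),
and the binary task labels malignant cases 1 and everything else 0 — 51
positives against 271 negatives. A CNN trained from scratch on such a set
overfits easily. This package implements a procedure that helps the network
in two complementary ways:

* **a cheat sheet** — classical, human-designed attributes (the mean
  intensity of an "electronic biopsy" of the ROI, and the ROI radius) are
  painted back into the image as two uniform 10-pixel frames around the ROI,
  turning hand-crafted features into visual patterns a convolutional network
  recognizes trivially; and
* **rotation augmentation** — each training image also contributes its 90°
  and 180° rotations, tripling the training set without interpolation
  artifacts.

The pipeline order matters and is fixed: ROI extraction → electronic biopsy
→ frame encoding → train/test split → augmentation (training set only) →
resize to 100 × 100 → CNN. Encoding precedes the split, so cheat-sheet arms
carry frames on test images too; augmentation follows the split, so no
rotation of a test image can leak into training (the experiment harness
asserts this per run from provenance tags).

## ROI extraction

The extraction stage assumes an MLO view: breast tissue attached to one
vertical edge, a brighter pectoral-muscle wedge in the upper corner of that
edge, a dark background, and possibly small bright label artifacts near the
opposite edge.

1. **Side detection** compares the summed intensity of the outer 10% column
   bands. Adding a constant to every pixel leaves the comparison unchanged.
2. **Artifact removal** looks outward from the breast edge for the dark gap
   — the first column whose maximum falls below 10% of the image maximum —
   and zeroes everything on the far side, provided something bright actually
   lies there (otherwise the image is returned untouched).
3. **Pectoral removal** thresholds with Otsu's rule computed on tissue
   pixels (above the same 10% floor) of the top-quarter, breast-side half,
   then removes the connected supra-threshold component containing the top
   corner. On noise-free phantoms the removed set equals the generator's
   wedge mask exactly; the tests assert this.
4. **The initial ROI (IROI)** is the tight bounding rectangle of the
   remaining nonzero pixels; its longer side is recorded as *R*.
5. **Refinement** takes a chromosome (*H*, *W*, CutVal): the refined
   rectangle has height *H·R* and width *W·R* (clipped to the IROI) and is
   placed on a stride-4 grid inside the IROI to maximize the count of pixels
   ≥ CutVal. Ties break toward the top-left placement; if no pixel reaches
   CutVal the IROI is kept and flagged (`fallback = TRUE`) — on normal
   images with no bright focus this is the expected, meaningful outcome.

Two readings were genuinely open and are fixed here as design choices: *H*
and *W* are interpreted as fractions of *R* (the refinement is a zooming
procedure, so *H*, *W* ∈ (0, 1]), and CutVal is used only to score candidate
placements — sub-threshold pixels inside the chosen ROI are kept, since
zeroing them would destroy lesion texture.

The genetic algorithm over the chromosome uses population 30, 20
generations, tournament selection of size 3, uniform crossover at rate 0.8,
per-gene Gaussian mutation with standard deviation 0.1 of the gene range
(clipped to bounds), and elitism of 1 — unremarkable defaults at this
problem size, all configurable via `ga_config()`. The fitness is pluggable:
the expensive option trains the classifier and returns AUOC; for phantom
cohorts `surrogate_lesion_fitness()` scores a chromosome by the fraction of
refined ROIs containing the planted lesion center, which is what the test
suite optimizes.

## Electronic biopsy and frame encoding

The biopsy samples pixels uniformly with replacement from the ROI crop and
averages them. The sample size is not prescribed anywhere, so the default is
10% of the ROI pixel count with a floor of 100; `enumerate = TRUE` averages
every pixel, which is the exact mean and the mode used in tests and worked
examples. The biopsy mean is rounded to the nearest integer for 8-bit
storage (R's round-half-to-even), the radius likewise and clipped at 255.

Frames are *appended* around the crop rather than overwriting its margins —
the encoded image grows by 40 pixels per axis — because overwriting would
destroy ROI pixels, and stripping the frames must recover the crop
bit-exactly (an asserted invariant). On a low-variation (normal) ROI the
outer frame is nearly indistinguishable from the tissue itself; on a bright
lesion it contrasts. That contrast is the signal the cheat sheet adds.

## Augmentation and resizing

Only 90° and 180° rotations are supported, as exact pixel permutations
(90° maps (r, c) to (c, H−1−r) in 0-based coordinates). "Rotation" rather
than mirroring is the chosen reading of the design, since 90°/180° are
rotation angles. Resizing to 100 × 100 uses bilinear interpolation (via
EBImage); no scheme was prescribed, and bilinear preserves constants exactly
and the image mean to well under a grayscale unit. Because resizing happens
after encoding, frame thickness in the final image scales with crop size —
the faithful reading of the pipeline order.

## The classifier

No layer-by-layer architecture is recoverable for the original network, so
the package defines a documented stand-in of equivalent scale, configurable
throughout: three valid-convolution blocks (16, 32, 64 filters, 3 × 3
kernels, ReLU, 2 × 2 max-pool), a dense layer of 64 with dropout 0.5, and a
single sigmoid output; 433,025 parameters at the 100 × 100 input. Training
is mini-batch Adam (learning rate 1e-3, batch 32, 50 epochs by default) on
binary cross-entropy. The loss is class-weighted inversely to class
frequency: with 271 negatives to 51 positives the degenerate all-negative
classifier already scores 84% accuracy, and nothing in the original design
addresses the imbalance, so weighting is this package's choice. The decision
threshold for AC/SE/SP is 0.5 (assumed, and exposed as an argument).

The network is implemented in RcppArmadillo (im2col + GEMM forward and
backward); analytic gradients are verified against finite differences in the
test suite, and training is bit-deterministic for a fixed seed on a given
platform. The validation split holds out `round(0.25 · n)` images — R's
round-half-to-even rule decides ties, so 666 training images yield 166
validation images.

## The four-arm experiment

`run_experiment()` builds OS / DA / CS / DACS arms per the design matrix
(cheat sheet: no/no/yes/yes; augmentation: no/yes/no/yes), redraws the
222/100 split per run with seed `base_seed + run − 1` (the run description
is per-run random selection; a fixed split remains available by reusing a
seed), and shares that seed across arms so each run index sees the same
split — the natural pairing for the downstream paired comparisons, though
whether the original campaign did so is not stated. Each of the 4 × 15 runs
contributes one row of AC/SE/SP/AUOC.

Cheat-sheet arms refine the ROI with a fixed default chromosome
(*H* = *W* = 0.75, CutVal = 170) rather than a per-run GA: the window keeps
most of the tissue while the cut-off sits between the breast base intensity
and lesion peaks of the phantom cohorts, and a GA-optimized chromosome can
be passed to `build_arm()`/`run_experiment()` where the extra cost is
warranted. On normal images no pixel reaches the cut-off and the IROI
fallback engages, which is the intended behavior.

Retraining on MIAS itself is deliberately out of scope for the tests: the
absolute accuracies of a 60-run campaign on external data are stochastic and
data-dependent. Instead the package ships the campaign's run table as a
plain-text fixture and regenerates everything computed from it.

## Statistics

Per-arm summaries are arithmetic means and sample (n−1) standard deviations,
reported at one decimal. Variance comparisons use the one-sided 95% lower
bound (s²ₓ/s²ᵧ)/F₀.₉₅;ₙₓ₋₁,ₙᵧ₋₁; mean comparisons use the pooled-variance t
bound with nₓ+nᵧ−2 degrees of freedom. The pooled form is used because it
regenerates the published H04 bound (8.56) exactly, where the
unequal-variance form gives 8.54. Both operations are equivariant under
scaling (bounds scale by c²) and translation (bounds shift by d), which the
tests assert, and both are cross-checked against `stats::var.test()` and
`stats::t.test()`.

Three published values deserve notes, all flagged by
`reproduce_reference_tables()` rather than silently asserted:

* H05 (published 13.25) and H06 (published 1.45) do not regenerate from the
  run table under the same pooled-t formula that reproduces H04 and the
  headline bounds; recomputation gives 14.19 and 2.39. No differing
  procedure for those two rows is documented, so the recomputed values are
  reported with a `reproduces = FALSE` flag.
* H07 (published −4.56) recomputes to −4.59 — agreement at one decimal but
  not at the printed two; it is treated as reproducing within 0.05.
* The published H03 p-value (0.003) is about twice the one-sided upper-tail
  value (0.0015); H01 and H02 match the one-sided convention, which is what
  the package reports.

## The phantom generator

`generate_phantom()` renders what the removal stages key on, nothing more: a
semi-elliptical breast region attached to one vertical edge (base intensity
140), a brighter triangular pectoral wedge in the upper corner (230), a dark
gap, an optional bright label strip (200) near the far edge, an optional
Gaussian-profile lesion, and additive Gaussian pixel noise. Benign phantoms
default to smaller, dimmer lesions (intensity 185, radius ≈ 0.047 of the
image side) than malignant ones (250, ≈ 0.09) so a small network can learn
the separation at desk scale. The default image side is 256 pixels — enough
structure for every stage while keeping tests fast; MIAS originals are 1024
and the size is configurable.

With zero noise every pixel is analytically predictable, which is what makes
the exact-mask assertions possible. What the phantoms do **not** emulate:
radiographic texture, tissue-density classes, lesion morphology
(spiculation, calcifications), scanner artifacts beyond a label strip, or
anatomically variable pectoral shapes. Passing the phantom suite therefore
demonstrates that the pipeline's logic is correct and that the planted
signal is recoverable — not that the classifier reaches any particular
accuracy on real mammograms.

## Problem sizes in the test suite

The suite keeps its cohorts small by choice: unit fixtures use 64–128-pixel
phantoms; the ROI ground-truth property runs on a 50-phantom noise-free
cohort with a surrogate-fitness GA of population 20 over 10 generations; the
end-to-end check trains the combined DA/CS arm on a 60-phantom cohort
(30/15/15) for 3 runs of 10 epochs with batch 8, requiring mean test AUOC
above 80 against a chance level of 50; and the 60-row counting invariant
uses a one-epoch reduced network. The full-scale defaults (256-pixel
phantoms, 50 epochs, population 30) remain the exported defaults.

## Known limitations

* The refinement placement scans a stride grid (default 4 px), so the
  reported optimum can be off by up to the stride relative to an exhaustive
  scan.
* The pectoral step assumes the wedge is the brightest connected structure
  touching the top corner; unusually dense glandular tissue merging with the
  wedge would be removed with it.
* The CNN is a documented stand-in of equivalent scale, not a reconstruction
  of the original architecture; absolute MIAS accuracies are reproduced via
  the packaged run table, not by retraining.
* `detect_side()` assumes one-sided MLO geometry and fails (by design) on
  constant images; craniocaudal views are out of scope.
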