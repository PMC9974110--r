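---
title: "Invasive-carcinoma detection on whole-slide images: models, filters, and the calibration protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invasive-carcinoma detection on whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(icdetect)
```

## The problem

A whole-slide image (WSI) is a gigapixel pyramidal scan of a stained tissue
section. Invasive carcinoma (IC) of the breast — invasive ductal, invasive
lobular, and mucinous carcinoma, grouped as one positive class against a
"Rest" class of benign and healthy findings — is diagnosed by pathologists
in the nuclear epithelial regions of these slides. `icdetect` implements a
patch-based pipeline that localizes IC on a WSI and produces a slide-level
call, together with a two-phase transfer-learning protocol that keeps the
classifier usable when a laboratory switches to a different scanner or
staining routine.

The pipeline is, in order:

1. **Epithelial filtering.** Fast, non-learned image-processing tests find
   the small fraction of the slide worth analyzing.
2. **Patch parsing.** Epithelial regions are cut into 256×256 patches at
   zoom x20; each patch is paired with a same-center 256×256 patch at
   zoom x5 covering 16× the tissue area.
3. **Patch scoring.** The x5 context image is scored by a convolutional
   feature extractor with a random-forest head; the score is attributed to
   the x20 base patch, which keeps localization resolution at x20.
4. **Slide scoring.** With patch threshold \(P_0\), the slide score is
   \[S_{IC} = \sum_{P > P_0} P \, / \, N,\]
   the sum of above-threshold patch scores over the total number \(N\) of
   epithelial patches. The slide is called IC when \(S_{IC}\) is strictly
   above a slide threshold. Both thresholds are chosen by F1 maximization
   on validation data (an ROC/Youden alternative is exposed via
   `select_threshold(..., method = "roc")`, since the two selection rules
   are both described in the source material for this design).

Because real multi-center hospital cohorts are private, every stage is
exercised on **synthetic slides** with known ground truth; the generator is
first-class, tested code.

## The synthetic stated world

`generate_slide()` renders a 3-level pyramid (downsamples 1/4/16, standing
for x20, x5 and a thumbnail) from polygonal geometry:

* **Stroma** — an eosin-toned value-noise texture over the tissue polygon.
  Its mixing floor is chosen so stroma saturation stays above the tissue
  detector's floor.
* **Benign epithelium** — Poisson-scattered hematoxylin-toned nuclear
  discs, radius 14 px at level 0 (≈ 6 µm at 0.44 µm/px), density
  2.4×10⁻⁴ px⁻², radius CV 0.15, over a faintly tinted cytoplasm.
* **IC** — the same scatter with radius ×1.6, density ×2, and radius CV
  0.4 (enlarged, crowded, pleomorphic nuclei), rendered only inside
  epithelium. At the network's coarse input resolution the dominant
  learnable cue is chromatin density/texture rather than individual
  nuclear outlines — hypercellularity is itself a genuine histological
  signal, so we accept that mean intensity correlates with class.
* **Blur regions** — Gaussian-blurred (σ = 8 px) before scanner noise is
  added, to exercise the blur filter.
* **Center style** (`make_center_style()`) — nuclear/stroma/background
  colors, brightness factor, hue rotation, additive Gaussian noise, and
  µm/px resolution. Styles stand in for the inter-center appearance shift;
  unset fields are drawn from documented ranges so a seed defines a
  plausible center.

What the generator does **not** emulate: real chromatin texture, gland
architecture, mitoses, biopsy-vs-mastectomy differences, stain physics,
scanner optics. A green test therefore establishes that the *pipeline
machinery and its statistical protocol* behave as specified on a world with
known truth — not that the classifier would reach any particular accuracy
on clinical slides.

All outputs are pure functions of (parameters, seed): rendering twice is
bit-identical, and the cohort writer (`generate_cohort()`) emits pyramids,
GeoJSON ROI annotations and a manifest TSV whose IC/Rest classes follow the
"a slide is IC iff it contains an IC region" rule.

## Filtering choices

The original filtering appendix is not publicly available, so the four
tests are documented stand-ins built from standard operators, consistent
with the design goal of "simple, fast, non-learned criteria":

| test | operator | default |
|---|---|---|
| tissue | 3×3-smoothed HSV saturation ≥ floor | 0.08 |
| nuclei | hematoxylin optical density (Ruifrok vector) ≥ floor | 0.40 |
| epithelium | local nuclear-pixel density over a ~patch-sized window ≥ floor, morphological closing, area ≥ 16384 px² | 0.08 |
| blur | variance of Laplacian of the 3×3-smoothed grayscale < floor | 4.0 |

The blur floor was calibrated once on generator output (sharp epithelial
patches measure ≈ 5–80, σ = 8-blurred regions ≤ 3.3 under the noisiest
default style; 4.0 sits between the two populations) *before* the
acceptance tests were written. One field was added beyond the obvious
thresholds: `tissue_fraction_min` (0.10), the patch-level tissue-pixel
fraction below which `no_tissue` fires, so that no constant hides outside
the serialized config. A patch is discarded when **any** flag fires;
flags are computed on the x20 base patch only. The patch grid is aligned
to the level-0 origin (cells `[256i, 256i+256)`), and a cell becomes a
patch when its overlap with the epithelial region is ≥ 0.5.

Coordinate conventions live in one module: level-0 pixels, 0-based,
half-open windows addressed by patch *centers* (forced by the shared-center
x20/x5 construction). Out-of-slide context windows are padded with a
documented background constant, and the padded fraction is recorded, so
edge epithelium is still scored. The x5/x20 geometric contract — the
central 64×64 block of an x5 image equals the 4×4 box-downsampled x20
window — is exact for 4-aligned centers and within a mean absolute
difference of 16 (0–255 scale) for arbitrary centers, where the slack is
pure sub-pixel misalignment (≤ 3 level-0 px).

## The classifier

The reference design is a ResNet50 feature extractor whose final fully
connected layers are replaced by a random forest. Offline, no R
deep-learning runtime exists, so the package ships `tiny_cnn`: three 3×3
convolution blocks (8/16/32 channels) with max pooling, global average
pooling to a 32-dim feature vector, implemented directly on BLAS matrix
products with an exact hand-derived backward pass (verified against
numerical gradients). It exposes the identical contract — image in,
fixed-length features out — at a 64×64 effective input (larger inputs are
block-averaged by a stem). `backbone_arch = "resnet50"` is accepted by the
config and raises an informative error at build time; this narrowing is
deliberate and recorded.

Training follows the published recipe: binary cross entropy, Adam at
initial learning rate 0.001, no frozen layers ever, early stopping on
validation loss (patience 5, min-delta 10⁻⁴ by default) with best-weights
restoration. Augmentation — flips, 90° rotations (free-angle optional),
additive Gaussian noise, hue/saturation/contrast/brightness jitter — uses
fixed documented ranges (the original grid-searched values are
unpublished) and deliberately stays *smaller* than the inter-center style
shift, so that a domain gap survives augmentation; an augmentation range
that swallowed the shift would make the calibration experiment vacuous.

The random-forest head (in-package Rcpp implementation: CART, Gini,
bootstrap, `mtry = √p`, 200 trees grown to purity) consumes the pooled
features and outputs the fraction-of-trees IC probability. Interpretive
choices, each pinned by a test: the forest is **refitted** during
calibration (the feature space moves under fine-tuning); feature pooling is
global average pooling; validation data for early stopping and thresholds
is a 10% patient-level carve-out of the training split; class imbalance is
left unweighted.

## Calibration and the two-phase protocol

`calibrate()` takes the master's weights as the starting state and
continues training on target-center data with the same hyperparameters and
augmentation, then refits the forest and reselects \(P_0\) on target
validation data. The protocol's data-efficiency claim — roughly tenfold
less target data — is enforced as a gate: the fixture experiment uses
2,000 reference vs 200 target training patches, and `run_two_phase()`
refuses target train sets above a configurable fraction (default 1/5) of
the reference.

`calibration_experiment()` reproduces the qualitative 2×2 pattern on
synthetic centers (reference: near-default HES; target: +30° hue, ×0.8
brightness, noise sd 8, independently drawn stain tones):

* master on reference test — high (gate ≥ 0.85),
* master on target test — degraded (gate ≥ 0.15 below),
* calibrated on target test — recovered (gate: within 0.05 of master-on-reference),
* calibrated on reference test — below master-on-reference (forgetting).

These margins gate the synthetic world only; they are not the clinical
accuracies, which were measured on private data and are out of scope here.
The slide-cohort variant (`run_two_phase()`) is validated structurally
(patient-exclusive splits, bundle provenance, the data-efficiency guard)
on deliberately tiny cohorts; the statistical assertions live at patch
level where the sample sizes make them stable.

## Numerical and degenerate-input decisions

* Strict inequalities at both thresholds (`P > P0`, `S_IC > t`); boundary
  behavior pinned by tests.
* Threshold ties break to the **smallest** maximizer over the candidate
  set (sorted unique scores plus 0 and 1).
* Ratios with a zero denominator (precision/recall without positives) are
  reported `NA`, never 0.
* A slide with zero kept patches yields an explicit *no-epithelium*
  outcome (CLI exit code 3), not a Rest call — the safer clinical
  semantics for, e.g., a blank or badly scanned slide.
* `N` in \(S_{IC}\) counts patches **after** quality filtering — the only
  patches that carry scores; the alternative reading (before filtering)
  is noted as interpretive.
* Patient splitting uses an exact subset-sum dynamic program over shuffled
  patients rather than the randomized-greedy sketch: it is deterministic
  under the seed *and* provably ratio-optimal, which the greedy cannot
  guarantee and the acceptance property demands.
* Single-class degenerate validation sets (possible in tiny synthetic
  cohorts) fall back to \(P_0 = 0.5\) with a warning instead of failing
  the whole run; `select_threshold()` itself still errors on single-class
  input, as specified.

## Known limitations

* `tiny_cnn` at 64×64 effective resolution cannot represent fine nuclear
  morphology; on real WSI a ResNet50-scale backbone (and a DL runtime)
  would be required.
* The pyramid container is a package-owned raw-plane directory, not TIFF;
  vendor WSI dialects would enter through `open_slide()` only.
* Perlin-style stroma and disc nuclei are statistically, not visually,
  histology-like; filter thresholds are calibrated to this world and would
  need re-profiling for stained tissue.
* Inference-time augmentation, stain normalization, and multi-center
  (>2) federation are out of scope.
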