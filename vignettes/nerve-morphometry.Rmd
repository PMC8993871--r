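---
title: "Automated histomorphometry of peripheral nerve cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated histomorphometry of peripheral nerve cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervemorph)
```

## The problem

Axon diameter, myelin sheath thickness and g-ratio are standard outcome
measures in nerve regeneration studies and in the staging of neuropathies.
In osmium-stained semithin cross-sections of rodent nerves, myelinated
fibers appear as dark rings (the lipid-rich myelin) around lighter axoplasm
on a bright background. A single extremity nerve contains thousands of such
fibers, so manual straight-line measurement is slow, restricted to small
regions of interest and prone to observer bias: in non-circular fibers the
choice of "representative diameter" is subjective, and manual measurements
tend to overestimate axonal dimensions.

`nervemorph` takes the measurement problem downstream of segmentation: given
a three-class semantic mask (background / myelin / axon) from *any*
segmenter — a neural network, a classical thresholder, or a human annotator
— it extracts per-fiber instances, measures them, scores masks against
ground truth, and quantifies between-method agreement. A synthetic phantom
generator supplies images with exact ground truth so the entire chain is
testable without any acquired data.

## The circular model

All length measurements derive from areas under an equivalent-circle model,
which standardizes measurements across irregular fiber shapes. With
\(A_{axon}\) the axon cross-sectional area and \(A_{myelin}\) the sheath
area (both in µm², from pixel counts times the squared pixel size):

\[
d_{axon} = 2\sqrt{A_{axon}/\pi}, \qquad
t_{myelin} = \frac{2\sqrt{(A_{axon}+A_{myelin})/\pi} - d_{axon}}{2}, \qquad
g = \sqrt{\frac{A_{axon}}{A_{axon}+A_{myelin}}}.
\]

The g-ratio is the equivalent-diameter ratio (axon diameter over fiber
diameter), the standard convention and the one consistent with the diameter
and thickness definitions above; physiological values cluster near 0.6–0.7.
These identities are exact by construction: `g_ratio * fiber_diameter`
equals `axon_diameter` to machine precision, and thickness is zero exactly
when the myelin area is zero.

Shape descriptors (solidity, eccentricity, orientation) and the centroid
are computed on the axon pixel set, since they describe the conduction
pathway; computing them on axon+myelin would mostly reflect the sheath.
Orientation is reported in degrees in \((-90, 90]\), measured from the +x
(column) axis in the image frame (y increases downward); eccentricity comes
from the eigenvalues of the central second-moment matrix, solidity from the
pixel count over the convex-hull-filled pixel count.

## From semantic mask to fibers

Axons are 8-connected components of axon pixels (8-connectivity avoids
spurious splits at rasterized diagonals of near-circular objects);
components under `min_axon_px` (default 5 px, ≈ 0.25 µm equivalent diameter
at 0.1 µm/px) are discarded as noise. Each myelin pixel is then assigned to
the axon component at the smallest Euclidean distance — computed exactly via
one distance transform per component, with ties going to the lower fiber id
— provided its 8-connected myelin component touches at least one axon.
Myelin components touching no axon remain *orphan* and never enter fiber
morphometry; they are counted and reported separately, since attributing
stray myelin (e.g. debris, artifacts) to a fiber would corrupt its
thickness.

Fibers whose axon *or assigned myelin* reaches the first/last row or column
are flagged `BORDER`: a fiber cropped by the region of interest has a
truncated sheath and a biased thickness, so border fibers are excludable
(`exclude_border_fibers()`, preserving ids). Excluding them skews samples
toward smaller fibers — which is why whole-section analysis is preferable to
small ROIs in the first place.

Records are never deleted by screening: `flag_artifacts()` adds `LOW_G`
(g < 0.35), `HIGH_G` (g > 0.90) and `SMALL_AXON` (d < 0.30 µm) flags.
Misclassified myelin-split artifacts typically produce near-zero diameters
with very low g-ratios; unmyelinated axons misread as thinly myelinated
fibers produce unphysiologically high g-ratios. The 0.35 floor is the
established screening threshold; the 0.90 ceiling and 0.30 µm diameter
floor are this package's defaults for the qualitatively described artifact
signatures, and all three are configurable.

## Evaluation

Pixel-level scoring uses the five standard overlap quantities for a source
mask \(S\) (automated) and target \(T\) (ground truth), per class:
overlap \(|S\cap T|/|T|\), Jaccard \(|S\cap T|/|S\cup T|\),
Dice \(2|S\cap T|/(|S|+|T|)\), false-negative error \(|T\setminus S|/|T|\)
and false-positive error \(|S\setminus T|/|S|\). Ratios with empty
denominators are reported as `NA`, never silently as 0; two empty sets get
Jaccard = Dice = 1 (vacuous agreement). The identities
\(\mathrm{Dice} = 2J/(1+J)\) and overlap \(= 1 - \mathrm{FNE}\) hold for
every computed pair and are property-tested.

Object-level detection uses one-to-one instance matching: candidate pairs
are axon components with positive pixel intersection (an IoU floor is
available; the default accepts any overlap), selected greedily by
descending intersection with deterministic tie-breaks. One-to-one matching
is essential — without it a prediction split across one true fiber would
count twice. Greedy selection can in principle fall short of the optimal
assignment; the test suite checks it against brute-force enumeration on
small instance sets (equal cardinality in ≥ 95% of random cases, never
exceeding it). TP/FP/FN then give precision, sensitivity and F-score;
metrics are carried at full precision and only rounded for display
(half away from zero, two decimals).

Agreement between two morphometry sources is quantified per fiber with
Bland–Altman analysis in the B − A direction (A = automated, B = ground
truth): bias = mean difference, limits of agreement = bias ± 1.96 × SD of
the differences (sample SD, n − 1). The normal-theory 1.96 multiplier is
used without a small-sample t correction; for the hundreds of fibers
typical of a section the difference is negligible. Group-level testing
(ANOVA and post-hoc comparisons) is deliberately out of scope: the package
exports tidy per-fiber tables that any statistics environment consumes
directly.

## Tiled segmentation

Large sections are processed as overlapping 512 × 512 patches:
resample to the working resolution (default 0.1 µm/px) divided by the zoom
factor, optional auto-contrast (percentile-clipped linear stretch, 0.1% per
tail by default — monotone, so pixel ordering is preserved), split, segment
each patch, stitch, and resample labels back to the native pixel size and
shape. Anchors are laid at stride `patch − overlap` plus a final anchor
clamped to the image edge; undersized images are reflect-padded. In
overlaps, per-class scores are averaged; the final argmax breaks ties with
priority axon > myelin > background so thin axons are not erased. The zoom
factor multiplies the working resolution (a 0.55× zoom coarsens pixels to
avoid over-segmentation of large fibers); since the order of zoom and
resampling composes into a single working pixel size, the pipeline applies
them as one resampling step.

Two numerical choices matter here. Bilinear resampling uses pixel-center
alignment (`src = (dst + 0.5)·scale − 0.5`), which makes resampling at an
unchanged scale the exact identity — so a split→stitch round trip with
one-hot scores reproduces any mask bit-exactly, for every tested shape and
overlap. Label resampling converts classes to indicator planes, resamples
them bilinearly and takes the argmax (same tie priority), keeping labels
categorical while interpolating boundaries smoothly; it is idempotent at a
fixed scale.

The built-in classical baseline (`baseline_segment`) thresholds dark pixels
as myelin (Otsu by default, or a fixed threshold) and promotes enclosed
holes of at least `min_hole_px` to axon. It exists so the pipeline and
evaluation suite run end-to-end with a fully transparent segmenter, and as
the default for the `segment` CLI subcommand; any per-patch function
returning class scores (e.g. a CNN wrapper) can replace it. Its known
failure mode is instructive: a fiber whose myelin ring is cut by a patch
seam cannot be hole-filled inside either patch, so seam-straddling fibers
are missed (sensitivity ≈ 0.9 on a 1024² phantom with 512-px patches)
while matched fibers are measured essentially without bias. Appearance-based
segmenters do not share this mode, which is one reason learned models
tolerate tiling better.

## The phantom generator

`simulate_sample()` emulates the geometry and contrast of osmium-stained
cross-sections: bright background (gray 230), dark annular myelin (40),
intermediate axoplasm (150), Gaussian noise (SD 8), densely packed
non-overlapping elliptical fibers. Fibers are parameterized by *equivalent
diameter*, so the simulated truth is definitionally commensurate with the
circular-model morphometry: the outer ellipse has equivalent diameter
`d/g` and the concentric inner ellipse equivalent diameter `d`.

Default population: axon diameters lognormal with distribution mean 4 µm
and `sdlog` 0.15 (a regenerating-nerve-like, moderately dispersed caliber
spectrum — healthy adult nerves are broader and often bimodal, which the
two-component mixture option covers); g-ratio truncated-normal with mean
0.65, SD 0.05 on (0.40, 0.85); eccentricity uniform on [0, 0.3]; placement
by dart-throwing, largest fiber first, with a 2-px minimum boundary gap
enforced conservatively through the circumscribed circles. Unplaceable
fibers are dropped and reported. One seeded RNG stream drives all stages:
identical configurations give byte-identical outputs.

Two artifact types reproduce the documented confounders. Myelin-split
artifacts (per-fiber probability `p_split`) cut a bright 1–2 px
circumferential band through mid-annulus *in both image and truth mask* —
separated lamellae are real tissue structure that a faithful segmenter should
transcribe, and they produce the double-ring / tiny-axon signature.
Unmyelinated-fiber distractors (`p_unmyelinated`) are dark disks drawn in
the image only: they are not myelinated fibers, and a segmenter that labels
them becomes a false positive with an unphysiologically high g-ratio.

What the phantom does *not* emulate: partial-volume blur at class
boundaries (classes meet at hard edges, which is why a well-placed
threshold segments non-seam fibers pixel-perfectly), staining gradients,
Schwann cell nuclei, blood vessels, fascicle boundaries, and irregular
(non-elliptical) fiber outlines. Passing tests on phantoms therefore
demonstrate correctness of the measurement and evaluation machinery — not
segmentation performance on real histology, which depends on the segmenter
plugged into the pipeline.

## Problem sizes and reproducibility

The test suite validates formulas and invariants on closed-form fixtures
and small random masks, parameter recovery on a 2048² phantom with 200
fibers, and the end-to-end pipeline on a 1024² phantom with 50 fibers —
sizes chosen so the full suite runs in about a minute on one CPU while
keeping Monte-Carlo standard errors well inside the asserted tolerances
(at n = 200 the SE of the mean diameter is ≈ 1% of the 4 µm mean, against
a 2% tolerance). `scripts/acceptance.R` re-runs the 1024²/50 pipeline from
scratch under a caller-supplied seed and writes every headline quantity as
JSON. Every randomized test fixes its seed; the simulator never touches the
global RNG state outside its own call.

## Known limitations

- Myelin assignment follows Euclidean proximity. In pathologically
  asymmetric sheaths the proximity partition may differ from a human
  tracing of lamellae, though the total myelin area is unaffected.
- The orientation convention (degrees, y-down image frame) must be kept in
  mind when comparing against tools reporting radians or y-up angles.
- The classical baseline is a transparency tool, not a competitive
  segmenter: no texture model, no seam-aware hole filling.
- Spreadsheet (.xlsx) export is not provided; the CSV interface is
  normative and opens in any spreadsheet application.
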