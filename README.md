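# nervemorph

Segmenter-agnostic histomorphometry for peripheral nerve cross-sections.

Nerve regeneration studies and neuropathy staging rely on per-fiber axon
diameter, myelin sheath thickness and g-ratio, traditionally measured by
hand on small regions of osmium-stained semithin sections. `nervemorph`
automates everything downstream of segmentation: given a three-class
semantic mask (background / myelin / axon) from any source — a neural
network, a classical thresholder, or a human annotator — it

- extracts per-fiber instances (axon connected components + exact
  nearest-distance myelin assignment, with ROI border exclusion),
- measures each fiber under the equivalent-circle model,
- scores predicted masks against ground truth at pixel level (overlap,
  Jaccard, Dice, false negative/positive error) and object level
  (one-to-one matching, precision / sensitivity / F-score),
- quantifies between-method agreement per fiber with Bland–Altman bias and
  95% limits of agreement,
- orchestrates patch-based tiled segmentation (512-px patches, configurable
  overlap and zoom, score-averaged stitching) around a pluggable per-patch
  segmenter, with a classical threshold-and-fill baseline built in, and
- generates synthetic nerve cross-section phantoms with exact ground truth
  (fiber geometry, masks and per-fiber truth tables) for validation.

All lengths derive from areas, assuming an ideal circular shape:

```
axon diameter      d = 2 * sqrt(A_axon / pi)
myelin thickness   t = (2 * sqrt((A_axon + A_myelin) / pi) - d) / 2
g-ratio            g = sqrt(A_axon / (A_axon + A_myelin))
```

Masks are 8-bit single-channel PNG/TIFF with background = 0, myelin = 127,
axon = 255. The pixel size (µm/px) is always supplied explicitly — never
read from image metadata.

## Worked example

```r
library(nervemorph)

# a 1024x1024 phantom at 0.1 um/px with 50 fibers
cfg <- simulation_config(width = 1024, height = 1024, n_fibers = 50, seed = 1)
s <- simulate_sample(cfg)

# segment the image with the tiled classical baseline, then measure
pred <- run_tiled_segmentation(
  s$image, function(p) baseline_segment(p, myelin_threshold = 95))
fs  <- build_fiber_set(pred)
tbl <- flag_artifacts(measure_fiber_set(fs))
tbl[1:3, c("fiber_id", "axon_diameter_um", "myelin_thickness_um", "g_ratio")]
#> # A tibble: 3 x 4
#>   fiber_id axon_diameter_um myelin_thickness_um g_ratio
#>      <int>            <dbl>               <dbl>   <dbl>
#> 1        1             3.61               0.894   0.669
#> 2        2             4.07               0.971   0.677
#> 3        3             4.85               1.58    0.606

# evaluate against the simulation's ground truth
rep <- evaluate_masks(pred, s$truth_mask)
rep$pixel$myelin$dice        #> [1] 1
rep$detection
#> <detection_counts> present 50, detected 45 | TP 45 FP 0 FN 5 | P 1.00 S 0.90 F 0.95

# per-fiber agreement, automated (A) vs ground truth (B)
truth_tbl <- measure_fiber_set(build_fiber_set(s$truth_mask))
bland_altman(pair_by_match(tbl, truth_tbl, rep$match, "axon_diameter_um"))
#> <agreement_result> axon_diameter_um: n 45, bias 0.0000, SD 0.0000, 95% LoA [0.0000, 0.0000]
```

Fiber 1 is a 3.6 µm axon wrapped in a 0.89 µm sheath (g = 0.67, i.e. the
axon accounts for 67% of the fiber diameter — typical physiology). The five
false negatives are fibers straddling a patch seam, a documented limitation
of the hole-filling baseline (not of the tiling pipeline); the matched
fibers are measured with zero bias because the noiseless-boundary phantom
is separable exactly by a threshold. See the methods vignette
(`vignettes/nerve-morphometry.Rmd`) for the model, parameter defaults and
what phantom results do and do not show about real histology.

## Command line

A thin wrapper around the same functions is installed as `exec/nervemorph`:

```sh
nervemorph simulate --seed 7 --n-fibers 50 --out run/sim
nervemorph segment  --image run/sim/image.png --pixel-size 0.1 --threshold 95 --out run/seg
nervemorph measure  --mask run/seg/segmentation.png --pixel-size 0.1 \
                    --exclude-border --out run/morph.csv --overlay run/overlay.png
nervemorph evaluate --pred run/seg/segmentation.png --truth run/sim/mask.png \
                    --out run/report.json --pairs run/pairs.csv
nervemorph agree    --a run/morph.csv --b run/truth_morph.csv --match run/pairs.csv \
                    --metric axon_diameter_um --out run/agree.json
```

Each subcommand writes a `manifest.json` with its resolved parameters;
reruns with the same seed and inputs are bit-identical. Exit codes: 0
success, 2 usage error, 1 runtime failure.

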