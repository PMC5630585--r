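# starcut

Interactive, seed-based segmentation of hypoechoic liver lesions in 2-D
B-mode ultrasound images, for researchers who need reproducible
semiautomatic lesion outlines and the agreement metrics that go with them
(Dice score, Hausdorff distance, perpendicular diameters, intraclass
correlation).

During routine follow-up of cancer patients, liver metastases are outlined
on B-mode ultrasound to track their size. Manual outlining is slow and has
poor inter-observer agreement; `starcut` implements a semiautomatic
alternative: the user clicks one seed point inside the lesion, the
algorithm instantly returns a closed contour, and optional *helper seeds*
on the lesion border refine it locally. Because clinical images cannot be
redistributed, the package also ships a synthetic speckle-phantom
generator with known ground truth and a batch evaluation harness, so the
whole pipeline is testable end to end.

## The algorithm

A circular template of `K` radial rays with `N` nodes each is sampled
around the seed (bilinear interpolation, clockwise from "up"). With
`m` the mean gray value around the seed and `a_i = |g_i − m|` the absolute
gray deviation at node `i` of a ray, a directed graph is built:

* ∞-capacity **intra-edges** (node `i` → `i−1` along each ray) make the
  foreground a radius-prefix on every ray — the cut is **star-shaped**;
* ∞-capacity **inter-edges** (node `(k, i)` → `(k±1, max(0, i−Δr))`, with
  wrap-around) enforce the circular smoothness constraint
  `|c_k − c_{k±1}| ≤ Δr` on the per-ray cut indices (default `Δr = 2`);
* **terminal edges**: node 0 → source with `a_0`, node `N−1` → sink with
  `a_{N−1}`, interior node `i` with `|a_i − a_{i−1}|` to the source when
  `a_i − a_{i−1} < 0`, else to the sink.

The minimum s-t cut (max-flow, solved exactly) is converted to one
sub-pixel contour vertex per ray, rasterized to a mask, and the maximal
diameter *a* plus the perpendicular diameter *b* are measured in
millimeters. A helper seed pins the cut on its ray to the clicked radius
through ∞-edges. When several minimum cuts exist, the unique outermost one
is returned (deterministic), and an independent dynamic-programming oracle
verifies the solver exactly in the tests.

## Worked example

Segment a generated phantom with the centroid seed and the automatic
boundary-helper refinement (at most 4 helper seeds):

```r
library(starcut)

pc <- generatePhantom(phantomSpec(imageSize = 160, baseRadius = 40,
                                  harmonics = rbind(c(0.08, 3, 1)),
                                  lesionGain = 0.2, spacing = 0.25,
                                  rngSeed = 7))
seg <- segmentPhantomCase(pc, kMax = 4)
seg$result
#> SegmentationResult: seed=(79, 79), 4 helper(s), 60-vertex contour,
#>   area 3817 px, a=19.7 mm, b=19.0 mm, flow=1239

diceScore(lesionMask(seg$result), truthMask(pc))        # 86.1 %
hausdorffDistance(lesionMask(seg$result), truthMask(pc)) # 10 px
diametersOfMask(truthMask(pc))
#> DiameterPair: a=20.38 mm, b=19.93 mm
```

The printed result reports the refined contour (one vertex per ray), the
lesion area in pixels, the automatically measured diameters (the 10 mm
phantom radius at 0.25 mm/px gives a ≈ 20 mm true diameter — the
algorithm recovers 19.7 mm), and the min-cut flow value. The Dice score
says 86 % of the combined area agrees with ground truth; the Hausdorff
distance bounds the worst contour deviation at 10 px.

For interactive use on your own images:

```r
img <- readUltrasound("lesion.png")               # PNG, TIFF or DICOM
res <- segmentLesion(img, seed = c(210, 180))
res <- resegment(res, addHelpers = list(c(250, 140)))  # refine locally
writeMask(lesionMask(res), "lesion_mask.png")
writeContour(res, "lesion_contour.csv")
```

A thin command-line front end with the same functionality (plus suite
generation and batch evaluation, YAML-configurable) is installed at
`system.file("scripts", "uscut.R", package = "starcut")`.

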