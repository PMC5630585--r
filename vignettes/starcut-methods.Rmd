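---
title: "Star-shaped graph-cut segmentation of hypoechoic ultrasound lesions: methods and design"
author: "starcut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-shaped graph-cut segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starcut)
```

# The segmentation model

`starcut` segments a single hypoechoic lesion in a 2-D B-mode ultrasound
image from one user-supplied seed point placed inside the lesion.  The
construction is a *radial-ray graph cut*:

* $K$ rays are distributed equidistantly around the seed, clockwise on
  screen starting from "up"; along each ray, $N$ nodes are sampled at radii
  $(i+1)\,R/N$, $i = 0,\dots,N-1$, where $R$ is the template radius
  (`maxRadius`).  Gray values at sub-pixel node positions are obtained by
  bilinear interpolation; positions outside the image clamp to the border
  pixel, so the template may exceed the field of view on large lesions.
* Two virtual terminals $s$ (source = lesion) and $t$ (sink = background)
  are added.  A minimum $s$-$t$ cut partitions the nodes into foreground
  and background.
* **Intra-edges**: along each ray, $\infty$-capacity directed edges run
  from node $i$ to node $i-1$.  They force the foreground on each ray to be
  a radius-prefix, so the cut crosses each ray exactly once — the resulting
  contour is *star-shaped* about the seed.
* **Inter-edges**: from each node $(k, i)$, $\infty$-capacity edges run to
  node $(k \pm 1 \bmod K,\ \max(0, i - \Delta_r))$.  They enforce the
  circular smoothness constraint $|c_k - c_{k\pm1}| \le \Delta_r$ on the
  per-ray cut indices $c_k$: the larger $\Delta_r$, the more flexible the
  contour.  The package follows the fixed evaluation setting
  $\Delta_r = 2$.
* **Terminal edges** encode the image.  Let $m$ be the mean gray value in
  an `avgWindow`$\times$`avgWindow` square around the seed and
  $a_i = |g_i - m|$ the absolute deviation of the sampled gray at node
  $i$.  Node 0 is bound to the source with capacity $a_0$ and node $N-1$
  to the sink with capacity $a_{N-1}$.  Each interior node is bound with
  capacity $|a_i - a_{i-1}|$ — to the source when $a_i - a_{i-1} < 0$, to
  the sink when $\ge 0$ (a zero difference ties to the sink).

Because only terminal edges have finite capacity, the severed capacity of
a feasible cut is the sum, over rays, of the terminal capacities cut at
index $c_k$, and the max-flow solution is the global optimum over all
star-shaped, $\Delta_r$-smooth contours.

## What the weight rule actually optimizes

A short telescoping argument is central to understanding the method's
behavior, so we record it here.  Writing the per-ray cost of cutting at
index $c$ (sink capacities at nodes $\le c$ plus source capacities at
nodes $> c$), consecutive costs differ by exactly the signed difference
$a_{c+1} - a_c$, so

$$\mathrm{cost}_k(c) \;=\; a_{k,c} + \text{const}_k, \qquad c \le N-2 .$$

The minimum cut therefore selects, per ray and subject to the smoothness
coupling, the node whose gray value is *closest to the seed average* $m$.
Two consequences follow:

1. On a lesion with a homogeneous interior (noiseless disc, or a nearly
   texture-free hypoechoic lesion), *every* interior index ties at cost
   $\approx 0$ while nodes beyond the boundary pay the full contrast, so
   the choice of minimum cut among the ties decides everything (next
   section).
2. On an interior with strong speckle texture, the per-node costs inside
   the lesion are noise-like and statistically flat in radius, so the
   unconstrained contour settles on noise minima *anywhere inside* the
   lesion rather than at its boundary.  Helper seeds (below) are then the
   mechanism that anchors the contour; this matches the interactive usage
   the method was designed for, and it is the package's main documented
   limitation (see the last section).

## Tie-breaking: the outermost minimum cut

Minimum cuts are generically non-unique here (consequence 1 above).  The
package always returns the unique *maximal source side*, computed as the
complement of the set of residual-graph vertices that can still reach the
sink after max-flow.  Among all minimum cuts this is the outermost
contour.  The choice is deliberate:

* on the noiseless disc it puts the cut at the last interior node, i.e.
  at the true boundary (midpoint vertex placement then lands on the edge
  within half a node spacing plus the $\sqrt2$-pixel bilinear support
  margin);
* it is deterministic and keeps flow values exact (no epsilon
  perturbation of integer capacities), which the dynamic-programming
  oracle tests exploit for bit-exact equality.

The flip side is the degenerate case: on a perfectly uniform image every
cut has zero cost and the contour sits at the outermost feasible radius
(a circle at `maxRadius`).  The innermost convention was considered and
rejected because it collapses the contour to the first node on *any*
homogeneous lesion interior, not only on degenerate inputs.

## Helper seeds

A helper seed placed on the lesion border is mapped to its nearest ray
$k$ and node index $i$; nodes of that ray at or inside $i$ receive an
additional $\infty$-edge to the source and nodes beyond $i$ to the sink,
which forces $c_k = i$ exactly.  Neighboring rays follow through the
$\Delta_r$ constraint.  Helpers farther from the seed than `maxRadius`
are rejected; two helpers mapping to the same ray keep the last one with
a warning.  The "gray value" information helpers could contribute is
deliberately *not* used to re-estimate $m$ by default: index pinning alone
reproduces the described interactive behavior deterministically.
Re-running with a dragged seed or additional helpers is a pure function
call (`resegment`), equivalent to a fresh segmentation with the union of
the inputs.

# Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `nRays` $K$ | 60 | contour vertices; 6° angular resolution |
| `nNodes` $N$ | 40 | radial quantization; with the default template radius this is roughly 1–5 px node spacing at typical lesion scales |
| `maxRadius` $R$ | `min(border distance, 0.45 min(H, W))` px | the circular template should be able to cover the lesion from any interior seed without leaving the image more than necessary |
| `deltaR` $\Delta_r$ | 2 | radial steps the cut may move between adjacent rays |
| `avgWindow` | 9 px | seed-average window; large enough to average speckle, small enough to stay inside a 30 px lesion |

All are overridable per call and from the command line
(`inst/scripts/uscut.R`).

# The synthetic phantom model

No clinical images ship with the package, so every claim is tested on
synthetic speckle phantoms with known ground truth
(`generatePhantom`, `generateSuite`):

* **Geometry.** A star-shaped lesion boundary
  $r(\theta) = r_0 (1 + \sum_j A_j \sin(f_j \theta + \varphi_j))$ with
  amplitudes $A_j \le 0.25$ and integer frequencies 2–6; single-valued in
  $\theta$, hence star-shaped by construction — the phantom stays within
  the model class of the segmentation prior.  Ground truth is the
  rasterization of this contour (360 vertices) by the package's own
  pixel-center even-odd rasterizer.
* **Echogenicity.** Background 1.0, lesion `lesionGain` $< 1$
  (hypoechoic), optional echo-poor halo ring of width `haloWidth` at
  `haloGain` between lesion and background.  The halo is *excluded* from
  the ground truth by default (the "thin halo" reading); a flag includes
  it, mirroring the two legitimate clinical readings of whether the
  echo-poor rim belongs to the lesion.
* **Speckle.** $L$-look intensity speckle: per-pixel unit-mean
  gamma-distributed intensities with shape $L$ (the distribution of the
  average of $L$ squared independent zero-mean complex Gaussian fields),
  multiplied by the echogenicity map, blurred by a Gaussian PSF
  ($\sigma$ = `psfSigma`), then log-compressed
  ($g \propto \log(1 + 20 I)$, mapped to 0–255).  The pre-compression
  intensity field is kept on the `PhantomCase` so first- and second-order
  speckle statistics (CV $= 1/\sqrt{L}$, lesion/background mean ratio
  $=$ `lesionGain`) can be verified directly; those checks are run with
  `psfSigma = 0` because the PSF, applied to intensity, necessarily
  reduces the point-wise CV.

**Suite defaults** (chosen once from B-mode physics and frozen): $L = 16$
looks (modern scanners compound heavily), PSF $\sigma = 1.5$ px, lesion
gain uniform in 0.10–0.35 (−5 to −10 dB), halo in 30 % of cases
(gain 0.45–0.7, width 2–6 px), one low- plus one mid-frequency harmonic
with amplitudes 0.03–0.12 and 0.01–0.05.  Maximal diameters follow a
log-normal calibrated to the clinical size distribution of liver
metastases (median 20 mm, quartiles near 14 and 27 mm), truncated to
6–115 mm; each case is rendered at a zoom mapping its diameter
monotonically into 30–250 px, with the mm/px spacing set accordingly.
All randomness derives from a single master seed (default 42), and
regeneration is bit-identical.

**What the phantoms do not emulate:** attenuation and shadowing,
depth-dependent PSF anisotropy, reverberation and side-lobe artifacts,
heterogeneous lesion interiors, neighboring anatomy (vessels, diaphragm),
and the reduced speckle contrast of nearly scatterer-free (anechoic)
lesion cores — the multiplicative gain model keeps full speckle contrast
inside the lesion, which is the *hard* case for this weight scheme.
Passing the phantom suite therefore demonstrates correct mechanics and
behavior under fully developed speckle; it does not certify clinical
accuracy on real images.

# The evaluation harness

`evaluateSuite` emulates the reported study protocol on phantoms: the
seed goes to the truth-mask centroid; the cut is solved; then up to
`kMax` (default 4) *auto-boundary helper seeds* are placed, one at a
time, on the true boundary at the ray of maximal current radial error,
re-solving after each (an explicit surrogate for an examiner's
refinement clicks, not a claim about human behavior).  Candidate rays
whose pin would be jointly infeasible with existing pins under
$\Delta_r$ are skipped, and refinement stops early when the maximal
radial error falls below one node spacing.  Per case the harness reports
the Dice score (percent), the symmetric Hausdorff distance (pixels,
exact Euclidean distance transforms), and the absolute differences of
the automatically measured perpendicular diameters (mm); the summary
adds medians, percentile-bootstrap 95 % CIs of the medians
(deterministic seed), and the fraction of cases counted as satisfied
under a DSC $\ge 70\,\%$ proxy.  A case's "dissatisfied" state has no
feedback into the computation.

```{r eval = FALSE}
ev <- evaluateSuite(nCases = 105, masterSeed = 42, kMax = 4)
ev            # medians, CIs, satisfied rate
```

`scripts/acceptance.R` re-runs exactly this and writes the two medians to
JSON.  On the packaged default suite the median Dice is about 86 % and
the median Hausdorff distance about 14 px; the helper-free run
(`kMax = 0`) collapses to a median Dice near 24 %, which is the
speckle-wandering phenomenon of the cost identity above, quantified.

# Numerical choices

* **Coordinates.** 0-based, $x$ = column, $y$ = row, origin top-left,
  shared by every module.  Matrix access is `pixels[y + 1, x + 1]`.
* **Rasterization.** A pixel is foreground iff its center is inside the
  polygon under the even-odd rule; centers exactly on an edge follow a
  half-open top-left rule, so an axis-aligned $d \times d$ square always
  rasterizes to exactly $d^2$ pixels and results are deterministic.
* **Contour vertices** sit at the midpoint between the last foreground
  and first background node (at `maxRadius` when $c_k = N-1$),
  minimizing the expected quantization error of $\pm$ half a node
  spacing.
* **Infinity** is represented as (sum of all finite capacities) + 1,
  which no finite cut can reach, keeping arithmetic exact for integer
  capacities.
* **Degenerate inputs.** Empty masks: Dice of two empty masks is 100 %,
  Hausdorff and diameters raise errors; a single-pixel mask has
  diameters of one pixel extent.  Uniform images segment to the
  outermost feasible circle (documented above).  Jointly infeasible
  helper pins raise an informative error rather than returning an
  $\infty$-cut.
* **ICC.** The two-way random-effects, absolute-agreement,
  single-measurement form ICC(A,1), computed from the mean-square
  decomposition; the variant is printed in every JSON summary.  Absolute
  agreement is the standard choice for inter-operator variability
  because it penalizes systematic rater offsets.
* **DICOM.** A minimal reader for uncompressed little-endian
  single-frame grayscale files (the only DICOM flavor in scope);
  anisotropic `PixelSpacing` is averaged with a warning since the whole
  pipeline treats pixels isotropically.  Compressed transfer syntaxes
  and multi-frame files raise unsupported-format errors.

## Problem sizes used by the test suite

The shipped tests run the full 105-case suite once (about a minute), 200
random solver-vs-oracle instances at $K \le 8$, $N \le 12$, 100
random-image smoothness checks, 50 helper-pinning trials, and an 88-case
two-rater ICC recovery — sizes chosen so the whole suite completes in a
few minutes while each property retains clear statistical power.

# Known limitations

* The cost identity makes boundary localization rely on interior
  homogeneity or helper anchoring; under fully developed interior
  speckle the helper-free contour is unreliable, and with 4 helpers the
  contour can still sag between pinned rays by up to
  $\Delta_r \cdot R/N$ px per ray step.  The Hausdorff distance is the
  metric most sensitive to this, and the phantom-suite median HD
  (about 14 px) reflects it.
* A thick echo-poor halo is genuinely ambiguous: the algorithm treats
  intermediate-echogenicity rings as background unless helpers (or the
  halo-in-truth convention) say otherwise — the same failure mode
  reported for the clinical workflow this package models.
* Star-shaped contours only; multi-lesion scenes, 3-D data, cine loops
  and color Doppler are out of scope.
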