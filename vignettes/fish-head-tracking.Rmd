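---
title: "Tracking multiple fish by head detection: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking multiple fish by head detection: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishHeadTracker)
```

## The problem

Quantitative analysis of collective fish behavior needs per-individual
trajectories from top-view video of a tank. Whole-body tracking is fragile:
a swimming fish deforms continuously, and fish cross and occlude one
another, so blob-level trackers merge, split and lose identities.
`fishHeadTracker` implements a detection-first alternative: track only the
fish *head*. The head deforms little during swimming, occupies a small part
of the body (so it is occluded with lower probability), and carries a
well-defined orientation. Detections are then linked frame to frame with a
gated, globally optimal assignment that keeps the population size fixed
through occlusions.

## Detection model

**Moving-region segmentation.** With a static tank and mobile fish, the
per-pixel temporal median of the first `nBackgroundFrames` frames is a
robust background model. A pixel belongs to a moving region when the
absolute difference between background and frame strictly exceeds `tG`
(gray levels). The raw mask is cleaned in a fixed order: interior holes are
filled, connected components smaller than `minBlobArea` pixels are
discarded, and a binary median smoothing with a `medianKernel` window is
applied. For an even number of background frames the *lower* middle order
statistic is used, which keeps every background pixel an attainable gray
level of the camera.

**Centerline extraction.** The cleaned region of an elongated fish is
summarized by its centerline, computed with an augmented fast marching
skeletonization. The boundary of each component is traversed once
(clockwise Moore-neighbor contour following from the lexicographically
smallest boundary pixel) and parameterized with arrival values
U = 1, ..., L. U is then propagated inward so that every interior pixel
carries the U of its nearest boundary point; a pixel belongs to the
skeleton when the U values of its +x and +y neighbors differ from its own
by more than `tU`. Because U jumps from L back to 1 at the traversal seam,
every difference d is wrap-corrected to min(d, L − d) before thresholding;
without this correction a spurious skeleton ray appears at the (otherwise
arbitrary) traversal start, and with it the output is invariant to the
start choice. `tU`, measured in boundary pixels, is the pruning knob: small
values keep side branches (more detail, more burrs), large values retain
only the main body curve. The raw detector can yield a two-pixel-thick
ridge, so the ridge is thinned to unit width with Guo–Hall two-subiteration
thinning — chosen because it reduces 2-px diagonal ridges to a clean 1-px
curve, where Zhang–Suen-style schemes either keep them 2 px thick or erase
them entirely — and 1–3 px spur artifacts of thinning at line ends are
pruned before the skeleton is organized into endpoints, junctions and
branches. (Genuine side branches from occlusion are far longer and are
left to the branch-length filter.)

Inside the propagation we track, for every pixel, the coordinates of the
boundary pixel it inherited U from, and a pixel's arrival time is the exact
Euclidean distance to that source. On convex test shapes this keeps each
pixel's source within a pixel (in distance) of its true nearest boundary
point, which is what makes the wrap-corrected differences faithful to the
medial structure — a rectangle's skeleton lands on its midline and a disk's
collapses to its center.

**Head endpoints.** Skeleton endpoints mark the head and tail tips; under
occlusion, extra branch endpoints can appear elsewhere on the body. Two
filters isolate heads. First, endpoints whose along-skeleton (geodesic)
distance to the nearest junction is at most `tL` pixels are discarded as
burrs; endpoints of junction-free skeletons are always kept, since a clean
single fish has no junction at all. Second, the local body width at each
surviving endpoint is measured as the diameter of the largest inscribed
circle — twice the exact Euclidean distance from the endpoint to the
nearest background pixel — and endpoints wider than `tW` are heads (the
head is wider than the tail). If one connected component produces several
super-threshold endpoints (overlapping fish), all are emitted; sorting them
out is the tracker's job.

**Head direction.** At each head endpoint the orientation is estimated from
the eigenstructure of the Hessian of the (foreground-bright) image:
second-order Gaussian-derivative responses L_xx, L_xy, L_yy at scale *s*,
combined into the scale-normalized determinant
D = (L_xx·L_yy − L_xy²)·s⁴. The scale maximizing |D| over `scales` is
selected, adapting the operator to the head size. With eigenvalues ordered
|λ1| ≥ |λ2|, the eigenvector α2 of the smaller-magnitude eigenvalue points
along the axis of least curvature, i.e. along the head; θ = atan2(α22, α21).
An eigenvector is only defined up to sign, a point the eigen-decomposition
cannot resolve; we orient θ outward through the endpoint by requiring a
positive dot product with the local skeleton tangent (the unit vector from
the fifth skeleton pixel inward toward the endpoint). Patches whose
eigenvalue ratio |λ1|/|λ2| falls below `anisotropyMin` are effectively
isotropic; they are flagged direction-unavailable (`NA`) rather than
assigned a noise angle. Estimation runs on the foreground-bright polarity
(the image is inverted when `darkFish`) so that eigenvalue signs mean the
same thing for dark and light fish.

## Tracking model

Fish motion between consecutive frames is not modeled kinematically — no
velocity prediction is attempted. The association cost between track *i*
and detection *j* is

cv_ij = ω · pc_ij / pc_max + (1 − ω) · dc_ij / dc_max,

with pc the Euclidean position change, dc the smallest absolute angular
difference, and ω the position weight. Pairs farther apart than the gating
distance `tO` get infinite cost and can never associate. The
minimum-total-cost one-to-one matching is found with the Hungarian
algorithm (shortest-augmenting-path, O(n³)); gated entries are replaced by
a finite constant larger than any achievable finite total inside the
solver, the matrix is padded square with the same constant, and matches
through such entries are reported as unmatched.

Three cases arise with n tracks and m detections. m = n: everything
matches. m > n: the optimal n detections are used, the surplus is dropped.
m < n (occlusion): all m detections match optimally and each of the n − m
unmatched tracks *propagates* — keeps its previous position and direction
unchanged — until its fish is re-detected. Tracks unmatched because of
gating propagate the same way. Every frame therefore carries exactly N
states, which is what prevents trajectory breaks from merging and
splitting. Tracking starts at the first frame whose detection count equals
N (forward scan); if no frame reaches N the run fails explicitly rather
than returning a partial answer.

A detection whose direction is unavailable participates with an
uninformative direction term of dc_max/2 instead of being dropped: its
position is still the best evidence available, and the midpoint neither
favors nor penalizes any track. A propagated track re-enters gating with
its stored direction as-is.

## Parameters

| parameter | meaning | unit | D1 | D2 | synthetic |
|---|---|---|---|---|---|
| `tG` | background difference threshold | gray levels | 75 | 40 | 75 |
| `tU` | centerline pruning | boundary px | 70 | 40 | 25 |
| `tL` | endpoint branch-length filter | px | 9 | 7 | 9 |
| `tW` | head width threshold | px | 16 | 9 | 10 |
| `omega` | position weight in the cost | — | 0.5 | 0.4 | 0.5 |
| `pcMax` | max position change | px/frame | 60 | 80 | 60 |
| `dcMax` | max direction change | deg/frame | 180 | 180 | 180 |
| `tO` | gating distance | px | 300 | 350 | 300 |
| `nFish` | population size N | — | 20 | 40 | 10 |

D1 and D2 are the published settings for the two zebrafish groups they were
calibrated on (20 fish under strong lighting, 40 under ordinary lighting,
2048×2040 px at roughly 100 px/cm, fish 150–300 px long). The `synthetic`
profile is scaled to this package's renderer, whose fish are 60 px long
with an 8 px head half-width: `tU` scales with the boundary length
(70/40 on 150–300 px fish corresponds to roughly 15–25 on a 60 px fish,
and 25 preserves the body curve while pruning burrs), and `tW = 10` sits
midway between the rendered tail width (4 px) and head width (16 px).
`tW = 16` itself would reject these heads under the strict `width > tW`
rule — the skeleton endpoint sits at the head-cap center where the
inscribed circle diameter is exactly 16. Shared plumbing defaults:
`nBackgroundFrames = 31` (odd, so the median is a single order statistic),
`minBlobArea = 30` px (well below a 600 px fish, well above salt noise),
`medianKernel = 3`, `scales = {2, 3, 4, 6, 8}` px (spanning half the head
half-width to its double), `anisotropyMin = 1.2`.

## The synthetic benchmark

No public reference recordings exist for this task, so the package ships a
generator that renders ground-truthed sequences. A fish is a rigid tapered
capsule: head cap of radius 8 px at the ground-truth position, tail cap of
radius 2 px, 60 px overall, constant body gray 60 on background 200, plus
Gaussian pixel noise (σ = 2 by default). Pixels are inside the body when
they fall within the exact signed distance of the uneven capsule. Headings
follow a bounded random walk (turn uniform in ±15°/frame), speed is
6 ± 2 px/frame, and walls reflect. Each fish draws from its own
seed-derived stream, so adding a fish never changes the others' paths, and
a sequence is bit-exact reproducible from its seed.

Three profiles define the study conditions. `easy` (10 fish, 200 frames,
840×630) tiles the arena into one reflecting territory per fish; bodies
then stay geometrically farther apart than the occlusion threshold, so the
truth is occlusion-free by construction — the profile isolates detection
and association quality from occlusion handling. `occluding` (20 fish,
200 frames, 1000×800) adds five engineered crossings: designated pairs in
adjacent territories are steered to the midpoint of their shared edge on a
schedule, pass through each other, and are steered home. Occlusions are
therefore guaranteed, deterministic and temporally localized, which is what
an occlusion-handling test needs. `dense` (40 fish, 100 frames, 900×900)
lets all fish share the arena and interact freely. An earlier design used
reactive collision avoidance instead of territories; rigid bodies that
must keep a hard clearance deadlock into long stationary episodes, which
additionally poison the median background with fish-shaped ghosts — the
territorial design removes both failure modes at the cost of confining
each fish's range, which is immaterial to what the benchmarks measure.

The generator deliberately omits body flexion, size variation, lighting
gradients, shadows and water distortion. Passing benchmarks on it
demonstrates the pipeline's geometric and combinatorial correctness —
skeleton fidelity, width-based head selection, direction recovery,
assignment optimality, conservation through occlusion — not robustness to
photometric conditions of any particular laboratory setup.

## Evaluation criteria

Detection: ACDR (fraction of truth targets matched within a radius,
averaged over frames), AEDR (unmatched detections over truth targets — the
truth-target denominator keeps the two rates on one scale), AODR (the same
correct-detection rate restricted to targets flagged occluded), ADE (mean
smallest angular difference over correct detections). Matching is greedy
nearest within `matchRadius` (default 30 px, half the rendered fish
length). For synthetic truth the heading is exact, so ADE is computed
against true θ directly rather than against a hand-marked reference line.
Tracking: a truth trajectory's owner is the track currently matched to it;
MTT counts trajectories covered > 80 % of their frames, PTT those in
[20 %, 80 %], and TIS the total number of owner-change events. All three
are invariant to relabeling track ids.

## Numerical choices and degenerate inputs

* Fast-marching uses 4-connected upwind updates; heap ties break by
  insertion order, so propagation is deterministic. Skeleton connectivity
  is 8-connected.
* Boundary traversal starts at the lexicographically smallest (x, y)
  boundary pixel purely for reproducibility; wrap correction makes the
  skeleton invariant to that choice.
* `tU` must exceed 2 (unit-width steps can differ by 2 along a straight
  boundary); thresholds at or above L/2 empty the centerline, since
  wrap-corrected differences cannot exceed half the boundary length.
* Components are processed independently; U values are never compared
  across components.
* An endpoint on the image border measures its width against the border
  (outside pixels count as background).
* A component yielding no endpoint (a ring-shaped mask) contributes no
  detections; a frame with zero detections propagates every track.
* Hungarian ties between equal-cost assignments resolve to the lowest row
  index, keeping outputs byte-reproducible.
* Gaussian-derivative kernels truncate at 4s with replicate padding at the
  image border; padded evaluations are flagged.

## Problem sizes

The shipped tests and the acceptance script run the `easy` and `occluding`
profiles at their full 200 frames, direction recovery on 200 single-fish
renders, and assignment checks on one hundred matrices up to 7×7 against
exhaustive permutation search. These sizes were chosen so the whole battery
completes in a few minutes on one core while leaving each property
statistically meaningful.

## Known limitations

* The tracker has no motion model by design; a fish that moves farther
  than `tO` between frames while occluded cannot be re-acquired by gating
  alone.
* Identity through a crossing relies on position/direction continuity; two
  fish that swap positions symmetrically during a long mutual occlusion
  can exchange identities, and TIS counts every such event.
* N is fixed; fish entering or leaving the arena violate the model.
* The synthetic fish is rigid; centerline behavior on strongly flexed
  bodies is exercised only indirectly (curved skeletons still arise during
  crossings, when two bodies merge into one region).
* Background modeling assumes a static scene; slow illumination drift is
  out of scope.
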