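---
title: "Morphological CT organ segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological CT organ segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmorphseg)
```

## What the package computes

`ctmorphseg` implements the classical unsupervised route to CT organ
labels: the lungs and the skeleton have such strong intensity contrast in
Hounsfield units (air near −1000 HU, cortical bone several hundred HU) that
they can be detected by thresholding followed by binary mathematical
morphology, with no training data at all. Masks produced this way are
accurate enough to serve as weak supervision for a segmentation network,
which is why the package also ships the supporting numerics such a workflow
needs: anti-aliased resampling to a coarse isotropic grid, sliding-window
tile covers with overlap averaging, nearest-neighbour label upsampling, and
the smooth IOU (soft Jaccard) training loss.

## The morphology engine

Dilation of a binary image $f$ by a structuring element $k$ is computed in
the Fourier domain: a voxel of $D(f,k)$ is set wherever the real-valued
convolution $f \ast k$ is non-zero. Because the ideal convolution of 0/1
inputs is integer-valued, the implementation thresholds at $0.5$ — the
midpoint between the lattice values — so double-precision FFT round-off
(observed $\lesssim 10^{-10}$, tested to be below $10^{-3}$) can never flip
a voxel. Arrays are zero-padded to 2/3/5-smooth lengths, spectra
multiplied, and the inverse transform cropped centred on the element's
origin so output and input shapes match.

Erosion is the adjoint of dilation: the complement of the dilation of the
complement by the *point-reflected* element. The reflection matters only
for asymmetric elements — every element the segmentation algorithms use
(spheres, prisms, cubes) is symmetric — but without it opening and closing
lose their idempotence for general kernels, so the adjoint form is the one
implemented and tested.

Three boundary decisions are fixed and tested:

* **Dilation** treats out-of-bounds voxels as background (zero padding).
* **Erosion** never eats objects inward from the volume border (an
  all-true volume erodes to itself). This is what the segmentation
  algorithms need: exterior air must stay connected to the in-plane border
  through a closing so it can be recognised and removed.
* **Opening and closing** are evaluated on a domain padded by the element
  half-extent and cropped back (the "safe border" device familiar from
  ITK). The composite then equals the infinite-domain operator restricted
  to the volume, which restores the algebra a naive composition of
  border-convention primitives loses near the border: opening is
  anti-extensive, closing is extensive, and both are exactly idempotent.

A configuration switch (`options(ctmorphseg.backend = )`, or the `backend`
argument) selects the FFT engine or a direct set-theoretic implementation;
the two agree voxel-for-voxel and the test suite asserts it.

Structuring elements live in physical units: `make_sphere_se(d_mm,
spacing)` rasterises the ellipsoid $\sum_k (v_k u_k)^2 \le (d/2)^2$ on the
voxel grid, so anisotropic spacings give anisotropic voxel footprints of
the same physical sphere. Elements are forced to odd extents (even requests
are promoted) so the origin is the exact centre and the FFT crop has no
phase ambiguity.

## Lung segmentation

`segment_lungs()` finds the two largest air pockets inside the body:

1. threshold at $\tau = -150$ HU, keeping `hu <= tau` (the air image
   $f_\tau$; the comparison is inclusive at exactly $\tau$ — the choice is
   immaterial for real-valued CT data);
2. close with a $1 \times \lceil 10\,\mathrm{mm}/d \rceil \times 1$ voxel
   prism, where $d$ is the anterior–posterior (y) spacing: this punctures
   the thin dense wall of the exam table, joining its hollow interior to
   the exterior air (the prism is oriented along y because the table wall
   lies below a supine patient);
3. remove every component touching the in-plane (x/y) border of any axial
   slice — exterior air and the punctured table cavity. Components that
   touch only the first or last z-slice survive, which is what keeps the
   lungs when the trachea exits the scan through the top slice;
4. open with a 10 mm sphere, removing the thin air film of the chest wall
   and other small pockets;
5. keep the two largest components — the lungs. Fewer than two is an
   error when `strict = TRUE`, otherwise the single component is returned
   with a warning flag;
6. reconstruct from $f_\tau$: return the full components of $f_\tau$
   connected to the detected lungs, undoing the erosion of step 4. Seeds
   are the step-5 mask intersected with $f_\tau$, since opening can move a
   mask slightly off its source image.

The trachea and main bronchi stay attached whenever they are air-connected
to the lungs; no carina splitting is attempted.

## Skeleton segmentation

`segment_bones()` uses two thresholds, $\tau_1 = 0$ and $\tau_2 = 200$ HU:
almost all bone tissue (marrow included) is above $\tau_1$, while the hard
cortical shell is above $\tau_2$.

1. threshold at $\tau_2$ (strict `>`);
2. keep the largest connected component — the skeleton. This drops
   contrast-enhanced organs and other hyper-intense tissue not connected
   to it, and *also* drops ribs that are disconnected from the spine in
   cropped scans: a known failure mode that the package reproduces rather
   than patches;
3. close with a 25 mm sphere, bridging thin or invisible cortical bone and
   covering the marrow;
4. intersect the closed mask with `hu > tau1`. The step is read as acting
   on the current mask (removing soft tissue the closing captured), not as
   re-thresholding the whole scan — for the composition used here the two
   readings coincide on everything the closing did not add;
5. fill, per axial slice, holes not connected to the slice border,
   completing the centres of large bones such as vertebras and the pelvis.

Consequences worth knowing: the output always contains the entire largest
$\tau_2$ component (closing and hole filling are extensive, and
$\tau_2 > \tau_1$), and any sub-$\tau_1$ voxel in the output can only have
entered through axial hole filling.

## Connected-component conventions

3D connectivity defaults to 26 (diagonal contact counts — thin oblique
connections inside a lung survive), while 2D hole filling uses
4-connectivity for the background so diagonal leaks do not drain a hole.
Component ids are deterministic: sorted by size descending, ties broken by
the smallest linear voxel index, so every tie-break in the pipelines is
reproducible.

## Metrics

`dice()`, `surface_distances()` and `evaluate_labelmaps()` implement the
three reported quantities. Surface-distance conventions are rarely stated
in papers, so they are fixed here explicitly: a surface voxel is a
foreground voxel with at least one face-adjacent background neighbour (the
volume border counts as background); distances are voxel-centre to
voxel-centre in mm; the MSSD pools nearest-surface distances over both
directions into one mean; the Hausdorff distance is the true max of the
two directed maxima, not a percentile variant. Empty-mask conventions
(both empty: Dice 1, distances flagged absent) keep batch evaluation
total. Distances scale exactly linearly with spacing, and
Hausdorff ≥ MSSD always — both are tested properties.

## The synthetic phantom

`generate_phantom()` renders a scaled-down torso whose default field of
view is 192 × 192 × 224 mm at 2 mm isotropic spacing (≈ 1M voxels — small
enough that the full test cohort of ten phantoms segments in about a
minute). It contains every structure the two algorithms exploit:

* air background at −1000 HU and a hollow exam table below the body whose
  2 mm dense wall (100 HU) encloses an air cavity, open at the z ends —
  so its interior joins the exterior only after the step-2 puncture;
* an elliptic-cylinder soft-tissue body (40 HU) spanning the full z range;
* a skeleton — spinal tube, three pairs of rib arcs sloping inferiorly,
  and pelvic wings — with a 3 mm cortical shell at 700 HU around marrow at
  150 HU. Rib rings are 40 mm apart so the 25 mm bone closing does not
  bridge them (as in a coarse adult rib cage); rib arcs span ~110° per
  side so no axial slice shows a closed ring around the chest interior;
* two air-filled lungs (−780 HU) joined by sub-10 mm bronchi and a trachea
  exiting through the top slice — wide enough to keep the air network
  connected, narrow enough that the 10 mm opening separates the lungs;
* liver- and bladder-like soft blobs and, by default, two 8 mm decoy blobs
  at 250 HU ("contrast-enhanced organs") disconnected from the skeleton;
* seeded additive Gaussian noise (σ = 10 HU), truncated at 40 % of the
  smallest margin between any rendered intensity and any segmentation
  threshold (−150, 0, 200 HU), so noise can never carry a voxel across a
  threshold; and quantised to 1/8 HU so volumes survive 32-bit float NIfTI
  storage bit-exactly.

All intensities sit on the correct side of every threshold by
construction, which the tests assert voxel-by-voxel. The ground-truth
label map codes the whole air network (lungs + airways) as class 3 and the
whole skeleton (shell + marrow) as class 5 — the airways are included in
the lung class because retaining the attached trachea is the documented,
accepted behaviour of the algorithm being tested.

What the phantom does *not* emulate — and hence what passing tests do not
show about clinical data: partial-volume blur at tissue interfaces,
beam-hardening and streak artifacts, anatomical variability, pathology,
contrast washout, and anisotropic slice spacing (supported by the code,
not exercised by the default phantom). Recovery scores on the phantom are
upper bounds, not forecasts, for real scans.

`degrade_phantom()` produces three adversarial variants reproducing
documented failure modes: `crop_abdomen` cuts the scan below the ribs'
spinal attachments (the bone algorithm then silently drops the
disconnected rib fragments), `merge_lungs` carves a 14 mm air channel
between the lungs (the opening cannot separate them and the strict lung
run fails with a single-candidate error), and `remove_table` deletes the
table (lung output changes by well under 1 % — table handling is a no-op
when no table exists).

## File format conventions

Volumes and label maps are NIfTI-1 with 32-bit float data, named
`volume-n.nii.gz` / `labels-n.nii.gz` (`pair_paths()`). Organ codes:
0 background, 1 liver, 2 bladder, 3 lungs, 4 kidneys, 5 bone, 6 brain.
On read, label voxels must be within $10^{-3}$ of an integer in 0..6;
anything else is a format error. The canonical in-memory orientation is
LPS (x left, y posterior, z superior — the exam table at +y for a supine
patient); oriented files are reoriented on read and the orientation is
written into the qform on write.

## Resampling, tiling and the loss

For resampling a scan with per-axis spacing $u$ to an isotropic target
$r$ (default 3 mm), each axis is pre-smoothed with a Gaussian of
$\sigma_k = \tfrac{1}{3}\max(r/u_k - 1, 0)$ in source-voxel units — the
cutoff sits at the ratio of sampling rates; axes already at or above the
target resolution are left untouched — followed by trilinear interpolation
(kernels truncated at $3\sigma$, edges replicated). Resampling to the
source spacing is the identity to $10^{-6}$. Label maps travel the other
way by nearest-neighbour gathers, which can never invent a new code.

`tile_cover()` covers a volume with the minimal number of fixed-size tiles
per axis ($\lceil \text{extent}/\text{tile} \rceil$, offsets evenly spaced
from 0 to extent − tile; volumes smaller than a tile are treated as
zero-padded). `average_overlaps()` recombines per-tile probability maps by
an unweighted per-voxel mean — the mean of distributions is a
distribution, so no renormalisation is needed.

The smooth IOU loss for class $c$ is
$L_c = 1 - \dfrac{p_c \cdot y_c}{\lVert p_c\rVert_1 + \lVert y_c\rVert_1 - p_c \cdot y_c}$,
averaged over all classes *including background*. On binary probabilities
it equals $1 - J$ (Jaccard), which ties it to the Dice score through
$\text{Dice} = 2J/(1+J)$ — a cross-check the tests perform against the
metrics module. A class absent from both the prediction support and the
reference has a vanishing denominator and is defined to contribute zero
loss (perfect-agreement convention).

## Numerical and degenerate-input choices

* FFT threshold fixed at 0.5; integrality of the convolution is itself a
  tested invariant (within $10^{-3}$).
* `largest_components()` with fewer components than requested raises a
  typed condition carrying the count found, so callers can distinguish
  "no lungs" from other failures.
* Empty seeds reconstruct to an empty mask; empty masks are rejected by
  `surface_distances()` (surfaces are undefined) but handled by
  `evaluate_labelmaps()` through the absent-class conventions.
* The phantom generator restores the caller's RNG state, so test RNG
  streams do not interleave with phantom noise.

## Scope limits

The package deliberately stops where training infrastructure begins: no
network, optimiser, augmentation or checkpointing. Left/right lung
splitting, airway removal, per-bone instance labels, rib recovery in
cropped scans and spinal-cord exclusion are likewise out of scope — the
last three are documented limitations of the morphological approach that
the failure-mode tests reproduce on purpose.
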