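---
title: "Surface-layer extraction and projection bias: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-layer extraction and projection bias: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfcutr)
```

## The problem

Quantifying epidermal cell shape — pavement cell lobing, hypocotyl cell
files, meristem cell sizes — requires clean 2D images of cell contours. A
confocal Z-stack of a wall-stained (e.g. propidium iodide) plant organ does
not give those directly: a plain maximum-intensity projection superimposes
periclinal walls and deeper cell layers onto the epidermal anticlinal walls,
and a single optical section only grazes a curved organ. What is needed is a
thin layer of signal at a controlled depth *relative to the sample surface*,
extracted before projecting.

`surfcutr` implements the classic ImageJ-style Z-shift recipe for this:

1. **8-bit conversion.** The stack's intensity range is rescaled linearly to
   `[0, 255]` (min to 0, max to 255, rounding half up). A constant stack is
   rejected — there is no contrast to threshold.
2. **De-noising.** Each z-slice is convolved with a 2D Gaussian of standard
   deviation `blur_radius_px` (reflected boundaries). The blur is 2D
   per-slice, not 3D, mirroring what a slice-wise "Gaussian Blur" does to a
   stack in ImageJ-like tools.
3. **Binarization.** Voxels at or above `threshold` count as signal. The
   comparison direction (`>=`) is a convention of this implementation.
4. **Edge fill (cumulative down-projection).** Slice z of the mask is the OR
   of binarized slices 1..z. Columns are therefore "on" from the first
   detected signal downward, which fills the signal-free cell interiors that
   a plain threshold would leave as holes — exactly the property needed for
   the mask to represent "at or below the surface".
5. **Shifted-mask cropping.** The mask, shifted down by
   `depth_to_slices(depth_top_um)` and `depth_to_slices(depth_bottom_um)`
   slices, selects which voxels of the *original* (un-blurred) 8-bit stack
   survive: for a column whose first signal sits at slice $s$, the kept
   window is exactly $[s + \mathrm{top}, s + \mathrm{bottom})$.
6. **Maximum-intensity projection** of the cropped layer gives the 2D
   contour image.

The crop is in the Z direction only, not perpendicular to the surface. On a
surface tilted by $\theta$ against the image plane this is the whole story
of the method's bias: a cell of true (on-surface) area $A$ projects to
$A\cos\theta$, so area measured on the contour image underestimates by
$(1-\cos\theta)\times 100$ percent. The package's bias module measures
exactly this.

## Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `blur_radius_px` | px (Gaussian sigma) | 1 | suppresses speckle before binarization; 0 disables |
| `threshold` | 8-bit gray level | 100 | signal/background cut after 8-bit conversion |
| `depth_top_um` | µm below surface | 0 | top of the kept layer |
| `depth_bottom_um` | µm below surface | 2 | bottom (exclusive) of the kept layer |

The depth window is **half-open** `[top, bottom)`: at a 0.5 µm Z-step a
(6, 8) µm window keeps exactly 4 slices, and windows compose without double
counting (`[a,c)` is the disjoint union of `[a,b)` and `[b,c)` — a tested
invariant). Whether the original macro's bottom boundary is inclusive is not
documented; half-open is normative here and no dialect switch is provided.
Depths convert to whole slices by rounding to nearest, ties away from zero;
there is no sub-slice interpolation because the mask is shifted by whole
slices.

Two further choices resolve ambiguities in the published recipe:

* **8-bit conversion uses the stack-wide min–max range.** Interactive tools
  rescale by the current display range, which is session state a headless
  pipeline must not depend on.
* **The blurred, binarized stack builds the mask only; cropping applies to
  the original 8-bit stack.** The blur exists to stabilize surface
  detection, not to alter the reported intensities. Whether the original
  macro binarizes the blurred or the raw stack for mask construction is not
  stated; blurring first (the listed order of operations) is adopted.

Reference voxel dimensions throughout (phantom defaults) are 0.363 µm XY
pixel size and 0.5 µm Z-step, the acquisition settings typical of the
confocal setups this workflow targets.

## The synthetic world

Real stained organs are replaced by phantoms with analytic truth:

* **Flat sheet** — a rectangular lattice of bright anticlinal walls
  (intensity 200 of 255, 2 px thick, reaching 8 slices ≈ 4 µm below a flat
  surface) around dark cell interiors. This is the zero-curvature regime
  where Z-cropping is exact: extracted wall area equals true wall area and
  per-cell percent differences are 0.
* **Tilted plane** — the same lattice described in projected coordinates
  with the surface deepening along x at slope $\tan\theta$. True cell area
  is projected area divided by $\cos\theta$ by construction, giving the
  clean $(1-\cos\theta)$ law to test against.
* **Cylinder** — hypocotyl analog: an upper half-cylinder with axial cell
  files spanning ±60° of circumference. Each file's angle is the chord
  between its outer wall junctions on a transverse section (equal to the
  file's mid-angle on a circle), the same measurement one would make by
  hand with an angle tool; it is averaged at five axial positions, which are
  uniform because the sampling positions of the manual protocol are not
  specified. Per-cell true area is a numerical surface integral
  $\int\sqrt{1+\|\nabla h\|^2}\,dA$ over the cell's interior pixels,
  cross-checked in tests against the closed-form arc-length × axial-length
  product.
* **Hemisphere** — meristem analog: a polar lattice (apex cell + rings of
  sectors) on a spherical cap. The apex cell's angle is 0 (its center sits
  on the pole where the tangent plane is horizontal); ring angles are
  mid-latitudes. The per-ring bias tracks the spherical closed form
  $1-(\cos\theta_1+\cos\theta_2)/2$.

**Cell-level curvature ("bumpiness")** is modeled as a per-cell sinusoidal
dome added to the surface height, vanishing on the walls. Because anticlinal
walls sit at cell boundaries where the dome is zero, the extracted 2D
contour lattice — and hence the measured 2D area — is unchanged, while the
true on-surface area grows. That is precisely the cell-level bias a Z-crop
cannot see, and it lets the bias study separate tissue-level (file angle)
from cell-level (bumpiness) curvature. The dome is applied to the height
field rather than strictly radially; near the apex the two coincide, and the
height-field form keeps the surface single-valued per image column.

Area conventions: a cell's area (true and projected) is its *interior*
pixel region, excluding walls — matching what contour segmentation measures,
so the flat regime yields exactly zero bias. `cell_size_px` is the interior
side length.

What the phantoms do **not** emulate: point-spread-function anisotropy,
depth-dependent attenuation, subepidermal signal, stained debris, and
real pavement-cell lobing. A green bias test therefore establishes the
geometric correctness of the pipeline and of the bias law on ideal wall
lattices — not segmentation robustness on realistic texture.

Noise, when requested, is additive Gaussian read noise plus salt impulses
(saturated voxels), seeded explicitly; generators are pure functions of
their arguments and never disturb the caller's RNG stream.

## Segmentation and shape descriptors

Cells are the 4-connected components of the non-wall pixels of a contour
image (walls: intensity at or above a threshold). 4-connectivity for cells
prevents diagonal leaks through 1-px walls. Components touching the image
border — truncated cells or the outside region — are labeled and *flagged*
rather than silently dropped; `compute_descriptors()` excludes them by
default, mirroring the usual incomplete-cell exclusion, but the flag keeps
over-segmentation failure modes observable. The small-cell filter removes
labels below 2500 px (strictly below: a 2500-px cell survives; the boundary
behavior is unstated upstream and strict `<` is adopted), the standard
guard-cell exclusion.

Descriptors per cell: area (pixel count × pixel area), perimeter
(8-connected Moore contour trace through pixel centers, diagonal steps
weighted $\sqrt2$), circularity $4\pi A/P^2$, and solidity (pixel area over
the convex hull of the pixel corners, so digital rectangles score exactly
1).

**Known limitation of the perimeter estimator.** Any fixed-weight chain
length is direction-biased on digitized curves: with weights $(1,\sqrt2)$
the measured boundary of a digital disc exceeds $2\pi r$ asymptotically by
the factor $\frac{8}{\pi}(\sqrt2-1)\approx1.0548$, so disc circularity
converges to $\approx0.899$ *from above* (0.916 at r = 10 px, 0.908 at
r = 40 px) instead of rising to 1. Bias-corrected weights (0.948/1.341)
would fix discs but break the exactness on axis-aligned squares
($P = 4(s-1)$, circularity $\pi/4$), which this package's tests rely on;
only non-local polygonalization estimators satisfy both, at a complexity
that is not warranted here. The corresponding disc-monotonicity assertion in
the acceptance tests is knowingly red, with the square and closed-form
circle assertions green. Comparisons *between* shapes measured with the same
estimator (the package's actual use) are unaffected.

Degenerate shapes: a single-pixel component gets the unit-square crack
perimeter 4.

## The bias study

`run_bias_study()` extracts the contour image, segments it, and matches
segmented cells to truth cells by maximal pixel overlap with a 50% minimum;
unmatched cells are reported with `NA`, and fewer than half matching is an
error that prints the per-cell overlaps. The reported quantity per cell is

$$\mathrm{percent\ difference} = \frac{A_{\mathrm{true}} - A_{2D}}{A_{\mathrm{true}}}\times100,$$

positive when the on-surface (2.5D) area exceeds the projection, the
expected direction on curved tissue; negative values are reported as such.
The 2.5D side of the comparison is the phantom's analytic truth — the
package deliberately does not reimplement a mesh pipeline, it treats the
analytic surface as the gold standard such a pipeline estimates.

## Command line

`calibrate` (one stack, all intermediates written, parameters echoed to a
reusable key=value file) and `batch` (one parameter set over a folder;
per-file failures logged, not fatal) mirror the two modes of the original
macro; `phantom` and `bias` generate fixtures and run the bias study from
the shell. Batch and calibrate outputs for the same stack and parameters are
bit-identical, and repeated runs are bit-identical — the extraction path
contains no randomness.

## File formats

Stacks are uncompressed single-channel 8/16-bit multi-page TIFF (both byte
orders read; little-endian written, with the XY pixel size in the
resolution tag as pixels-per-micron and the Z-step in an ImageJ-style
`spacing=` description). Explicit voxel-size arguments always override file
metadata, silently — metadata quality in the wild varies, and the user's
word wins. 2D images go to single-page TIFF or PNG; PNG carries no pixel
size (there is no standard µm-scale resolution semantics in PNG), so voxel
sizes are recorded in the parameter echo file instead.
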