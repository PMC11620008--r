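---
title: "Device-agnostic ONH biomarkers from segmented OCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Device-agnostic ONH biomarkers from segmented OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhmark)
```

## The problem

OCT devices image the optic nerve head (ONH) with different acquisition
patterns — raster cubes of B-scans (e.g. 200 x 200 A-scans over 6 x 6 mm)
versus radial scans through the disc plus circular scans at fixed
diameters — and each manufacturer quantifies the anatomy with its own
proprietary software. The resulting measurements are not interchangeable,
which is a real obstacle for patient follow-up across clinics and for
multicenter studies.

`onhmark` implements the measurement layer of a device-agnostic approach:
given a *multi-class segmentation mask* of an ONH-centered OCT volume (from
any segmentation source — a CNN, manual annotation, or the package's own
synthetic generator), it computes the same four biomarkers in the same way
regardless of the acquiring device:

1. **BMO area** — the Bruch's membrane opening, the anatomic disc margin.
2. **cpRNFL thickness** — circumpapillary retinal nerve fiber layer
   thickness on a measurement circle (3.4 and/or 3.5 mm), with TSNIT sector,
   clock-hour and global means.
3. **BMO-MRW** — minimum rim width, the shortest distance from the BMO edge
   to the inner limiting membrane (ILM), per half-meridian.
4. **Cup volume** — the space enclosed between the chord through the BM
   endpoints of each B-scan and the inner tissue surface.

It also provides the agreement statistics used to compare devices (Dice
coefficient, absolute-agreement ICC with confidence intervals,
absolute-difference summaries, circular profile smoothing) and a synthetic
phantom generator whose ground truth is known in closed form.

## Input model

The input is a `label_volume`: a 3D integer array indexed
`(bscan, ascan, axial)`, axial index increasing with depth, plus physical
voxel spacings in micrometres, laterality and acquisition type. The label
scheme names the classes `background`, `rnfl`, `vessel`, `rpe_bm` (RPE and
Bruch's membrane are annotated jointly because BM, at ~2 um, is thinner
than the axial pixel of any spectral-domain device), `prelaminar`, and
optionally `lamina_cribrosa` and the three peripapillary atrophy (PPA)
zones. Volumes are read from NIfTI or multipage TIFF with a JSON sidecar;
radial/circular acquisitions are sets of 2D slices with angle and diameter
metadata.

All geometry is computed in micrometres, never in voxels: OCT voxels are
strongly anisotropic (30 um laterally vs ~3 um axially for a typical cube),
so voxel-space distances would be meaningless.

## The measurement procedures

### BMO detection

The en-face footprint of the RPE–BM complex (including alpha- and beta-zone
PPA where labeled; gamma-zone PPA, which lies inside the opening, counts as
absence) has a hole at the disc. A morphological closing with a disk
structuring element (default radius 3 en-face pixels, about 90 um on a
200-pixel/6-mm grid) corrects small segmentation defects; foreground specks
smaller than the structuring element are removed first, since the closing
radius itself defines the scale below which structure is treated as noise —
without this, a dilation step inflates speckle instead of correcting it.
The boundary of the interior hole is traced as a sub-pixel 0.5-level
isocontour (midway between the last hole pixel and first BM pixel, which
keeps the contour unbiased rather than half a pixel inside the opening),
and an ellipse is fitted by the direct least-squares method with the
ellipse constraint `4ac - b^2 = 1` in the numerically stable Halir–Flusser
block form. A constrained fit is used deliberately: an unconstrained conic
fit can return a hyperbola on noisy boundaries. The fitted center anchors
every downstream measurement; the area is `pi * a * b`.

### Vessel resolution and cpRNFL

Retinal vessels interrupt the RNFL band in the segmentation. Before
thickness is measured, every vessel voxel is reassigned to `rnfl` or
`background`, whichever non-vessel annotation is nearest in the physical
(anisotropic) metric within its own B-scan plane; exact ties go to `rnfl`
so continuous tissue is never punched open. The two distance maps come from
an exact anisotropic Euclidean distance transform (Felzenszwalb–Huttenlocher
lower-envelope algorithm, compiled code).

Thickness per A-scan is the count of `rnfl` voxels times the axial spacing —
the natural measure on a label mask, robust to non-contiguous labels. The
cpRNFL profile samples this map by bilinear interpolation at 720 equally
spaced angles (0.5 degrees, finer than both the 9-degree smoothing window
and the angular width of a vessel shadow) on the measurement circle.
Bilinear interpolation is exact for affine fields, which the tests exploit
as an oracle. For circle-scan devices the profile is instead read directly
off the acquired circular B-scan and mapped to angles via its start-angle
and direction metadata.

### TSNIT convention and sectors

Profiles are indexed in TSNIT degrees — 0 temporal, 90 superior, 180 nasal,
270 inferior — for both eyes (geometrically counterclockwise in the en-face
view for OD, clockwise for OS), so left and right eyes are directly
comparable. Sector bins are centered on the anatomical axes: temporal 90,
temporal-superior 40, nasal-superior 40, nasal 110, nasal-inferior 40,
temporal-inferior 40 degrees; clock hours are twelve 30-degree bins with
hour 12 centered superiorly and numbering proceeding nasally. When a fovea
position is available the temporal axis is tilted to the BMO-center-to-fovea
axis (as circle-scan devices do); otherwise the laterality-implied
horizontal is used and the fallback is recorded in provenance.

### MRW

The minimum rim width is computed per radial plane, matching how
radial-scan devices present it: for each of 24 radial slices (acquired, or
synthesized from a cube by nearest-neighbor resampling through the BMO
center — labels are categorical, so no interpolation), the BM edge is the
innermost column containing the RPE–BM complex on each side, its axial
position the mean of the complex's extent in that column (the measurement
is from the complex, not a sub-layer). The ILM is the shallowest
neural-tissue voxel per column, and the width is the exact minimum distance
from the edge point to any ILM point on that side, including points above
and beyond the edge. 24 radials give 48 half-meridian widths; meridians
with an obscured edge are excluded from means, counted, and more than 50%
missing is a quality error — obscured BMO edges are the dominant real-world
failure mode for rim measurements.

### Cup volume

Per B-scan, the chord joins the two BM endpoints flanking the BM gap;
columns strictly between them contribute
`max(0, tissue_top - chord) * lateral spacing`, and the per-B-scan areas sum
across the volume times the B-scan spacing. Tissue shallower than the chord
is clamped to zero — the cup is a volume, not a signed integral. This is a
chord-based definition per individual B-scan; manufacturers define cup
volume differently, so absolute values are comparable only within this
definition.

## The phantom generator

`phantom_spec()` / `make_phantom()` rasterize a continuous parametric eye
onto a voxel grid and return the analytic ground truth alongside. The
default mimics a 6 x 6 mm, 200 x 200 A-scan cube with 2 mm depth at
3.125 um axial spacing (within the 2.6–3.87 um range of common
spectral-domain devices): an elliptical BMO (a = 900, b = 600 um, rotated
30 degrees), a flat outer ILM, an RNFL thickness field
`t(theta) = 100 + 30 sin(2 theta)` um (the double-hump bundle pattern,
thicker superiorly and inferiorly), a 25-um RPE–BM complex giving an
ILM-to-BM-center separation of about 260 um, an elliptic-paraboloid cup
(semi-axes 0.35 of the BMO's, 400 um deep below the BM chord, so
`V = pi a_c b_c h / 2` in closed form), prelaminar tissue whose top
continues the ILM across the rim, and four vessel tubes inside the RNFL
band placed along the superior and inferior arcades. Vessels are kept
strictly inside the band so that, after the nearest-neighbor resolution
rule, the true thickness field is unchanged — the tubes exercise the rule
itself, not the thickness truth.

Ground truth comes from the continuous parameters only: BMO area
`pi a b` (shrunk by alpha/beta PPA annuli when present), cpRNFL sector
means by exact integration of the sinusoid, cup volume by the paraboloid
formula, and MRW certified by dense brute-force minimization over the
continuous ILM per meridian (for the default geometry it reduces to the
BM-center depth minus the ILM depth, identically over meridians — the cup
is kept laterally clear of the rim so the nearest ILM point to the edge is
always the flat plane directly above it). `derive_radial_set()` samples
radial and circular slices from the same continuous definition, not from
the cube raster, emulating a second device imaging the same eye: the two
routes share geometry but not discretization, which is the cross-device
design in miniature.

### Numerical anchoring of surfaces

Counting voxels across a slab measures its extent with a bias of
`(phase - 0.5) * spacing`, where `phase` is the fractional position of the
slab's top surface in axial-grid units; the voxel-position mean of a slab
carries the complementary bias. The default surface depths are therefore
placed at half-voxel phase of the reference axial grid (ILM at
601.5625 = 192.5 x 3.125 um; BM at 848.4375 = 271.5 x 3.125 um), which
zeroes the thickness bias at the reference resolution. The BM anchor index
is additionally chosen congruent 3 mod 4 so that under 2x grid coarsening
the phase halves in a pattern that keeps every quantization term
proportional to the spacing — discretization error then genuinely converges
under grid refinement instead of leaving a resolution-independent residual
that can accidentally cancel at one level. This is a property of the
generator's raster alignment, not of the extraction code.

### What the phantom does and does not emulate

It reproduces the geometry and label structure of real segmentations —
anisotropic voxels, an elliptical tilted disc, vessel interruptions, PPA
annuli, missing BM edges, speckle-like label noise and boundary jitter. It
does not simulate OCT intensities, speckle, motion artifacts, pathology
beyond geometric cup/rim variation, or segmentation errors correlated with
anatomy (a CNN's errors are not i.i.d.). Passing recovery tests therefore
demonstrates that the *measurement* layer is correct and convergent on
known geometry; it says nothing about segmentation quality on real scans,
which is the concern of whatever model produces the masks.

## Agreement statistics

`dice()` is the standard overlap coefficient, with `dice(empty, empty) = 1`
by convention (flagged). `icc_a1()` is the two-way, absolute-agreement,
single-measure intraclass correlation ICC(A,1) of McGraw & Wong, computed
from the two-way ANOVA mean squares, with the F-based 95% confidence
interval using Satterthwaite degrees of freedom; lower bounds can be
negative with small samples and are deliberately not clipped. Reliability
bands: below 0.5 poor, to 0.75 moderate, to 0.90 good (the 0.90 boundary
counts as good), above excellent. `smooth_profile()` is an equal-weight
circular moving average whose window spans the largest odd number of
samples not exceeding the requested width (9 degrees by default, chosen to
suppress focal vessel dips); it preserves the circular mean exactly.
`abs_diff_stats()` reports the mean and sample SD of absolute pairwise
differences.

One subtlety: ICC(A,1) is below ICC(C,1) (the consistency version) exactly
when the between-rater mean square exceeds the residual mean square. With a
genuine systematic offset between devices that is always the case, but on
tables with no rater effect the sample inequality can flip; the test suite
checks the exact algebraic equivalence rather than the loose inequality.

## Worked sizes and tolerances

The validation suite runs the full pipeline on the reference grid
(200 x 200 x 640) and two dyadic coarsenings (100 and 50 A-scans per side),
checking: BMO area within 2% of `pi a b`; cpRNFL global and all six sector
means within 2 um of the closed forms at both 3.4 and 3.5 mm; MRW within
one lateral plus one axial step of the analytic rim height; cup volume
within 3% of the paraboloid formula; strict error reduction under grid
refinement for all four biomarkers; agreement of the cube and
radial/circular routes within 2 um (cpRNFL) and 5 um (MRW) on the same
continuous eye; ICC(A,1) above 0.95 between the two simulated protocols
over eight eyes; and a median BMO-area error under 3% with 5% BM-pattern
flip noise (20 seeds). These problem sizes keep the whole suite within a
few minutes on a single CPU while using the full reference resolution where
the tolerances demand it.

## Known limitations

* Cup volume and BMO area need the full en-face raster, so they are flagged
  unavailable on radial/circular acquisitions (the BMO ellipse for such
  devices must come from the radial BM edges; only the center is needed for
  MRW, which radial sets carry implicitly).
* Sector means weight profile samples uniformly in angle; for circular
  scans with strongly nonuniform A-scan spacing this differs from
  arc-length weighting (identical on ideal circles).
* The BM edge position is quantized to the lateral resampling step of the
  radial slices; at 30 um steps this dominates the MRW quantization budget.
* `dice()` on volumes compares like-indexed B-scans; it does not register
  or align volumes first.
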