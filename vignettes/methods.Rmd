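---
title: "Reconstructing a sectioned tube: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a sectioned tube: models, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why:
the forward model behind the synthetic specimen, the estimators that
invert it, the numerical decisions that matter, and what the passing
tests do and do not demonstrate about real histological data.

## 1. The forward model

### The specimen phantom

`phantom_spec()`/`build_phantom()` rasterize a parametric specimen into a
labelled voxel volume. The tube axis is a gently bowed polyline spanning
the block in z (bow amplitude 1.2 mm, so sections are never exactly
perpendicular to the local axis). At each axial position the cross-section
is drawn in a local frame rotated by the twist angle
$\theta(s) = \theta_{\mathrm{total}}\, s$, where $s \in [0,1]$ is the
arc-length fraction along the axis — twist is linear in arc length by
construction, which the torsion module should (and does) recover as an
affine angle-versus-z relationship.

The cartilage is two joined capsules (rectangles with rounded caps): a
long medial lamina and a short lateral lamina meeting at a right angle —
the simplest shape with the "J" topology of tube cartilage and an
unambiguous principal axis. Dimensions are free parameters of the
fixture (the source anatomy gives none): medial 6 mm, lateral 2.5 mm,
thickness 0.9 mm. Toward the isthmus the laminae shorten by 35 % while
the thickness grows as $f^{-0.8}$ of the lamina scale $f$. The exponent
was chosen when the phantom was designed so that the construction shows
the qualitative behaviour reported for the real specimen — a
cross-sectional area that stays nearly constant (measured CV below 1 %
on the unsectioned phantom) while the circumference falls monotonically
(≈ 19.5 → 15 mm), i.e. the cartilage becomes more compact toward the
bony part — with the side benefit that the shape's principal-axis
offset drifts by less than a degree over the whole taper, so shape
change does not masquerade as torsion.

Around the cartilage sit, in the same rotating frame: a mucosal seam
whose lumen gap (0.5 mm) is open only over the pharyngeal 15 % of the
axis and closed elsewhere (the "largely closed tube, open at the
pharyngeal orifice" configuration); the TVPM and LVPM as capsules
flanking the cartilage; the Ostmann fat pad as a disk whose radius
tapers by 60 % toward the isthmus (monotonically vanishing area); and
bone in the last 15 % of the axis. Painting precedence is fixed
(cartilage over lumen over mucosa over muscle/fat/bone), and the three
needle fiducials are painted last with a hard error if they ever
intersect cartilage or lumen — the protocol's "needles outside the
cartilaginous tube" constraint, enforced at rasterization.

The three 0.45 mm-radius needles run within 1.5° of the z axis at
6–7 mm from the tube, at deliberately asymmetric angular positions
(25°, 140°, 262°) so that frame-to-frame correspondence and in-plane
rotation recovery are well conditioned. Three grooves (two opposite x
faces, one y face; non-collinear lever arms) provide the thickness
read-out points and registration landmarks. `make_reference_volume()`
maps labels to densities (needles ≈ steel high, bone high, soft tissue
intermediate, grooves carved out) and box-averages to 0.3 mm — the
resolution of the tomographic scan the protocol registers against. Box
averaging conserves the mean exactly on factor-divisible grids, which
is the conservation oracle the tests use.

Default problem size: 20 × 20 × 38 mm at 0.1 mm in-plane and 0.1815 mm
(half a section period) axially — 200 × 200 × 209 voxels. These sizes
were chosen so a phantom builds in a few seconds and the ten-replicate
torsion experiment completes in well under a minute, while keeping
recovery errors an order of magnitude below the acceptance tolerances;
nothing in the code assumes them. The axis spans z = 0.091 mm to
36.028 mm — exactly the voxel planes sampled by the first and last
section of the default protocol, so the full ground-truth twist is
observable in the sectioned data.

### The cutting protocol

`protocol_spec()` carries the study constants: 100 sections of 33 µm at
330 µm blade spacing (period 363 µm), the block split into two halves,
and the first section of each block lost during mounting (98 kept). Each
kept section is the voxel plane nearest the mid-plane of its 33 µm slab
— a convention; the protocol does not say where in the slab the imaged
surface lies. Perturbations are in-plane rigid (translation SD 0.3 mm,
rotation SD 2°), drawn once per section from a seeded stream. Tilt
(SD 0.2°) is modelled to first order: it offsets the groove read-outs
through their lever arms and is estimated and reported, but does not
re-warp the 2D image content — at 0.2° over a 20 mm block the in-plane
distortion is ~10 µm, below one pixel. Groove read-outs get 5 µm
Gaussian noise. Labels are resampled nearest-neighbour only (they are
categorical), and the z bookkeeping keeps lost sections as exact
one-period gaps.

## 2. The estimators

### Fiducial alignment

`detect_fiducials()` takes connected components of the needle label
(EBImage), filters them to 25–400 % of the expected needle
cross-section $\pi r^2$, and returns centre-of-mass centroids — sub-0.1
pixel accurate on rasterized disks. `correspond_tracks()` anchors ids in
the first three-detection section (ordered by angle about their
centroid, which makes the labelling invariant to detection order) and
propagates them by least total squared displacement over all injective
assignments, warning and breaking ties deterministically when two
assignments are within 1 µm² of equal cost.

`fit_stack_alignment()` estimates one rigid transform per section and
three straight 3D lines by minimizing the summed squared *in-plane*
distances between transformed detections and each line's intersection
with the section plane. Two block updates alternate: per-section 2D
Procrustes given the lines, and per-fiducial line fits given the
transforms. The line step regresses x and y on z (ordinary least
squares) rather than fitting a total-least-squares 3D line: because z
is fixed per section, the OLS line is the exact minimizer of the stated
in-plane criterion, which keeps the descent strictly monotone — with a
TLS line step the alternation is not an exact block minimization and in
practice stalls.

The criterion has a null space worth being explicit about. It is exactly
invariant under (i) one common rigid motion of all sections and (ii) a
translation *shear* linear in z — both merely move or tilt the straight
lines. It is *almost* invariant under (iii) a rotation drift linear in z
(a global twist of the stack): with needles perfectly parallel this
would be a third exact invariance, and it is precisely the systematic
torsion error that motivates registering the stack to a tomographic
reference. With needles ~1.5° off parallel the twist mode is weakly
identifiable, which makes it a pathologically slow direction for
coordinate descent. The implementation therefore (a) detrends modes
(i)–(iii) from the transforms every iteration, and (b) optimizes the
twist coefficient by an exact one-dimensional search in an outer loop:
for a fixed twist coefficient the remaining unknowns (translations and
line parameters) are linear and are eliminated in closed form, so the
profile cost of the twist coefficient is evaluated exactly and
minimized with `optimize()`. The final solution keeps the
maximum-likelihood twist; only the exact gauges (i)–(ii) are normalized
to zero. Ground-truth comparisons (`transform_recovery_error()`) apply
the same gauge, removing the mean and the linear-in-z component before
reporting per-section errors.

Convergence: relative cost change below 1e-10 (or a numerical floor for
exactly consistent data), at most 200 inner iterations, up to 50 outer
rounds; non-convergence is an error, not a warning. On noiseless
constructed tracks the recovered transforms match the inverse
perturbations to ~1e-8; on the rasterized default pipeline the
detection noise of ~0.017 mm (nearest-neighbour resampling of the
needle disks) propagates to ~0.1° / 0.3 px per-section recovery error.

Sections with fewer than two usable detections are not dropped (that
would cut holes in the morphometry): their transforms are interpolated
linearly in z and flagged. Two-block specimens are fitted jointly —
the needles are physically continuous through both blocks — with block
structure retained only in the z bookkeeping.

### z assignment

`assign_z()` inverts the groove model. The three read-outs of one
section define an exact plane over the groove lever arms; its value at
the block centre gives the cut depth (exact under tilt, where the plain
mean is biased by the mean lever arm), and its slopes give the tilt.
The depth maps to z as $z = H - d - p$ (block height $H$, period $p$:
the read-out is taken *after* the cut). An outlier groove is declared
when the three values disagree by more than 3× the read-out noise plus
the spread a 3-SD tilt could produce — the tilt allowance matters,
since tilt alone spreads the grooves by an order of magnitude more than
the read-out noise — and triggers a median fallback with tilt reported
as `NA`. A non-monotone corrected z sequence is an error naming the
offending positions.

### Registration

`register_landmarks()` is the closed-form SVD solution for the rigid
transform between matched 3D point sets, with the determinant
sign-corrected so a reflection is never returned, collinear sets
rejected (rotation about the line unidentifiable), and FRE = RMS
post-transform distance. `register_to_reference()` samples the fitted
needle lines at the first/middle/last section planes (nine landmarks)
and resolves the arbitrary track-id-to-needle assignment by trying all
six permutations and keeping the smallest FRE. On the default pipeline
the stack registers to the phantom's true needle lines with FRE
~0.1 mm, a third of the reference voxel; the residual is dominated by
the shear-gauge uncertainty of the line fit, which shrinks with the
number of sections (the 16-section test fixture registers to ~0.5 mm
for the same reason).

### Morphometry

Area is the exact pixel count times the pixel area. Circumference is
the length of the 0.5-level marching-squares contour
(`grDevices::contourLines` on the zero-padded mask), summed over all
components *and holes* — a folded, closed lumen has near-zero area but
large circumference, which is the configuration of interest. The raw
contour of a binary mask is a staircase that overestimates smooth
boundaries by ~6 % independent of size, so each closed contour polygon
is smoothed with a five-vertex circular moving average before
measuring: this preserves the contour topology exactly (any non-empty
mask keeps a positive perimeter — an invariant the profile asserts) and
measures rasterized disks to within 0.5 %. `smooth_window = 1` exposes
the raw length; an `outer_only` variant fills holes first, and the
profile reports both columns, since whether the original circumference
measurements counted internal fold contours is not stated.

`merge_perforated()` implements the "perforated compartments are one
functional unit if connected through adjacent sections" rule as 3D
connected components with 26-connectivity (igraph on the voxel
adjacency list), run on the stack of kept sections compacted in z so
that adjacency spans lost-section gaps. `profile_stack()` measures area
and circumference on the *original* section images — rigid alignment
changes neither, so no resampling error is introduced — and takes the
per-section functional-unit counts from the aligned, assembled volume.
Lost sections are omitted, never interpolated.

### Torsion

`slice_orientation()` gives the major principal axis of the cartilage
mask from second central moments, in degrees CCW in the physical (x, y)
frame, wrapped to (−90°, 90°], plus the anisotropy ratio
$\sqrt{\lambda_1/\lambda_2}$; below 1.05 the orientation is flagged
unreliable (a disk has no meaningful axis). Orientations live on a
180°-periodic circle, so `unwrap_orientations()` adjusts successive
values by multiples of 180° to minimize each step, erroring on an
exactly-90° step (genuinely ambiguous). `total_torsion()` measures
orientations on the raw sections and *adds* each section's recovered
rotation — a rigid rotation shifts the principal axis exactly, so the
aligned-frame orientation needs no image resampling. The total is the
endpoint difference of the unwrapped sequence over reliable sections
(unreliable ones are interpolated in the sequence but excluded from
the fit), with a least-absolute-deviations line fit (IRLS) reported
alongside as slope and R². Sign convention: positive torsion is the
caudal edge turning medially from pharynx toward middle ear; reversing
the stack negates the total exactly, and a common rotation of all
sections leaves it unchanged (both are tested invariants).

### Meshes

`label_to_mesh()` extracts the 0.5-level surface of a compartment mask
by marching tetrahedra on the Freudenthal decomposition: every cell
between eight voxel centres splits into six tetrahedra sharing the main
diagonal, each crossed tetrahedron contributes one or two triangles
with vertices at crossing-edge midpoints, and because every cell uses
the same decomposition, adjacent cells agree on their shared-face
triangulation — the surface is watertight by construction, with no
marching-cubes ambiguity table. The mask is padded with background so
surfaces always close. Enclosed volume (divergence theorem) matches the
analytic sphere and the voxel count to within 5 %. Optional Laplacian
smoothing stops early if the enclosed volume would drift more than 5 %.
Output is binary little-endian STL (80-byte header, 50 bytes per
triangle, normals recomputed from the winding), one file per
compartment; reading validates byte counts and reports the offset of a
truncation.

## 3. What the synthetic data does and does not show

The generator reproduces the *geometry* of the protocol: the twist, the
compartment topology and its axial trends, the fiducial/groove
references, the sectioning arithmetic, rigid mounting errors, tilt at
the groove read-outs, section loss, and measurement noise. Passing
tests therefore demonstrate that the estimators invert this geometry —
that alignment, z assignment, registration, morphometry and torsion
recover known ground truth at the protocol's noise levels.

They do not demonstrate robustness to everything real sections add:
stain variability, tears, folds, saw-kerf artifacts, non-rigid
deformation of sections, segmentation error (the phantom supplies
perfect labels), or needle voids that must be found in RGB intensity
rather than a label. The torsion reference value itself is a
single-specimen measurement with no stated angular landmark or error
bar; the package reproduces it as parameter recovery on the phantom,
not as a re-measurement of the original data. Finally, the stacking
criterion genuinely cannot see a global twist with perfectly parallel
needles; the accuracy of the recovered torsion rests on the needles'
slight non-parallelism and, in the real protocol, on the tomographic
registration.

## 4. Parameter summary

| Parameter | Default | Units | Why |
|---|---|---|---|
| section thickness | 33 | µm | cutting protocol |
| blade thickness | 330 | µm | cutting protocol |
| sections / lost | 100 / 2 | – | protocol; first of each block lost |
| translation SD | 0.3 | mm | mounting error scale |
| rotation SD | 2 | ° | mounting error scale |
| tilt SD | 0.2 | ° | "slight" non-parallelism, first order |
| groove noise | 5 | µm | micrometer read-out |
| needle radius | 0.45 | mm | 0.9 mm cannulas |
| twist | 38 | ° | specimen's reported cartilage torsion |
| reference resolution | 0.3 | mm | tomographic scan resolution |
| voxel (x, y, z) | 0.1, 0.1, 0.1815 | mm | desk-scale fixture |
| detection area gate | 0.25–4 × πr² | – | obliquity allowance |
| anisotropy gate | 1.05 | – | orientation reliability |
| BCD tolerance | 1e-10 | relative | exact-recovery regime |
| perimeter smoothing | 5 | vertices | staircase-bias removal |
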