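---
title: "Methods: mapping and measuring cylindrical S-layer lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping and measuring cylindrical S-layer lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slayermap)
```

## The system and the model

Many archaea coat their cytoplasmic membrane with a paracrystalline protein
surface layer (S-layer). In rod-shaped methanogens such as *Methanospirillum
hungatei* the S-layer is a hexagonal lattice of six-subunit protein tiles
(hexamers) wrapped seamlessly around a cylindrical cell roughly 0.4 um across
and 7 um long, sandwiched between the membrane and an outer sheath. Cryo-
electron tomography with subtomogram averaging (STA) yields one 3D pose per
hexamer: a position and an intrinsic-ZYZ Euler orientation in RELION's
convention. `slayermap` treats that pose table as its raw data and answers
geometric questions about the lattice:

* what is the lattice unit distance, and which particle pairs are neighbours;
* how the three tiling directions run relative to the cell's cylinder axis,
  including a possible small helical offset;
* where the lattice is locally curved versus flattened (the basis for
  selecting particles for C6 -> C2 symmetry relaxation);
* whether coordination defects (vacancies, pentamer-like sites) occur;
* and what the tiling implies at whole-cell scale: copy numbers, pore
  counts, surface-to-volume ratio, and the extra area of the dimpled tile
  surface.

Because no public particle tables are needed to exercise any of this, the
package includes a first-class synthetic generator whose defaults *are* the
study conditions; every downstream stage is validated against its ground
truth.

## The synthetic lattice generator

`generate_cylinder_lattice()` builds a triangular lattice with unit distance
$a$ in the unrolled (circumference, axis) plane and wraps it onto a cylinder
of diameter $d$:

* rows are spaced exactly $a\sqrt{3}/2$ around the circumference;
  $n_\mathrm{circ} = \lfloor \pi d / (a\sqrt{3}/2) \rfloor$ rows fit, and the
  non-integer remainder is absorbed in a single seam gap (seam particles are
  marked in the truth labels). This keeps the unit distance undistorted and
  matches floor-based repeat counting.
* the axial extent covered is exactly $\lfloor L/a \rfloor$ repeats, so at
  zero helix angle the particle count equals the product of the two repeat
  counts reported by `lattice_repeats()` — 466 x 96 = 44,736 for the default
  geometry.
* a helical offset rotates the lattice basis in the unrolled plane before
  wrapping; its sign sets the chirality (the measurement on real cells does
  not determine chirality, so both are supported).
* each particle's Euler orientation encodes the outward surface normal
  (third frame axis) and the direction-1 lattice vector (first frame axis).

**Units.** The canonical internal unit is nm; STAR coordinates default to
pixels with an explicit pixel size in Angstrom per pixel (Angstrom input is
available behind a flag), matching common STA export practice.

**Diameter versus radius.** Published descriptions of this cell quote both
"0.4-um radius" and 0.4-0.5 um *diameter*. Only the diameter reading is
consistent with the printed repeat counts (96 rows need a circumference of
$\pi \times 400$ nm) and with the observed cell widths, so `slayermap` uses
0.4 um as the diameter throughout and documents this choice.

**Noise model.** Positional noise is isotropic Gaussian in 3D applied after
wrapping (default study condition: $\sigma = 0.5$ nm, a small fraction of the
15-nm unit distance, consistent with sub-nanometre STA alignment precision);
orientation noise is optional Gaussian on a random rotation axis (default 0).
Dropout removes sites independently with fixed probability. No spatially
correlated distortions (stage drift, local lattice strain) are simulated:
passing tests show correct recovery under independent noise, not robustness
to correlated deformation fields.

**Flattening.** Plunge-frozen cells compress near the air-water interface,
becoming elliptical in cross-section. `apply_flattening()` maps the circular
cross-section to an ellipse of *equal perimeter* (semi-minor axis
$b = R(1-f)$; the semi-major axis solves the perimeter equation numerically),
so arc length along the surface — and hence lattice spacing — is preserved to
first order. The true cross-sectional curvature $\kappa(t) = ab/(a^2\sin^2 t
+ b^2\cos^2 t)^{3/2}$ at each particle is stored as a truth label, giving the
curvature classifier an exact reference.

**Defects.** Vacancies (removed sites with their former neighbours marked)
stand in for lattice defects. True 5-fold disclinations are *not* generated:
on real cells pentamer-induced vertices are confined to the end-plug caps,
and no geometry is published for tube-region disclinations to emulate.

**Envelope layers.** `generate_envelope_layers()` samples four concentric
cylindrical point sets — membrane, S-layer base, S-layer cap, sheath — at
gaps of 12 nm (PS-1), 9.5 nm (tile height) and 4 nm (PS-2) by default,
mirroring the envelope cross-section seen in tomograms.

## Lattice graph reconstruction

`estimate_unit_distance()` pools first-shell inter-particle distances (below
1.6 x a rough nearest-neighbour scale, which keeps the second shell at
$a\sqrt{3}$ out) and returns the kernel-density mode. The mode of the
*first-shell distance distribution* is used rather than the mode of each
particle's minimum distance: the minimum of six noisy edges is biased low by
order $\sigma$, while the first-shell peak stays centred on $a$. On a
cylinder even noiseless estimates sit a hair (< 0.05%) below $a$ because
circumferential neighbour distances are chords.

`build_graph()` links pairs within $a(1 \pm 0.2)$ by default — wide enough
for 0.5-nm noise and mild flattening, narrow enough to exclude the second
shell. Neighbour search uses a grid cell-list (linear scaling); an $O(n^2)$
all-pairs oracle in the test suite verifies exact agreement.

**Tangent frames.** Each node's normal is the smallest-variance PCA axis of
its neighbourhood. Signs are first made consistent across the neighbour
graph (breadth-first propagation), then each connected component is oriented
outward by its *aggregate* convexity — the summed component of
(node - neighbourhood centroid) along the normal, positive outside a convex
surface. Per-node convexity is an unreliable sign cue at realistic noise
(the centroid dip of ~0.5 nm is comparable to $\sigma$); the component
aggregate over thousands of nodes is not. Euler-encoded normals can be
trusted instead via `use_pose_normals = TRUE`.

**Boundary versus defect.** A node is *boundary* when its tangent-plane
neighbour directions leave an angular gap > 150 degrees, or when a gap in
(100, 150] degrees has no second-shell support (no particle at 1.3-2.6 unit
distances inside the gap arc). This two-step rule is needed because a
vacancy neighbour (coordination 5) shows a 120-degree gap exactly like an
axial end-row node; the difference is that behind a vacancy the lattice
continues. Interior nodes with coordination other than 6 are reported by
`detect_defects()`.

**Direction classes.** Edge orientations are measured in each node's tangent
plane against a common reference — the projection of the cell axis — and
clustered with the 6-fold bond-orientational (hexatic) order parameter
$\psi_6 = \langle e^{6i\phi} \rangle$: its argument fixes a base axis and the
three class axes sit 60 degrees apart. Class 1 is the axis closest to the
cell axis; edges further than 15 degrees from every axis, or whole cells with
$|\psi_6| < 0.4$, stay unassigned with a warning. Because the reference is
derived from the data, the classification is invariant under rigid motion.

## Curvature

The estimator is a least-squares quadric height field over each particle's
neighbourhood within 2.2 unit distances (the 1- and 2-ring of the lattice —
the tightest window that leaves the fit well-conditioned at lattice point
density; nothing in the published work specifies an estimator, so this
choice is the package's own). The fitted form includes constant and linear
terms, and principal curvatures come from the shape operator with the slope
correction, so small tangent-frame misalignments do not bias the result.
Sign convention: curvature is positive where the surface bends away from the
outward normal — a tube seen from outside has $k_1 = +1/R$, $k_2 = 0$, mean
curvature $H = 1/(2R)$.

Classification labels a particle *curved* when $|H|$ reaches a threshold.
The default threshold, half the fitted tube's mean curvature
($0.5 \times 1/(2R_\mathrm{fit})$), cleanly separates the flattened top and
bottom of a compressed cell from its tightly curved flanks; it is exposed as
a parameter because the published selection of "curved portions" names no
numeric value. `export_subset()` writes either class back out as a
STAR-compatible particle set for external STA refinement.

## Cylinder axis and the direction-1 angle

`fit_cylinder()` initialises the axis from the first principal component and
refines four parameters (two axis offsets, two tilts; the radius is profiled
as the mean radial distance) by Levenberg-Marquardt on the radial residuals.
The fit requires particles spanning more than two diameters along the long
axis: shorter clouds have more radial than axial variance, so the principal
axis — and any axis-dependent measurement — becomes unreliable. The analysis
scripts therefore simulate segments of at least 1 um. A cell whose RMS
radial residual far exceeds the noise level (e.g. a flattened cell) is not
cylindrical; the residual is reported so callers can exclude such cells.

The direction-1 angle is measured per class-1 edge, in the tangent plane,
against the projected axis; the per-cell value is the circular mean with
period 60 degrees (the hexagonal symmetry) folded into [0, 30] degrees.
Per-edge-then-per-cell averaging was chosen over averaging direction vectors
directly because tangent planes rotate around the tube, and over per-cell
medians for comparability with a mean over cells; the signed variant
(chirality) is available behind a flag. `aggregate_angles()` takes the
arithmetic mean over cells and bins a histogram, mirroring how the
measurement is reported across a cohort of cells.

## The geometric census

With $L = 7$ um, $a = 15$ nm, $d = 0.4$ um:

* repeats: $\lfloor L/a \rfloor = 466$ axial,
  $\lfloor \pi d/(a\sqrt{3}/2) \rfloor = 96$ circumferential (floor, not
  round — 7000/15 = 466.7 and 1256.6/12.99 = 96.7);
* copies: $466 \times 96 = 44{,}736$ hexamers, $\times 6 = 268{,}416$
  monomers;
* pores per tile on the infinite lattice: the 7 intrinsic pores (1 central
  SP-1 + 6 peripheral SP-2) plus interface pores divided by their sharing —
  6 trimeric vertices per tile in two alternating classes (SP-3, SP-4), each
  shared by 3 tiles, contributing $3/3 + 3/3 = 2$; 6 dimeric edges (SP-5),
  each shared by 2, contributing $6/2 = 3$ — totalling 12, i.e. 536,832
  pores per cell. The two-class vertex accounting is the only reading
  consistent with both "two for SP-3 and SP-4" and the total of 12. The
  formula is verified in the tests against brute-force enumeration of
  distinct pores on toroidal lattices where the sharing factors emerge from
  deduplication rather than being assumed;
* SA/V: the capped cylinder reaches 0.0103 /nm against 0.0050 /nm for the
  equal-volume sphere — a ratio of 2.04, the "doubling" afforded by the rod
  shape.

**Dimpled-surface area factor.** The exposed tile surface is not flat, and
no parametric form of the relief is published, so the factor is explicitly
model-dependent and always reported with its model name. Two surfaces are
offered: a three-wave hexagonal corrugation (midpoint quadrature with
grid-doubling convergence control) and a spherical cap per tile (closed
form $1 + \pi h^2 / (\tfrac{\sqrt{3}}{2} a^2)$). With the full 9.5-nm tile
height both models exceed the ~30-40% enhancement expected of the dimpled
topology (sinusoidal: +56%, cap: +146%); that band is matched when $h$ is
taken as the relief depth of the cap domain (~4-5 nm) rather than the full
tile height, which includes the undimpled domain thickness. The factor's
flat limit and monotonicity in height and spatial frequency are what the
tests pin down; the absolute value is a modelling statement, not a
measurement.

## Numerical choices and degenerate inputs

* Seeded runs are bit-reproducible; every generator consumes an explicit
  seed and restores the caller's RNG state.
* Euler extraction handles the gimbal cases (tilt 0 or 180) by folding the
  degenerate angle into `rot`; rot/psi are canonicalised to [-180, 180).
* Quadric fits with fewer than 6 neighbours or a rank-deficient tangent
  plane yield records marked invalid; invalid records are excluded from
  classification and counted in reports.
* `estimate_unit_distance()` falls back to the median when all first-shell
  distances are numerically identical (a noiseless lattice would otherwise
  break the kernel bandwidth selector).
* Ties between class-1 axis candidates are broken by the smaller absolute
  angle to the axis, then the lower class index.
* The ellipse arc-length map inverts a dense cumulative-arc table (8192
  intervals, rescaled to close exactly), keeping perimeter error below 0.1%.

## Problem sizes in the tests and scripts

The packaged analyses run on desk-scale synthetic cells: segments of
0.9-1.2 um (3,800-7,700 particles) for graph, curvature, defect and axis
measurements, a 24-cell cohort for the angle histogram, and the full
44,736-particle tube only where the copy-number arithmetic itself is under
test. These sizes keep every simulated measurement comfortably converged
(the angle-recovery SD across replicates is ~0.006 degrees, far inside the
0.3-degree acceptance band) while the whole suite stays fast.

## Known limitations

* Tomogram-dependent quantities (map resolutions, the measured angle
  distribution over real cells, the measured 15-nm/9.5-nm dimensions) are
  generator presets and recovery targets here, not re-measurements.
* The generator's vacancies are not disclinations; detector behaviour on
  true 5-fold defects is untested for lack of a published geometry.
* The flattening map preserves arc length only to first order in lattice
  spacing; for extreme flattening (f close to 1) the local spacing near the
  tight flanks distorts.
* Direction classification assumes a single coherent lattice patch per
  cell; polycrystalline lattices (multiple grains) would need per-patch
  hexatic clustering.
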