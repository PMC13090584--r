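---
title: "Data model and methods of tomopick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data model and methods of tomopick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomopick)
```

`tomopick` models collaborative cryo-electron tomography (cryoET)
annotation projects: tomographic volumes, particle picks with full 3D
poses, voxel segmentations and surface meshes, organized in layered,
storage-agnostic projects, plus the processing operations used to convert
and filter annotations. This vignette documents the data model, the
numerical conventions, the genuinely open design choices the package makes,
and what the test suite does and does not demonstrate.

## The layered project model

A project is defined by a single JSON configuration: a list of *pickable
objects* (each with a unique name, a segmentation label in 1..255 — labels
must fit the 8-bit semantic masks, 0 being background — an RGBA display
color, a particle radius in angstrom when the object is a particle, and
optional PDB/EMDB/ontology identifiers) and an ordered list of storage
*layers*. Each layer is a storage root resolved through a pluggable backend
registry; local directories ship with the package, and remote schemes can
register factories implementing the same read/write/list/delete contract.

Exactly one layer is mutable; all writes land there. Static layers are
opened read-only at the backend level, so even a buggy caller cannot modify
shared reference data — the test suite asserts this by hashing every file
under a static root before and after full command-line sessions. When no
modes are given in the configuration, the last layer is taken as mutable;
this default makes the common "shared reference + private overlay" setup a
two-line configuration. Unknown configuration keys are ignored rather than
rejected, so configurations written by newer tools still load.

All data derived from one region of interest form a *Run*. Within a run an
entity is identified by `(kind, object, user, session)`; the session
distinguishes concurrent annotation sessions of one user. `list_entities()`
returns the union over layers in deterministic order (layer order, then
lexicographic identity). When the same identity exists in a static and the
mutable layer, both are listed and reads default to the mutable one —
refinements shadow references, but provenance is preserved and the static
copy remains addressable explicitly. `copy_to_mutable()` copies payload
bytes verbatim, which is the supported route for refining reference
annotations.

On disk a layer follows a fixed layout
(`ExperimentRuns/<run>/Picks/<user>_<session>_<object>.json`,
`.../Meshes/...glb`, `.../Segmentations/<spacing>_..._<object>.zarr`,
`.../VoxelSpacing<s>/<name>.zarr`). This naming is this package's dialect;
user and session identifiers may not contain underscores because
underscores delimit the fields.

## Multiscale volume storage

Volumes are 3D arrays in ZYX axis order with an isotropic voxel spacing
`s` in angstrom per voxel. Each stored volume is a three-level pyramid at
binnings 1, 2 and 4, level `L` having shape `ceiling(shape0 / 2^L)` per
axis — ceiling, so that odd dimensions keep partial edge blocks and no
voxel is ever dropped.

The binning operator is a design decision the storage format leaves open.
Continuous data (tomograms, feature maps) use the 2×2×2 block **mean**:
it anti-aliases and conserves total intensity, and edge blocks average over
the voxels actually present. Label data use the 2×2×2 block **majority
vote** with ties broken toward the smaller label; this keeps integer
semantics, is deterministic, and guarantees that no pyramid level
introduces a label absent from level 0 (background 0 participates in the
vote like any label).

Chunks default to 256³ voxels, clipped to the array shape for small
volumes, and are encoded with a byte-shuffle filter followed by an LZ4
block codec — both implemented in C++ in this package and emitting the
byte layout of the corresponding numcodecs codecs, so stores remain
readable by other OME-Zarr implementations. Tomograms and features are
stored as 32-bit floats (values are snapped to float32 on import, so the
in-memory array equals the stored one bit for bit); semantic segmentations
as 8-bit unsigned integers. Instance segmentations with more than 255
labels are stored at 16 bits and flagged in metadata as an extension.
Voxel spacing is encoded as one scale transformation per level in the
OME-Zarr v0.4 group attributes. Region reads decode only the chunks
intersecting the requested half-open ranges, which the tests assert with
an instrumented counting backend.

MRC2014 exports write the standard 1024-byte header with no extended
header, mode 2 for float data, and the voxel spacing in the cell dimension
fields; a float export is therefore exactly `1024 + 4·n_voxels` bytes, a
law the tests verify on real files and `mrc_file_size()` extrapolates.
Import accepts modes 0, 1, 2 and 6. EM-format support is a fixed
512-byte header plus raw payload. TIFF volumes are read through the `tiff`
package; writing emits baseline little-endian float32 TIFFs directly,
because general-purpose TIFF writers rescale float data to [0, 1] and
would break lossless round trips of physical densities.

## Geometry conventions

All physical positions — pick locations, mesh vertices, transform
translations — are in angstrom, measured from the volume corner with
zero-based indexing in a right-handed frame:
`(x, y, z) = (ix·s, iy·s, iz·s)`. There is **no** half-voxel offset; index
0 maps to coordinate 0. The inverse mapping rounds half-up per axis (a
`floor` mode is available). This one convention is applied consistently in
rasterization, centroids, containment, distance computation and surface
extraction, which is what makes conversion round trips self-consistent.

Particle poses are 4×4 homogeneous matrices mapping the particle reference
frame into tomogram space, `p_tomo = T p_ref`, validated to have bottom row
(0, 0, 0, 1) and a rotation block in SO(3) within 1e-6 (orthonormality and
determinant). The translation captures positional refinement applied after
rotation.

Euler-angle ecosystems disagree on conventions, so all conversions route
through the matrix form. The dialects implemented are documented choices:

| dialect | axes | angles (degrees) | stored matrix |
|---|---|---|---|
| `relion` | ZYZ, intrinsic | rot, tilt, psi | `Rz(-rot) Ry(-tilt) Rz(-psi)` — transpose of that ecosystem's reference-to-particle matrix |
| `dynamo` | ZXZ | tdrot, tilt, narot | `Rz(tdrot) Rx(tilt) Rz(narot)` |

Matrix-to-angle extraction picks the solution with tilt in [0, 180]
degrees. At gimbal lock (tilt 0 or 180) the third angle is set to 0, the
residual in-plane rotation is folded into the first angle, and the result
carries a `gimbal_lock` attribute. Round trips are exact to well below
1e-6 away from and at the lock.

External particle tables: STAR (`_rlnCoordinateX/Y/Z`,
`_rlnAngleRot/Tilt/Psi`), Dynamo 35-column tables (coordinates 24–26 plus
shifts 4–6, angles 7–9) and CSV (`x,y,z` header required, optional
relion-dialect angles, scores preserved verbatim). Because those ecosystems
store coordinates in voxels as often as in angstrom, STAR and Dynamo
import requires an explicit `units` flag (with `spacing` for voxel units)
instead of guessing; exported shifts are always folded into coordinates in
the requested unit. TOM/AV3 MAT-files are out of scope (binary MATLAB
containers); the CSV path covers that exchange.

## Annotation operations

All thresholds (radius, distance, size) compare inclusively (`<=`), making
boundary behavior deterministic.

* **picks → segmentation** marks voxels whose position lies within the
  radius of a pick; each in-grid pick additionally stamps its nearest
  voxel, so a degenerate radius below the voxel pitch yields exactly one
  voxel per pick. Picks whose centers fall outside the grid are skipped and
  counted.
* **segmentation → picks** places one identity-pose pick at each connected
  component's centroid (mean of member voxel positions). Components are
  numbered in scan order of their first voxel, making output order
  deterministic.
* **segmentation → mesh** uses the cuberille construction: each foreground
  voxel owns the cube `[i·s − s/2, i·s + s/2]³` and every face adjacent to
  background emits an outward-oriented quad. The surface sits at the 0.5
  level of the nearest-neighbor-interpolated binary field, is closed by
  construction, and encloses every foreground voxel center — so
  voxelizing it back recovers the input mask exactly, comfortably above
  the 95% round-trip requirement. A marching-cubes-style surface would be
  smoother but does not admit this exact inverse; optional Laplacian
  smoothing is available for display, off by default because it shrinks
  the surface.
* **mesh → segmentation** checks each voxel center against the closed
  surface by ray parity (Möller–Trumbore, with points within a small
  tolerance of the surface counting as inside). Grazing rays near triangle
  edges are detected and retried along a different direction, so
  axis-aligned meshes do not produce parity artifacts. Non-watertight
  meshes are rejected with a boundary-edge count.
* **Distances** to meshes are exact point-to-triangle minima; distances to
  segmentations are minima over foreground voxel centers — cheaper,
  monotone, and consistent with the voxel position convention. The mesh
  path exists when sub-voxel exactness matters.
* **Boolean operations** require identical grid shape and spacing; mixed
  grids are rejected, never silently resampled (`resample_to_spacing()`
  is the explicit escape hatch: nearest-neighbor for labels, trilinear for
  continuous data). `subtract` is `a AND NOT b`, the operation used to
  carve intermembrane space from nested membrane masks.
* **Connected components** support 6/18/26 connectivity (default 26);
  **size filtering** keeps components within inclusive voxel-count bounds.
  **Skeletonization** is sequential thinning that only removes *simple
  points* — voxels whose deletion provably changes neither foreground nor
  background topology in the (26, 6) digital topology — while keeping
  curve endpoints; topology preservation is therefore by construction, at
  the cost of a scan-order-dependent (but deterministic) medial axis.
* **Convex hulls** are built incrementally over pick positions or
  foreground voxel centers; degenerate (collinear/coplanar) inputs raise a
  dimensionality error rather than returning a flat shell.
* **Surface sampling** draws faces proportional to area and points
  uniformly in barycentric coordinates from a caller-supplied seed; the
  seed is recorded on the result.

## The command-line surface

Commands live in a registry keyed by category (`processing`, `convert`,
`logical`, `project`) and name; external packages can register additional
`command_spec()`s, and collisions are errors. The registry drives three
surfaces with no per-command code: `--help`, a versioned JSON catalog
(`introspect`) listing every command with typed, documented parameters,
and a dry-run validator that checks a candidate command line without
executing. That catalog plus validation is deliberately the complete
contract an external agent needs to discover and compose pipelines;
language-model integration itself is out of scope. Exit codes: 0 success,
1 validation/execution failure, 2 unknown command or usage error (with
nearest-command suggestions). Every command accepts `--config`, `--run`,
`--log-level` and `--overwrite`; without `--overwrite`, writing an existing
identity is a conflict — the layer semantics, not a convenience default.

## The synthetic fixture generator

`make_fixture_project()` builds a deterministic two-layer toy project: the
static layer holds a tomogram (sum of solid spherical particle densities
and a slab or spherical-shell membrane plus additive Gaussian noise, dense
= bright for test readability — the opposite sign of raw cryoET contrast),
reference picks and the membrane mask; the mutable overlay starts empty.
Defaults: 48³ voxels at 10 Å/voxel, 8 particles of radius 30 Å with
minimum separation of three radii (keeping rasterized spheres disjoint so
component counting is unambiguous), membrane thickness 20 Å, noise σ 0.1
against unit-intensity structures — a size chosen so the full suite runs
in seconds while every code path (chunking, pyramids, all conversions) is
exercised. Particle centers also keep one radius plus half the membrane
thickness clear of the membrane. Ground truth records the planted
positions, the membrane mask and each particle's distance to the nearest
membrane voxel center.

What the fixture does *not* emulate: contrast transfer function effects,
the missing wedge, structured noise, crowding, or particle orientation
inside the density (spheres are isotropic). Passing tests therefore
demonstrate geometric and storage correctness — positions, shapes,
topology, byte-level round trips — not detection performance on real
micrograph-derived data.

## Numerical choices and limitations

* Float data are snapped to float32 at import so "stored equals in-memory"
  holds exactly; comparisons against float64 sources see ~1e-7 relative
  rounding.
* Majority-vote ties go to the smaller label; half-way coordinates round
  half-up; all range thresholds are inclusive — every tie-break is
  documented and deterministic.
* The LZ4 encoder is a greedy single-probe matcher: decode-compatible with
  the reference format and fast, but compression ratios trail the
  reference implementation's optimal parser on highly redundant data.
* Point-to-mesh distances and ray-parity tests are exact loops over
  triangles, adequate for annotation-scale meshes (10³–10⁵ faces); no
  spatial index is built.
* Skeletons are topology-exact but not centered medial axes; different
  scan orders would yield different (equally valid) skeletons.
* Remote storage backends (SSH, S3) are an interface, not an
  implementation: the backend registry accepts factories with the local
  contract, and only local directories ship here.
* Round-tripping a project written by other tools is not guaranteed: the
  on-disk naming is this package's documented dialect.

## Problem sizes used in checks

The shipped tests and the acceptance script work at desk scale: volumes up
to 70³ voxels, pyramids verified on ~10 random shapes, 100-instance
operation/oracle sweeps on ≤16³ grids, 200–400 random rotations for pose
round trips, and full CLI sessions on the 48³ fixture. The storage layer is
size-oblivious (chunked writes never materialize more than one chunk
beyond the input array), and the MRC size law is verified on real files
and extrapolated exactly to production-scale dimensions.
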