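---
title: "Quantifying contact-dependent intercellular transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contact-dependent intercellular transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The assay and what is measured

In a donor/acceptor co-culture, single DiD-stained donor cells sit
isolated (≥ 200 µm apart) in a confluent lawn of unstained acceptor
cells. Because membrane dye does not move through the medium on the assay
time scale, any supra-threshold DiD punctum found inside an acceptor cell
must have been transferred by cell contact from that field's donor. The
read-out per field is therefore:

* **transfer volume** — the number of voxels inside acceptor cells whose
  DiD intensity lies *strictly above* a global threshold (100 of 256
  gray levels; 100 or 160 of 256 for an EGFP read-out), excluding the
  dilated donor mask;
* **integrated transfer intensity** — the sum of gray values over those
  same voxels;
* **density** — intensity per voxel, a property of the transferred
  material itself.

Donor-free fields are quantified through the identical code path using a
*pseudo-donor* (the segmented cell whose centroid is nearest the stack
centre, blanked as if it were the donor), so background is measured with
the same estimator and the same exclusions as transfer.

All intensity thresholds are interpreted on the 8-bit scale;
`normalize_to_8bit()` (linear rescale, round-half-up) must be applied to
deeper acquisitions first, and `read_channel_set()` refuses to guess a
missing voxel size — every volume filter is expressed in µm³, so voxel
dimensions are mandatory metadata. "Above the threshold" is implemented
as strictly greater than everywhere, including the donor-intensity
threshold; this single convention is load-bearing for several exact-count
tests.

# Segmentation

Acceptor cells are segmented from the membrane stain in four stages, each
an exported function so it can be tested and replaced independently:

1. **Anisotropic diffusion** (`smooth_anisotropic`): Perona–Malik with
   edge-stopping function $g(\nabla u)=\exp\{-(\nabla u/K)^2\}$,
   explicit 6-neighbour scheme. Defaults: 4 iterations, conductance
   $K = 30$ gray units, time step 0.15 (the explicit scheme is stable for
   $\mathrm{d}t \le 1/6$). Gradients well above $K$ — membrane edges —
   are preserved; noise below $K$ is smoothed. Zero iterations is the
   identity.
2. **Marker generation** (`generate_markers`): the nuclear channel is
   thresholded (default 100), 26-connected components below the minimum
   nucleus volume (default 30 µm³) are discarded, and one *background
   marker* is added from low-membrane-intensity space connected to the
   axial faces of the volume (the medium above and the substrate side
   below the lawn). 6-connectivity is used for the background component
   so it cannot leak diagonally through a one-voxel membrane.
3. **Marker-controlled watershed** (`watershed_cells`): priority flood of
   the smoothed membrane intensity from all markers; each foreground
   marker grows into exactly one region, the background marker's region
   becomes label 0. Flooding is ordered by intensity with
   first-queued-first-served ties. The tie rule matters: membrane ridges
   are broad intensity plateaus, and a tie-break that prefers low marker
   labels would let the first cell flood an entire connected ridge
   network; FIFO ordering advances all fronts fairly across plateaus and
   is still fully deterministic. Flooding uses 6-connectivity on the
   voxel grid without physical-distance weighting; anisotropy is handled
   only by the µm-based volume filters downstream.
4. **Region classification** (`classify_regions`): a region is kept as a
   cell when its volume does not exceed `max_region_volume` (default
   20,000 µm³, several times a typical cell) and at least
   `min_boundary_coverage` (default 0.6) of its *surface* is
   membrane-covered. The surface is the region's boundary to other
   labels plus its image-border faces; a surface voxel counts as covered
   when the smoothed membrane exceeds `min_boundary_intensity` (default
   100) at the voxel or at an adjacent different-label voxel — region
   interfaces own one side of the membrane each, so the second clause
   makes the feature symmetric. Cells are wrapped in membrane almost
   everywhere and score near 1; a region spanning the medium above the
   lawn is bounded mostly by the bare image border and fails. Survivors
   are renumbered contiguously; the operation is idempotent.

None of these internal parameters is part of the published method; they
were tuned once against the synthetic generator and frozen as defaults so
results are reproducible.

# Donor detection and quantification

`detect_donor` recognises the donor by near-saturation signal: donors
are acquired with roughly half their volume at detector saturation, so
the detection threshold defaults to 250 of 255 (configurable,
`donor_intensity_threshold`); the exact level used by the original
implementation is not published. Thresholding is followed by discarding
26-connected components below 1,000 µm³, morphological closing to fill
internal holes, optional union with the EGFP-channel representation, and
union with the watershed cell of highest voxel overlap. The resulting
mask is dilated by one voxel in all directions (3×3×3 cube) and blanked
from all acceptor counts. Design choices where the published description
is ambiguous:

* *Closing element*: "two pixels" is read as a disc of radius 2 applied
  per z-slice — the conservative interpretation given the ~2:1 z
  anisotropy; a 3D ball is available via `closing_3d = TRUE`.
* *EGFP threshold*: 100 by default; 160 is selectable per experiment in
  the config, never auto-chosen.
* *Multiple donors*: stacks whose donor components attach to different
  watershed cells are rejected with an error rather than quantified —
  donor doublets void the attribution premise of the assay.
* *Weak donors*: a supra-transfer-threshold blob of donor size that
  stays below the donor intensity level marks the stack `weak_donor` for
  manual review instead of being silently quantified as a control.
* *Boundary exclusion* applies to the lateral (x/y) image borders only:
  the z-range of an acquisition is chosen to span the cells, so every
  cell touches the axial extremes of its own extent and excluding on z
  would discard everything.

# ROI selection on well mosaics

Low-resolution tiles (775 µm scan fields) are assembled row-major into a
well super-image. Donor candidates are supra-threshold 8-connected blobs
above a minimum area (default 50 µm²; the published method does not state
its cutoff). A donor position qualifies when the nearest other donor is
at least 200 µm away and at least 15 nuclei lie within a 200 µm radius;
both rules are inclusive at the boundary ("at least" reads as ≥), and
distances are measured from the donor centroid. Nuclei are detected as
supra-threshold local intensity maxima with a minimum mutual separation
of about one nuclear diameter (10 µm). Up to 15 control positions are
rejection-sampled uniformly over the well, each required to have no
donor within 200 µm, the same nucleus density, and a high-resolution
field footprint (an axis-aligned square, default 228 µm side) disjoint
from every previously accepted footprint; the sampler is deterministic
given its seed. The module ends at the coordinate CSV — microscope
control is out of scope.

# Statistics

Integrated transfer intensities are heavily right-skewed, so the layer
follows the assay's published procedure: per experiment, all values are
scaled by $100/\mathrm{median}(\text{control})$ (the control median
becomes exactly 100 %), then natural-log transformed; all tests run on
the transformed data, while dot plots and medians report the
untransformed normalized scale. Normality is checked with a chi-square
goodness-of-fit test against a normal with the sample mean and SD, using
equal-probability bins ($k = \lceil n/5 \rceil$ capped at 20, df
$= k - 3$); the binning is frozen so p-values are reproducible. With two
conditions a two-sided Student's t-test (equal variances, the classic
form; Welch optional) is used; with more, one-way ANOVA followed by
Dunnett's many-to-one comparisons against the control, with adjusted
p-values from the multivariate-t distribution (via `multcomp`).
Significance is called at α = 0.05.

Zero transfer values (possible for fully inhibited donors) cannot be
logged; they are replaced by a configurable pseudo-count (default 1
gray·voxel on the normalized scale) and the replacement count is carried
in the report. Values pooled across experiments are compared directly;
an experiment grouping column is preserved for users who prefer
per-batch analysis, but no mixed-effects modelling is attempted.

# The synthetic generator

`generate_lawn` emulates the acquisition the method was designed for: a
512 × 512 field with 1.01 µm z-spacing by default. The xy pixel size of
the original acquisition is not published; the default of 0.45 µm is
what a 40× objective at zoom 1.7 over 512 pixels implies (a ~230 µm
field). Cells are 2D Voronoi regions of Poisson-disc-placed nucleus
centres, extruded through a z-slab — columnar cells on a substrate. The
membrane channel carries a 1–2 voxel shell at every inter-cell boundary
(including diagonal adjacencies, so no flood can leak through a corner)
plus sealing planes at the slab faces; nuclei are bright ellipsoids; the
DiD channel is uniform noise strictly below the transfer threshold, so
noise can never be counted as transfer. Donors are painted with half
their volume at saturation as a coherent ball around the cell centroid —
a scattered random subset would fragment into sub-1,000 µm³ components
at threshold — and the remainder at a sub-saturation rim (default 180),
so detection cannot rely on saturation alone. Puncta are spheres of
known intensity whose centres keep a Chebyshev clearance of radius + 2
voxels from any cell boundary and never touch the dilated donor; ±1
voxel segmentation errors therefore cannot reassign ground-truth
transfer, which isolates quantification correctness from segmentation
accuracy in the tests. Well mosaics render nuclei as Gaussian spots and
donors as bright discs at known stage positions.

What the generator deliberately does **not** emulate: optics (PSF,
spectral bleed-through, photobleaching), nanotube geometry, irregular
cell shapes, intensity gradients with depth, or time-lapse dynamics.
Passing tests therefore demonstrate algorithmic correctness — exact
bookkeeping of labels, volumes, thresholds, masks and statistics — not
robustness to optical artefacts of real microscopy data.

# Problem sizes and verification

The test suite and the acceptance script characterise the package at
20 × 256 × 256 voxels with ~50 cells per stack — a quarter-field crop of
the default geometry that preserves cell size and density — using 50
seeded stacks for oracle equivalence (exact integer agreement between
the vectorised quantification and a brute-force triple voxel loop),
seeded wells for ROI-selection equivalence against exhaustive filtering,
1,000 null replicates for the family-wise error calibration of the
Dunnett pipeline (accepted range 3–7 % at nominal 5 %), and a per-cell
Jaccard ≥ 0.8 guard-rail for segmentation against ground-truth labels —
a property of the synthetic world that protects the downstream tests,
not a claim about real data.

# Known limitations

* Segmentation quality on real stacks depends on membrane-stain quality;
  the classification defaults assume a reasonably continuous stain.
* The watershed assigns ridge voxels to one of the abutting cells;
  per-cell volumes carry half-a-membrane uncertainty.
* Dunnett p-values from the multivariate-t distribution are computed by
  adaptive numerical integration and can vary in the fourth decimal
  between runs.
* TIFF I/O covers plain multi-page TIFF with a YAML metadata sidecar;
  proprietary formats must be converted upstream.
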