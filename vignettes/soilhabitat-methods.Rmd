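---
title: "Quantifying the microbial habitat around POM in soil microCT volumes"
author: "soilhabitat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the microbial habitat around POM in soil microCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilhabitat)
```

## The problem

Heterotrophic decomposition of particulate organic matter (POM) in soil
depends on the physical micro-environment around each particle: how much
pore space surrounds it (supplying oxygen, removing CO~2~, and carrying
dissolved nitrogen toward the decomposers), and whether that local pore
space connects to large, air-filled pores in the bulk soil. X-ray
micro-computed tomography resolves this micro-environment
non-destructively in incubated soil cores, but turning a gray-value
volume into habitat metrics takes a chain of image-analysis steps, each
with choices that are rarely published in enough detail to reproduce.

`soilhabitat` implements that chain end to end:

1. **Preprocessing** — contrast enhancement, 16→8-bit conversion,
   cylindrical region-of-interest (ROI) selection, Gaussian denoising.
2. **Three-phase segmentation** — mineral matrix by a conservative
   single threshold; added OM by dual (hysteresis) thresholding of the
   mineral-subtracted residual; pore space by subtracting OM from a
   conservative pore+OM threshold.
3. **Pore network** — exact Euclidean distance map, marker-based
   watershed separation, neck diameters as the maximum inscribed sphere
   on shared watershed boundaries, and the pore-neck-size distribution
   (PND) in seven classes: 10–30, 30–60, 60–90, 90–150, 150–250,
   250–350 and >350 µm.
4. **Local habitat** — a 350 µm shell around every OM particle, its
   *local porosity*, and its *connectivity*: the share of shell pore
   volume linked (through the region-adjacency graph) to bulk pores
   with equivalent sphere diameter (ESD) above 300 µm.
5. **Incubation metrics** — headspace CO~2~ to mineralized carbon via
   the ideal gas law, cumulative and net/relative C~min~, water-filled
   pore space (WFPS), and PLFA community indices (bacteria:fungi ratio,
   saturated:mono-unsaturated stress index, 1% abundance filter).

Because scanned cores of this kind are rarely deposited, the package
ships a first-class synthetic-phantom generator with analytic ground
truth; every stage of the pipeline is validated against construction,
brute-force oracles, or closed-form geometry.

## The phantom generator

A `phantomSpec()` describes a desk-scale analogue of an incubated core:
a cubic grid (default 256³ voxels at 10 µm pitch, i.e. a 2.56 mm cube —
full-scale scans of 1455 × 1455 × 1274 voxels are handled by the same
code but are not needed to exercise it), a target porosity, mineral
grain-size fractions, and ellipsoidal OM particles with diameters drawn
from the sieved range 500–1000 µm.

The two study structures are grain mixtures of coarse sand : fine sand
: silt+clay at **10:40:50** ("dense", fines-rich) and **20:60:20**
("loose", fines-poor). Three deliberate simplifications:

* **Grains are spheres.** Real grains are irregular; spheres keep the
  geometry analytic and placement trivial to verify. Irregular shape
  mainly adds surface roughness at scales near the voxel pitch, which
  the segmentation stage never resolves anyway.
* **Silt and clay are a sub-resolution matrix, not grains.** At 10 µm
  pitch a 20 µm grain is two voxels; the scans themselves cannot
  resolve this fraction (CT-visible porosity means pores wider than
  10 µm). Any grain fraction whose lower diameter bound is below two
  pitches is therefore rendered as a homogeneous mineral *matrix*: after
  sphere packing, the void voxels nearest to resolved surfaces are
  converted to mineral — a coating — until the solid fraction matches
  the target exactly. This makes the achieved porosity exact by
  construction (the ±2% calibration band in the tests is slack, not
  error) and reproduces the intuition that fines-rich soils coat
  surfaces and narrow pores.
* **OM-aware packing.** `generatePhantom()` places OM particles first
  and packs grains around them (grains reject overlap with OM). Packing
  *around* particles is what creates a structural boundary layer whose
  width scales with grain size: coarse mixtures cannot fill the region
  next to a particle as tightly as fine mixtures plus matrix can. This
  is the mechanism by which the generator reproduces the observed
  direction — lower local porosity around OM in fines-rich cores at
  equal bulk porosity. Carving particles into a finished pack
  (`embedOmParticles()`, also provided for its contract) leaves shell
  statistics identical to the bulk and cannot show a structure effect.

Sphere placement is random sequential addition with voxel-level
overlap rejection, largest fraction first, with a global cap of 10⁶
candidate draws. RSA jams near 38% solid for one sphere size; mixtures
with a matrix fraction are immune (the matrix absorbs the shortfall
exactly), and sphere-only specifications beyond jamming fail loudly,
reporting the achieved solid fraction. All candidate draws flow through
R's RNG, so a given `(spec, seed)` is bit-reproducible.

Gray rendering uses mean levels pore 40 < OM 110 < mineral 200 (8-bit)
plus additive Gaussian noise clipped to the bit range — the simplest
model that makes thresholds non-trivial. The scans' actual gray
statistics are unpublished, so these levels are free parameters, chosen
once, not calibrated to any figure.

## Segmentation choices

* Thresholds are caller-supplied (the original analysis chose them by
  inspection); `autoThresholdValley()` suggests a bimodal valley but is
  never applied silently.
* Dual thresholding keeps a weak-range voxel only if it is connected to
  a strong-range voxel through weak-range voxels. Connectivity defaults
  to 26 (the permissive foreground convention; 6 and 18 are options).
  On every fixture up to 64³ the implementation is checked voxel for
  voxel against an independent flood-fill-from-strong-seeds oracle
  built on `igraph` connected components.
* Components smaller than a 250 µm sphere (half the smallest sieved OM
  size) are discarded by default — added particles are ≥500 µm and
  native POM was removed from the soil before packing, so smaller
  components are partial-volume artifacts.
* Voxels inside the ROI claimed by neither the conservative mineral
  threshold nor the conservative pore+OM threshold are counted as
  mineral by default (`unclassified = "keep"` preserves them as an
  explicit label instead); porosity denominators always use the full
  ROI.

On noise-free phantoms any thresholds strictly between the phase gray
levels reproduce ground truth exactly; with noise at 10% of the
smallest phase contrast, the voxel error rate stays well below 1%
because the midway thresholds sit more than 4 s.d. from each phase
mean and isolated mislabeled voxels are removed by the component filter.

## Pore network numerics

The distance map is the exact Euclidean distance (not chamfer) from
each pore voxel center to the nearest non-pore voxel center, computed
by the separable lower-envelope algorithm; the volume boundary is
treated as solid. Watershed markers are regional maxima after h-maxima
suppression with `hMinUm` = one pitch by default: deep enough to remove
plateau/discretization maxima, shallow enough not to merge genuine
pores (the parameter used by the original proprietary tool is
unpublished). Flooding proceeds highest-distance-first with
first-in-first-out tie-breaking, so labelings are deterministic;
region labels follow raster discovery order of the markers.

Necks use the standard conventions: region adjacency and boundaries are
face (6-) adjacency, pore connectivity is 26, and the neck diameter is
twice the maximum distance-map value over the shared boundary — the
diameter of the maximum inscribed sphere in the neck. On two-sphere
neck phantoms with true diameters 20–300 µm at 10 µm pitch, measured
necks land within two pitches of truth and always in the correct PND
class.

For the PND, a region connected by several necks is classed by its
*largest* neck (best-access convention; `rule = "smallest"` is the
alternative), while isolated regions and the single largest region are
classed by their own maximum inscribed sphere. Governing diameters
below 10 µm (possible for slivers of a few voxels) are counted in the
lowest class so that class volumes always sum to the pore volume
exactly.

## Local habitat

The shell of a particle is its Euclidean dilation by the shell radius
(default 350 µm) minus the particle, other OM particles, and
out-of-ROI voxels; shells of neighboring particles may overlap, and a
shell truncated by the grid or ROI is flagged `clipped`. The 350 µm
default is the radius at which the between-particle variance of local
porosity settles — `shellRadiusSweep()` reproduces that diagnostic.
Local porosity is pore voxels over shell voxels (OM excluded from the
denominator, consistent with bulk porosity; an inclusive denominator is
a one-line sensitivity variant via the shell voxel set).

Connectivity treats the watershed regions intersecting the shell as
"local pores"; a local pore is connected if any path in the
neck-adjacency graph reaches a region with ESD > 300 µm that has at
least one voxel outside the shell (or if it is itself such a region).
Defaults follow the study (350 µm shell, 300 µm ESD cutoff — pores of
that size remain air-filled at the study's moisture levels); both are
plain arguments. Two documented ambiguities are exposed as options
rather than guessed: volume share (default) vs count share of local
pores, and any-length paths (default) vs direct adjacency only.

## Incubation metrics

CO~2~ fluxes convert blank-corrected headspace ppm to µg C g⁻¹ via the
ideal gas law (R = 0.0820574 L atm mol⁻¹ K⁻¹, C = 12.011 g mol⁻¹).
The integration rule for cumulative C~min~ — not stated in typical
protocols — is declared: the enclosure-period rate holds from the
midpoint of the previous sampling interval to the midpoint of the next
(day 0 opens the first interval; the series ends on the last sampling
day). The synthetic generator uses the same forward model, so the
pipeline recovers its truth exactly at zero noise; this is a round-trip
check of unit bookkeeping, not evidence about real gas exchange.
Relative C~min~ requires the substrate application rate as an input
(`substrateCarbonAdded()`), since absolute rates are study-specific.

PLFA indices follow the marker-group table in `plfaMarkerGroups()`.
The 1% abundance filter is applied per sample against that sample's
total (the per-dataset alternative is a flag), retains acids *strictly
above* the threshold, and is idempotent because removing an acid can
only raise the shares of the remainder. Saturation classes are parsed
from the acid-name grammar; cyclopropyl and methyl-branched acids
carry no double bond and count as saturated, a documented convention
(whether the original stress index included cyclopropyl acids is not
stated anywhere we could verify).

## What the tests do and do not show

Problem sizes were chosen so the full suite exercises every contract at
desk scale: segmentation on ten 256³ cores, dual thresholding on fifty
64³ fixtures, watershed against a brute-force priority flood on ≤32³
fixtures, the structure effect on twenty pairs of 128³ cores with 40 OM
particles each (OM and grain sizes scaled to the grid: OM 200–350 µm,
sand fractions 53–500 µm). Passing them shows the *pipeline* is
correct: exact phase recovery, oracle-identical flood fills and
watersheds, neck diameters within two voxels, analytic shell volumes,
exact porosity accounting, and the qualitative dense-vs-loose direction
under the generator's assumptions.

They do not show that real scans behave like phantoms. Real data add
partial-volume gray values at every interface, beam hardening and ring
artifacts, irregular grain and particle shapes, and gray-level overlap
between OM and wet clay; threshold choice on real data remains a
judgment the package records (in `PhaseMap@thresholds`) but does not
make. The structure-effect test demonstrates the direction of the
habitat contrast under sphere packing with a matrix coating, not its
magnitude in soil.

## Known limitations

* Hysteresis, labeling and watershed are single-threaded; full-size
  scans (~2.7 × 10⁹ voxels) work but take correspondingly longer and
  need the volume in memory (double precision for the distance map).
* The matrix fill is a geometric stand-in for sub-resolution texture;
  it cannot emulate water menisci or aggregate-scale structure.
* `embedOmParticles()` re-renders the volume from truth labels, so it
  is only meaningful on phantoms, not on measured volumes.
* No significance testing or ordination is included by design; the
  outputs are tidy per-core tables meant for the user's own statistics.
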