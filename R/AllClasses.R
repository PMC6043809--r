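#' VoxelVolume: a 3D grayscale scalar field with physical voxel pitch
#'
#' Container for reconstructed microCT data (or synthetic phantoms).
#' Values are stored as a numeric 3D array holding unsigned integer gray
#' values at the recorded bit depth; the voxel pitch (edge length, in
#' micrometers) carries all linear measures. In-memory axis order is
#' (y, x, z): the third array index is the slice (z) axis, matching one
#' TIFF page per z-slice on disk.
#'
#' @slot values 3D array of gray values.
#' @slot pitchUm Voxel edge length in micrometers (> 0).
#' @slot bitDepth Integer, 8 or 16.
#' @export
setClass("VoxelVolume",
  representation(values = "array", pitchUm = "numeric", bitDepth = "integer"))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@pitchUm) != 1L || !is.finite(object@pitchUm) ||
      object@pitchUm <= 0)
    msg <- c(msg, "pitchUm must be a single positive number")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  rng <- suppressWarnings(range(object@values))
  if (is.finite(rng[1]) &&
      (rng[1] < 0 || rng[2] > 2^object@bitDepth - 1))
    msg <- c(msg, "values exceed the recorded bit range")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelVolume
#'
#' @param values 3D numeric array of gray values.
#' @param pitchUm Voxel pitch in micrometers.
#' @param bitDepth 8 or 16 (default 8).
#' @return A [VoxelVolume-class] object.
#' @export
#' @examples
#' v <- VoxelVolume(array(0, c(4, 4, 4)), pitchUm = 10)
#' pitchUm(v)
VoxelVolume <- function(values, pitchUm, bitDepth = 8L) {
  storage.mode(values) <- "double"
  new("VoxelVolume", values = values, pitchUm = as.numeric(pitchUm),
      bitDepth = as.integer(bitDepth))
}

#' RoiMask: cylindrical (or arbitrary) region-of-interest mask
#'
#' Boolean per-voxel mask selecting the analysis region, normally a
#' cylinder inscribed in the lateral cross-section to avoid container
#' border artifacts. `geometry` records the cylinder descriptor.
#'
#' @slot mask 3D logical array.
#' @slot geometry List describing the mask (type, center, radius
#'   in voxels, z range), or an empty list for free-form masks.
#' @export
setClass("RoiMask", representation(mask = "array", geometry = "list"))

setValidity("RoiMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' PhaseMap: per-voxel phase labels
#'
#' Result of three-phase segmentation. Labels use the codes of
#' [phaseCodes()]: outside ROI, mineral, pore, organic matter (and
#' optionally an explicit unclassified remainder). `thresholds` records
#' the gray thresholds used, for provenance.
#'
#' @slot labels 3D integer array of phase codes.
#' @slot pitchUm Voxel pitch (micrometers).
#' @slot thresholds Named list of the thresholds that produced the map.
#' @export
setClass("PhaseMap",
  representation(labels = "array", pitchUm = "numeric", thresholds = "list"))

setValidity("PhaseMap", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  codes <- unique(as.vector(object@labels))
  if (!all(codes %in% .PHASE)) return("unknown phase codes present")
  if (object@pitchUm <= 0) return("pitchUm must be positive")
  TRUE
})

#' OmParticleSet: labeled organic-matter particles
#'
#' Connected components of the segmented OM phase. `ids` holds the
#' particle id per OM voxel (0 elsewhere); `particles` is one row per
#' particle with voxel count, centroid (voxel coordinates, 0-based) and
#' bounding box.
#'
#' @slot ids 3D integer array of particle ids (0 = background).
#' @slot particles data.frame: id, voxels, centroid/bbox columns.
#' @slot pitchUm Voxel pitch (micrometers).
#' @slot connectivity Neighborhood used for labeling (6, 18 or 26).
#' @export
setClass("OmParticleSet",
  representation(ids = "array", particles = "data.frame",
                 pitchUm = "numeric", connectivity = "integer"))

setValidity("OmParticleSet", function(object) {
  if (length(dim(object@ids)) != 3L) return("ids must be a 3D array")
  if (!(object@connectivity %in% c(6L, 18L, 26L)))
    return("connectivity must be 6, 18 or 26")
  TRUE
})

#' DistanceMap: Euclidean distance to the nearest non-pore voxel
#'
#' Per-pore-voxel Euclidean distance (micrometers, center-to-center) to
#' the nearest non-pore voxel; zero outside the pore mask. The volume
#' boundary is treated as solid.
#'
#' @slot values 3D numeric array of distances (micrometers).
#' @slot pitchUm Voxel pitch (micrometers).
#' @export
setClass("DistanceMap",
  representation(values = "array", pitchUm = "numeric"))

#' PoreNetwork: watershed-separated pore regions and their necks
#'
#' @slot labels 3D integer array of pore-region labels (0 = non-pore).
#' @slot regions data.frame: id, voxels, volume_um3, esd_um,
#'   max_insphere_um.
#' @slot necks data.frame: id_a, id_b, neck_um — one row per
#'   face-adjacent region pair; the neck diameter is twice the maximum
#'   distance-map value on the shared watershed boundary.
#' @slot pitchUm Voxel pitch (micrometers).
#' @export
setClass("PoreNetwork",
  representation(labels = "array", regions = "data.frame",
                 necks = "data.frame", pitchUm = "numeric"))

setValidity("PoreNetwork", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  need <- c("id", "voxels", "volume_um3", "esd_um", "max_insphere_um")
  if (!all(need %in% names(object@regions)))
    return("regions table is missing required columns")
  if (nrow(object@necks) &&
      !all(c("id_a", "id_b", "neck_um") %in% names(object@necks)))
    return("necks table is missing required columns")
  TRUE
})

#' GroundTruth: analytic truth for a synthetic phantom
#'
#' @slot labels 3D integer array of phase codes (mineral/pore/om).
#' @slot omIds 3D integer array of OM particle ids (0 = none).
#' @slot omParticles data.frame of placed particles.
#' @slot pitchUm Voxel pitch (micrometers).
#' @slot truePorosity Pore fraction of the non-OM grid volume.
#' @slot info List of extra analytic descriptors (e.g. neck diameter).
#' @export
setClass("GroundTruth",
  representation(labels = "array", omIds = "array",
                 omParticles = "data.frame", pitchUm = "numeric",
                 truePorosity = "numeric", info = "list"))

#' HabitatShell: the local-porosity shell of one OM particle
#'
#' Voxel set within a fixed Euclidean radius (default 350 um) of an OM
#' particle, excluding the particle itself, other OM particles, and
#' voxels outside the ROI. Stored as linear voxel indices into the grid.
#'
#' @slot particleId Particle id the shell belongs to.
#' @slot voxels Integer vector of linear voxel indices (1-based).
#' @slot dim Grid dimensions.
#' @slot radiusUm Shell radius in micrometers.
#' @slot pitchUm Voxel pitch in micrometers.
#' @slot clipped TRUE if the shell was clipped by the grid or ROI.
#' @export
setClass("HabitatShell",
  representation(particleId = "integer", voxels = "integer",
                 dim = "integer", radiusUm = "numeric",
                 pitchUm = "numeric", clipped = "logical"))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, pitch %.3g um, %d-bit\n",
              d[1], d[2], d[3], object@pitchUm, object@bitDepth))
  cat(sprintf("  gray range [%g, %g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("RoiMask: %d of %d voxels selected (%.1f%%)\n",
              sum(object@mask), prod(d), 100 * mean(object@mask)))
  if (length(object@geometry))
    cat("  geometry:", object@geometry$type,
        sprintf("radius %.1f vox", object@geometry$radius_vox), "\n")
})

setMethod("show", "PhaseMap", function(object) {
  tab <- tabulate(object@labels + 1L, nbins = 5L)
  names(tab) <- names(.PHASE)
  cat("PhaseMap:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "OmParticleSet", function(object) {
  cat(sprintf("OmParticleSet: %d particles, %d OM voxels (conn %d)\n",
              nrow(object@particles), sum(object@ids > 0L),
              object@connectivity))
})

setMethod("show", "PoreNetwork", function(object) {
  cat(sprintf("PoreNetwork: %d regions, %d necks, pitch %.3g um\n",
              nrow(object@regions), nrow(object@necks), object@pitchUm))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: porosity %.4f, %d OM particles\n",
              object@truePorosity, nrow(object@omParticles)))
})

setMethod("show", "HabitatShell", function(object) {
  cat(sprintf("HabitatShell: particle %d, %d voxels, radius %g um%s\n",
              object@particleId, length(object@voxels), object@radiusUm,
              if (object@clipped) " (clipped)" else ""))
})
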