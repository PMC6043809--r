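#' Voxel pitch accessor
#' @param x An object carrying a voxel pitch.
#' @return Voxel edge length in micrometers.
#' @export
setGeneric("pitchUm", function(x) standardGeneric("pitchUm"))

#' @rdname pitchUm
#' @export
setMethod("pitchUm", "VoxelVolume", function(x) x@pitchUm)
#' @rdname pitchUm
#' @export
setMethod("pitchUm", "PhaseMap", function(x) x@pitchUm)
#' @rdname pitchUm
#' @export
setMethod("pitchUm", "OmParticleSet", function(x) x@pitchUm)
#' @rdname pitchUm
#' @export
setMethod("pitchUm", "DistanceMap", function(x) x@pitchUm)
#' @rdname pitchUm
#' @export
setMethod("pitchUm", "PoreNetwork", function(x) x@pitchUm)
#' @rdname pitchUm
#' @export
setMethod("pitchUm", "GroundTruth", function(x) x@pitchUm)

#' Voxel data accessor
#'
#' Returns the underlying 3D array: gray values for a `VoxelVolume`,
#' distances for a `DistanceMap`, the logical mask for an `RoiMask`.
#' @param x The object.
#' @return A 3D array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@values)
#' @rdname voxelData
#' @export
setMethod("voxelData", "DistanceMap", function(x) x@values)
#' @rdname voxelData
#' @export
setMethod("voxelData", "RoiMask", function(x) x@mask)

#' Label array accessor
#'
#' Per-voxel integer labels: phase codes for a `PhaseMap` or
#' `GroundTruth`, particle ids for an `OmParticleSet`, pore-region
#' labels for a `PoreNetwork`.
#' @param x The object.
#' @return A 3D integer array.
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname labelArray
#' @export
setMethod("labelArray", "PhaseMap", function(x) x@labels)
#' @rdname labelArray
#' @export
setMethod("labelArray", "OmParticleSet", function(x) x@ids)
#' @rdname labelArray
#' @export
setMethod("labelArray", "PoreNetwork", function(x) x@labels)
#' @rdname labelArray
#' @export
setMethod("labelArray", "GroundTruth", function(x) x@labels)

#' Bit depth of a volume
#' @param x A VoxelVolume.
#' @return 8 or 16.
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname bitDepth
#' @export
setMethod("bitDepth", "VoxelVolume", function(x) x@bitDepth)

#' Particle table of an OmParticleSet
#' @param x An OmParticleSet or GroundTruth.
#' @return data.frame with one row per particle.
#' @export
setGeneric("particleTable", function(x) standardGeneric("particleTable"))
#' @rdname particleTable
#' @export
setMethod("particleTable", "OmParticleSet", function(x) x@particles)
#' @rdname particleTable
#' @export
setMethod("particleTable", "GroundTruth", function(x) x@omParticles)

#' Region table of a PoreNetwork
#' @param x A PoreNetwork.
#' @return data.frame: id, voxels, volume_um3, esd_um, max_insphere_um.
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname regionTable
#' @export
setMethod("regionTable", "PoreNetwork", function(x) x@regions)

#' Neck table of a PoreNetwork
#' @param x A PoreNetwork.
#' @return data.frame: id_a, id_b, neck_um.
#' @export
setGeneric("neckTable", function(x) standardGeneric("neckTable"))
#' @rdname neckTable
#' @export
setMethod("neckTable", "PoreNetwork", function(x) x@necks)
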