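#' Conservative mineral threshold
#'
#' Selects the mineral matrix with a single gray-value threshold:
#' voxels with `value >= t` inside the ROI. The threshold is chosen
#' conservatively (high) by the caller so that only voxels containing
#' mineral material are selected; the mask is later subtracted from the
#' volume before OM segmentation.
#'
#' @param v A [VoxelVolume-class].
#' @param t Gray threshold (within the bit range).
#' @param roi Optional [RoiMask-class] or logical array.
#' @return Logical 3D array: the mineral mask.
#' @export
thresholdMineral <- function(v, t, roi = NULL) {
  stopifnot(is(v, "VoxelVolume"))
  if (t < 0 || t > 2^v@bitDepth - 1 + 1)
    stop("threshold outside the bit range")
  m <- .roi_array(roi, dim(v@values))
  v@values >= t & m
}

#' Dual-threshold (hysteresis) segmentation of added organic matter
#'
#' A voxel is OM iff its gray value lies in the weak range AND it is
#' connected, through weak-range voxels, to at least one voxel in the
#' strong range (the center of the OM gray-value distribution). The
#' mineral mask is removed from the volume beforehand, so OM is
#' segmented from the mineral-subtracted residual and can never overlap
#' mineral. Components smaller than `minSizeVoxels` are removed: added
#' particles are at least 500 um, so smaller components are
#' partial-volume or noise artifacts.
#'
#' @param v A [VoxelVolume-class].
#' @param weak Gray range `c(lo, hi)` selecting all of OM.
#' @param strong Gray range strictly inside `weak` selecting certain OM.
#' @param mineralMask Logical array from [thresholdMineral()] (optional).
#' @param roi Optional [RoiMask-class] or logical array.
#' @param minSizeVoxels Minimum component size; default is the voxel
#'   count of a 250 um diameter sphere at the volume's pitch (half the
#'   smallest sieved particle size).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return An [OmParticleSet-class].
#' @export
segmentOmDual <- function(v, weak, strong, mineralMask = NULL, roi = NULL,
                          minSizeVoxels = NULL, connectivity = 26L) {
  stopifnot(is(v, "VoxelVolume"), length(weak) == 2L, length(strong) == 2L)
  if (strong[1] < weak[1] || strong[2] > weak[2])
    stop("strong range must lie within the weak range")
  connectivity <- .check_conn(connectivity)
  d <- .as_dim3(v@values)
  if (is.null(minSizeVoxels))
    minSizeVoxels <- round(4 / 3 * pi * (125 / v@pitchUm)^3)
  m <- .roi_array(roi, d)
  if (!is.null(mineralMask)) m <- m & !mineralMask
  weakMask <- v@values >= weak[1] & v@values <= weak[2] & m
  strongMask <- v@values >= strong[1] & v@values <= strong[2] & m
  if (!any(strongMask)) {
    warning("empty strong set: no OM segmented")
    omMask <- array(FALSE, d)
  } else {
    omMask <- array(cpp_hysteresis(as.vector(weakMask), as.vector(strongMask),
                                   d, connectivity), d)
  }
  ids <- .label3d(omMask, connectivity)
  if (max(ids) > 0L && minSizeVoxels > 1) {
    sizes <- tabulate(ids[ids > 0L], nbins = max(ids))
    keep <- which(sizes >= minSizeVoxels)
    remap <- integer(max(ids))
    remap[keep] <- seq_along(keep)
    pos <- ids > 0L
    ids[pos] <- remap[ids[pos]]
  }
  new("OmParticleSet", ids = ids,
      particles = .om_particle_table(ids, v@pitchUm),
      pitchUm = v@pitchUm, connectivity = connectivity)
}

#' Segment the pore space
#'
#' Applies a single conservative threshold selecting pore space and OM
#' together (`value <= t`, avoiding any mineral-phase voxels), then
#' subtracts the previously segmented OM volume, leaving pore space
#' only.
#'
#' @param v A [VoxelVolume-class].
#' @param t Gray threshold: pore+OM voxels have `value <= t`.
#' @param om An [OmParticleSet-class] (or NULL if no OM present).
#' @param roi Optional [RoiMask-class] or logical array.
#' @return Logical 3D array: the pore mask.
#' @export
segmentPores <- function(v, t, om = NULL, roi = NULL) {
  stopifnot(is(v, "VoxelVolume"))
  m <- .roi_array(roi, dim(v@values))
  pore <- v@values <= t & m
  if (!is.null(om)) pore <- pore & labelArray(om) == 0L
  pore
}

#' Assemble a three-phase map
#'
#' Combines the mineral, pore and OM masks into one [PhaseMap-class].
#' Voxels inside the ROI claimed by no mask (a possible gray band
#' between the conservative thresholds) are counted as mineral by
#' default, or kept as an explicit `unclassified` label.
#'
#' @param mineral,pore Logical arrays.
#' @param om An [OmParticleSet-class] or 3D integer/logical array.
#' @param pitchUm Voxel pitch (micrometers).
#' @param roi Optional [RoiMask-class] or logical array.
#' @param thresholds Named list recorded for provenance.
#' @param unclassified `"mineral"` (default) or `"keep"`.
#' @return A [PhaseMap-class].
#' @export
assemblePhaseMap <- function(mineral, pore, om, pitchUm, roi = NULL,
                             thresholds = list(),
                             unclassified = c("mineral", "keep")) {
  unclassified <- match.arg(unclassified)
  d <- .as_dim3(mineral)
  m <- .roi_array(roi, d)
  omMask <- if (is(om, "OmParticleSet")) labelArray(om) > 0L else om > 0L
  fill <- if (unclassified == "mineral") .PHASE[["mineral"]] else .PHASE[["unclassified"]]
  labels <- array(.PHASE[["outside"]], d)
  labels[m] <- fill
  labels[m & mineral] <- .PHASE[["mineral"]]
  labels[m & pore & !omMask] <- .PHASE[["pore"]]
  labels[m & omMask] <- .PHASE[["om"]]
  storage.mode(labels) <- "integer"
  new("PhaseMap", labels = labels, pitchUm = pitchUm,
      thresholds = thresholds)
}

#' Three-phase segmentation of a core volume
#'
#' The full scheme: conservative mineral threshold, dual-threshold OM
#' segmentation of the mineral-subtracted residual, pore space by
#' subtraction of OM from the conservative pore+OM mask.
#'
#' @param v A [VoxelVolume-class].
#' @param tMineral Mineral threshold (`>=`).
#' @param weak,strong OM gray ranges (see [segmentOmDual()]).
#' @param tPoreOm Pore+OM threshold (`<=`).
#' @param roi Optional [RoiMask-class] or logical array.
#' @param minSizeVoxels,connectivity Passed to [segmentOmDual()].
#' @param unclassified Passed to [assemblePhaseMap()].
#' @return List: `phase` ([PhaseMap-class]) and `om`
#'   ([OmParticleSet-class]).
#' @export
segmentCore <- function(v, tMineral, weak, strong, tPoreOm, roi = NULL,
                        minSizeVoxels = NULL, connectivity = 26L,
                        unclassified = "mineral") {
  mineral <- thresholdMineral(v, tMineral, roi)
  om <- segmentOmDual(v, weak, strong, mineralMask = mineral, roi = roi,
                      minSizeVoxels = minSizeVoxels,
                      connectivity = connectivity)
  pore <- segmentPores(v, tPoreOm, om = om, roi = roi)
  phase <- assemblePhaseMap(mineral, pore, om, v@pitchUm, roi = roi,
                            thresholds = list(mineral = tMineral,
                                              weak = weak, strong = strong,
                                              pore_om = tPoreOm),
                            unclassified = unclassified)
  list(phase = phase, om = om)
}

#' CT-visible porosity
#'
#' Pore volume as a percentage of the ROI volume; "CT-visible" because
#' only pores wider than the voxel pitch are resolved.
#'
#' @param phase A [PhaseMap-class], [GroundTruth-class] or logical pore
#'   mask.
#' @param roi Optional [RoiMask-class] or logical array; for a PhaseMap
#'   the default ROI is every inside (non-`outside`) voxel.
#' @return Porosity in percent.
#' @export
ctVisiblePorosity <- function(phase, roi = NULL) {
  if (is(phase, "PhaseMap") || is(phase, "GroundTruth")) {
    labels <- labelArray(phase)
    pore <- labels == .PHASE[["pore"]]
    m <- if (is.null(roi)) labels != .PHASE[["outside"]]
         else .roi_array(roi, dim(labels))
  } else {
    pore <- phase
    m <- .roi_array(roi, dim(pore))
  }
  nRoi <- sum(m)
  if (nRoi == 0) stop("empty ROI: porosity undefined")
  100 * sum(pore & m) / nRoi
}

#' Bimodal valley threshold helper
#'
#' Suggests a threshold at the deepest histogram valley between the two
#' dominant gray modes. Provided as a starting point for manual
#' threshold choice; it is never applied automatically.
#'
#' @param v A [VoxelVolume-class].
#' @param smooth Half-width (gray levels) of the moving-average
#'   smoothing applied to the histogram.
#' @return Suggested gray threshold.
#' @export
autoThresholdValley <- function(v, smooth = 3L) {
  stopifnot(is(v, "VoxelVolume"))
  maxval <- 2^v@bitDepth - 1
  h <- tabulate(as.vector(v@values) + 1L, nbins = maxval + 1)
  k <- 2L * smooth + 1L
  hs <- as.numeric(stats::filter(h, rep(1 / k, k), sides = 2))
  hs[is.na(hs)] <- h[is.na(hs)]
  n <- length(hs)
  isMax <- which(hs > c(-Inf, hs[-n]) & hs >= c(hs[-1], -Inf))
  if (length(isMax) < 2L) stop("no bimodal structure found")
  top2 <- sort(isMax[order(hs[isMax], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(hs[top2[1]:top2[2]]) - 1L
  valley - 1 # gray values are 0-based
}
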