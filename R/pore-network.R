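#' Euclidean distance map of the pore space
#'
#' Exact Euclidean distance (micrometers, voxel center to voxel center)
#' from each pore voxel to the nearest non-pore voxel. The volume
#' boundary is treated as solid, so pores touching the boundary are
#' bounded there. Non-pore voxels have distance zero.
#'
#' @param pore A [PhaseMap-class], [GroundTruth-class] or logical pore
#'   mask.
#' @param pitchUm Voxel pitch in micrometers (taken from `pore` when it
#'   carries one).
#' @return A [DistanceMap-class].
#' @export
distanceMap <- function(pore, pitchUm = NULL) {
  if (is(pore, "PhaseMap") || is(pore, "GroundTruth")) {
    if (is.null(pitchUm)) pitchUm <- pitchUm(pore)
    pore <- labelArray(pore) == .PHASE[["pore"]]
  }
  if (is.null(pitchUm)) stop("pitchUm required for a bare mask")
  d <- .edt_vox(pore, borderSolid = TRUE) * pitchUm
  new("DistanceMap", values = d, pitchUm = pitchUm)
}

#' Watershed separation of the pore space
#'
#' Markers are the regional maxima of the distance map after h-maxima
#' suppression of maxima shallower than `hMinUm` (default one voxel
#' pitch, removing plateau and noise maxima without merging genuine
#' pores). The watershed then floods the distance map from the markers,
#' highest distance first, restricted to the pore mask; ties are
#' resolved first-in-first-out so the labeling is deterministic.
#'
#' @param d A [DistanceMap-class] from [distanceMap()].
#' @param pore Logical pore mask (or PhaseMap/GroundTruth).
#' @param hMinUm Marker suppression depth, micrometers.
#' @param connectivity Pore connectivity for flooding (default 26).
#' @return A [PoreNetwork-class] with labels and per-region statistics;
#'   necks are filled by [neckDiameters()] (or use [poreNetwork()]).
#' @export
watershedSeparate <- function(d, pore, hMinUm = NULL, connectivity = 26L) {
  stopifnot(is(d, "DistanceMap"))
  if (is(pore, "PhaseMap") || is(pore, "GroundTruth"))
    pore <- labelArray(pore) == .PHASE[["pore"]]
  connectivity <- .check_conn(connectivity)
  if (is.null(hMinUm)) hMinUm <- d@pitchUm
  dm <- .as_dim3(d@values)
  if (!any(pore)) {
    return(new("PoreNetwork", labels = array(0L, dm),
               regions = .region_table(array(0L, dm), d),
               necks = .empty_necks(), pitchUm = d@pitchUm))
  }
  dv <- as.vector(d@values)
  dv[!pore] <- 0
  if (hMinUm > 0) {
    rec <- cpp_reconstruct(pmax(dv - hMinUm, 0), dv, dm, connectivity)
  } else rec <- dv
  markers <- cpp_regional_maxima(rec, as.vector(pore), dm, connectivity)
  labels <- cpp_watershed(dv, markers, as.vector(pore), dm, connectivity)
  labels <- array(labels, dm)
  new("PoreNetwork", labels = labels, regions = .region_table(labels, d),
      necks = .empty_necks(), pitchUm = d@pitchUm)
}

.empty_necks <- function() {
  data.frame(id_a = integer(), id_b = integer(), neck_um = numeric())
}

.region_table <- function(labels, d) {
  K <- max(labels)
  pitch <- d@pitchUm
  if (K == 0L)
    return(data.frame(id = integer(), voxels = integer(),
                      volume_um3 = numeric(), esd_um = numeric(),
                      max_insphere_um = numeric()))
  st <- cpp_region_stats(as.vector(labels), as.vector(d@values),
                         .as_dim3(labels))
  voxels <- as.integer(st$count)
  data.frame(id = seq_len(K), voxels = voxels,
             volume_um3 = voxels * pitch^3,
             esd_um = equivalentSphereDiameter(voxels, pitch),
             max_insphere_um = 2 * st$max_aux)
}

#' Neck diameters between adjacent pore regions
#'
#' For each pair of watershed regions sharing a face-adjacent boundary,
#' the neck diameter is twice the maximum distance-map value over the
#' boundary voxels: the diameter of the maximum inscribed sphere in the
#' neck.
#'
#' @param net A [PoreNetwork-class].
#' @param d The [DistanceMap-class] used for the separation.
#' @return data.frame: `id_a`, `id_b`, `neck_um` (one row per adjacent
#'   pair; no rows for isolated regions).
#' @export
neckDiameters <- function(net, d) {
  stopifnot(is(net, "PoreNetwork"), is(d, "DistanceMap"))
  tab <- cpp_neck_table(as.vector(net@labels), as.vector(d@values),
                        .as_dim3(net@labels))
  data.frame(id_a = tab$id_a, id_b = tab$id_b,
             neck_um = 2 * tab$max_dist)
}

#' Complete pore-network extraction
#'
#' Distance map, watershed separation and neck measurement in one call.
#'
#' @inheritParams watershedSeparate
#' @param pore Logical pore mask, [PhaseMap-class] or
#'   [GroundTruth-class].
#' @param pitchUm Voxel pitch (taken from `pore` when it carries one).
#' @return A [PoreNetwork-class] with necks filled in.
#' @export
#' @examples
#' np <- makeNeckPhantom(150, 75, 100, pitchUm = 10)
#' net <- poreNetwork(np$truth)
#' neckTable(net)
poreNetwork <- function(pore, pitchUm = NULL, hMinUm = NULL,
                        connectivity = 26L) {
  d <- distanceMap(pore, pitchUm)
  if (is(pore, "PhaseMap") || is(pore, "GroundTruth"))
    pore <- labelArray(pore) == .PHASE[["pore"]]
  net <- watershedSeparate(d, pore, hMinUm, connectivity)
  net@necks <- neckDiameters(net, d)
  net
}

#' Pore network from an existing label volume
#'
#' Builds a [PoreNetwork-class] from externally supplied region labels
#' (e.g. a constructed fixture or a labeling imported from other
#' software), computing region statistics and necks from the label
#' geometry.
#'
#' @param labels 3D integer array of pore-region labels (0 = non-pore).
#' @param pitchUm Voxel pitch in micrometers.
#' @return A [PoreNetwork-class].
#' @export
poreNetworkFromLabels <- function(labels, pitchUm) {
  storage.mode(labels) <- "integer"
  d <- distanceMap(labels > 0L, pitchUm)
  net <- new("PoreNetwork", labels = labels,
             regions = .region_table(labels, d), necks = .empty_necks(),
             pitchUm = pitchUm)
  net@necks <- neckDiameters(net, d)
  net
}

#' Pore-neck-size distribution (PND)
#'
#' Bins the pore volume into the seven fixed neck-diameter classes
#' 10-30, 30-60, 60-90, 90-150, 150-250, 250-350 and >350 um. Each
#' region is assigned the class of its governing neck diameter: by
#' default the largest neck connecting it to the rest of the network
#' (best-access convention; `rule = "smallest"` uses the narrowest
#' neck). Isolated regions and the single largest region are governed
#' by their own maximum-inscribed-sphere diameter. Diameters below
#' 10 um (possible for single-voxel boundary regions) are counted in
#' the lowest class so that volume is conserved.
#'
#' @param net A [PoreNetwork-class] with necks computed.
#' @param rule `"largest"` (default) or `"smallest"` governing neck.
#' @return data.frame: class label, lower/upper edge (um), volume_um3,
#'   pct of classified pore volume.
#' @export
pnd <- function(net, rule = c("largest", "smallest")) {
  rule <- match.arg(rule)
  stopifnot(is(net, "PoreNetwork"))
  edges <- c(10, 30, 60, 90, 150, 250, 350)
  lab <- c("10-30", "30-60", "60-90", "90-150", "150-250", "250-350",
           ">350")
  reg <- net@regions
  out <- data.frame(class = lab, lo_um = edges,
                    hi_um = c(edges[-1], Inf),
                    volume_um3 = numeric(7), pct = numeric(7))
  if (nrow(reg) == 0L) return(out)
  necks <- net@necks
  gov <- reg$max_insphere_um
  if (nrow(necks)) {
    agg <- if (rule == "largest") max else min
    ids <- c(necks$id_a, necks$id_b)
    nd <- rep(necks$neck_um, 2)
    gv <- tapply(nd, ids, agg)
    hit <- match(reg$id, as.integer(names(gv)))
    gov[!is.na(hit)] <- gv[hit[!is.na(hit)]]
  }
  largest <- reg$id[which.max(reg$voxels)]
  gov[reg$id == largest] <- reg$max_insphere_um[reg$id == largest]
  cls <- findInterval(gov, edges[-1]) + 1L
  for (k in seq_len(7))
    out$volume_um3[k] <- sum(reg$volume_um3[cls == k])
  tot <- sum(out$volume_um3)
  if (tot > 0) out$pct <- 100 * out$volume_um3 / tot
  out
}

#' Equivalent sphere diameter
#'
#' Diameter of the sphere with the same volume as a region of
#' `volumeVoxels` voxels: `(6 V / pi)^(1/3)` with
#' `V = volumeVoxels * pitchUm^3`.
#'
#' @param volumeVoxels Voxel count(s), >= 1.
#' @param pitchUm Voxel pitch in micrometers.
#' @return Diameter(s) in micrometers.
#' @export
#' @examples
#' equivalentSphereDiameter(1, 10) # (6000/pi)^(1/3)
equivalentSphereDiameter <- function(volumeVoxels, pitchUm) {
  stopifnot(all(volumeVoxels >= 1), pitchUm > 0)
  (6 * volumeVoxels * pitchUm^3 / pi)^(1 / 3)
}

#' CT-invisible porosity from bulk density
#'
#' Pore volume below the CT resolution, as total porosity
#' (`1 - BD/PD`) minus the CT-visible porosity.
#'
#' @param bulkDensity Bulk density, g cm^-3.
#' @param ctVisiblePct CT-visible porosity, percent.
#' @param particleDensity Particle density, g cm^-3 (default 2.65).
#' @return Invisible porosity in percent.
#' @export
invisiblePorosity <- function(bulkDensity, ctVisiblePct,
                              particleDensity = 2.65) {
  stopifnot(bulkDensity > 0, bulkDensity < particleDensity)
  100 * (1 - bulkDensity / particleDensity) - ctVisiblePct
}
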