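#' @include phantom-spec.R
NULL

.MAX_PLACEMENT_ATTEMPTS <- 1e6

# gray rendering of a truth label array; clips to 8-bit range
.render_truth <- function(labels, grayLevels, pitchUm) {
  lv <- c(0, grayLevels$mineral, grayLevels$pore, grayLevels$om)
  vals <- lv[as.vector(labels) + 1]
  if (grayLevels$noiseSd > 0)
    vals <- vals + rnorm(length(vals), 0, grayLevels$noiseSd)
  vals <- round(pmin(pmax(vals, 0), 255))
  VoxelVolume(array(vals, dim(labels)), pitchUm, 8L)
}

# OM particle table from an id array
.om_particle_table <- function(omIds, pitchUm) {
  d <- .as_dim3(omIds)
  K <- max(omIds)
  if (K == 0L)
    return(data.frame(id = integer(), voxels = integer(),
                      centroid_y = numeric(), centroid_x = numeric(),
                      centroid_z = numeric(),
                      bbox_y0 = integer(), bbox_y1 = integer(),
                      bbox_x0 = integer(), bbox_x1 = integer(),
                      bbox_z0 = integer(), bbox_z1 = integer()))
  st <- cpp_region_stats(as.vector(omIds), numeric(0), d)
  cnt <- st$count
  data.frame(id = seq_len(K), voxels = as.integer(cnt),
             centroid_y = st$sum1 / cnt, centroid_x = st$sum2 / cnt,
             centroid_z = st$sum3 / cnt,
             bbox_y0 = st$lo1, bbox_y1 = st$hi1,
             bbox_x0 = st$lo2, bbox_x1 = st$hi2,
             bbox_z0 = st$lo3, bbox_z1 = st$hi3)
}

# place nWanted ellipsoids into omIds (non-overlap with existing OM),
# drawing candidates from the current RNG stream; errors if impossible
.place_om <- function(omIds, spec, nWanted, maxAttempts = .MAX_PLACEMENT_ATTEMPTS) {
  d <- .as_dim3(omIds)
  if (nWanted == 0L) return(omIds)
  axUm <- spec@omSizeRangeUm
  firstId <- max(omIds) + 1L
  placed <- 0L
  attempts <- 0
  batch <- max(64L, nWanted * 4L)
  while (placed < nWanted && attempts < maxAttempts) {
    nb <- min(batch, ceiling(maxAttempts - attempts))
    centers <- cbind(runif(nb, 0, d[1] - 1), runif(nb, 0, d[2] - 1),
                     runif(nb, 0, d[3] - 1))
    semi <- matrix(runif(3 * nb, axUm[1], axUm[2]) / 2 / spec@pitchUm,
                   ncol = 3)
    res <- cpp_place_ellipsoids(as.vector(omIds), d, centers, semi,
                                nWanted - placed, firstId + placed)
    omIds <- array(res$om, d)
    placed <- placed + res$n_placed
    attempts <- attempts + nb
  }
  if (placed < nWanted)
    stop(sprintf("could not place requested OM particles: %d of %d placed after %d attempts",
                 placed, nWanted, as.integer(attempts)))
  omIds
}

# sphere packing for the resolvable grain fractions + sub-resolution
# matrix fill; returns list(labels, porosity). omIds blocks placement.
.pack_grains <- function(spec, omIds, maxAttempts = .MAX_PLACEMENT_ATTEMPTS) {
  d <- spec@shape
  n <- prod(as.numeric(d))
  omMask <- omIds > 0L
  nOm <- sum(omMask)
  navail <- n - nOm
  solidTarget <- round((1 - spec@targetPorosity) * navail)

  gf <- spec@grainSizeFractions
  isMatrix <- gf$d_min_um < 2 * spec@pitchUm
  occ <- array(0L, d)
  attempts <- 0
  placedTotal <- 0

  sph <- gf[!isMatrix, , drop = FALSE]
  if (nrow(sph)) sph <- sph[order(-sph$d_max_um), , drop = FALSE]
  sphereTarget <- 0
  for (f in seq_len(nrow(sph))) {
    target <- sph$fraction[f] * navail
    if (target < 1) next
    sphereTarget <- sphereTarget + target
    rmin <- sph$d_min_um[f] / 2 / spec@pitchUm
    minVol <- max(1, 4 / 3 * pi * rmin^3)
    placedFrac <- 0
    emptyBatches <- 0L
    while (placedFrac + 0.9 * minVol < target &&
           emptyBatches < 10L && attempts < maxAttempts) {
      nb <- 2000L
      centers <- cbind(runif(nb, 0, d[1] - 1), runif(nb, 0, d[2] - 1),
                       runif(nb, 0, d[3] - 1))
      radii <- runif(nb, sph$d_min_um[f], sph$d_max_um[f]) / 2 / spec@pitchUm
      res <- cpp_place_spheres(as.vector(occ), as.vector(omMask), d,
                               centers, radii, 1L, target - placedFrac)
      occ <- array(res$occ, d)
      placedFrac <- placedFrac + res$added_voxels
      attempts <- attempts + res$n_tried
      emptyBatches <- if (res$n_accepted == 0L) emptyBatches + 1L else 0L
    }
    placedTotal <- placedTotal + placedFrac
  }

  # grain placement that jammed (or ran out of attempts) short of the
  # sphere target can only be carried by a sub-resolution matrix
  # fraction; without one the target porosity is unreachable
  shortfall <- sphereTarget - placedTotal
  if (!any(isMatrix) && shortfall > 0.02 * navail)
    stop(sprintf("unreachable target porosity %.3f: sphere packing jammed at solid fraction %.3f after %d attempts",
                 spec@targetPorosity, placedTotal / navail,
                 as.integer(attempts)))

  # sub-resolution matrix: convert the void voxels nearest to resolved
  # solids (grains or OM) into mineral until the solid target is met
  need <- solidTarget - sum(occ > 0L)
  if (need > 0 && !any(isMatrix) && need > 0.02 * navail)
    stop(sprintf("unreachable target porosity %.3f: no sub-resolution fraction to fill remaining %.0f voxels",
                 spec@targetPorosity, need))
  if (need > 0) {
    void <- occ == 0L & !omMask
    anySolid <- occ > 0L | omMask
    if (any(anySolid)) {
      dist <- .edt_vox(!anySolid, borderSolid = FALSE)
    } else {
      dist <- array(0, d) # degenerate: no resolved solid at all
    }
    dv <- dist[void]
    idx <- which(void)
    if (need >= length(idx)) {
      occ[idx] <- 2L
    } else {
      thr <- sort(dv, partial = need)[need]
      take <- idx[dv < thr]
      remaining <- need - length(take)
      ties <- idx[dv == thr]
      occ[c(take, ties[seq_len(remaining)])] <- 2L
    }
  }

  labels <- array(.PHASE[["pore"]], d)
  labels[occ > 0L] <- .PHASE[["mineral"]]
  labels[omMask] <- .PHASE[["om"]]
  porosity <- sum(labels == .PHASE[["pore"]]) / navail
  list(labels = labels, porosity = porosity)
}

.make_truth <- function(labels, omIds, spec, info = list()) {
  navail <- sum(labels != .PHASE[["om"]])
  new("GroundTruth", labels = labels, omIds = omIds,
      omParticles = .om_particle_table(omIds, spec@pitchUm),
      pitchUm = spec@pitchUm,
      truePorosity = sum(labels == .PHASE[["pore"]]) / navail,
      info = info)
}

#' Generate a mineral grain pack with known ground truth
#'
#' Random sequential addition of non-overlapping spheres drawn from the
#' resolvable grain-size fractions until each fraction's solid volume is
#' reached; sub-resolution fractions (lower diameter bound below two
#' pitches) are added as a mineral matrix coating the void voxels
#' nearest to resolved surfaces, until the total solid fraction matches
#' `1 - targetPorosity` exactly (up to distance ties). Remaining voxels
#' are pore. Grayscale is rendered from the spec's gray levels plus
#' additive Gaussian noise.
#'
#' @param spec A [PhantomSpec-class]; each axis must be >= 64 voxels.
#' @param exclude Optional 3D integer array of OM particle ids that
#'   grains must not overlap (as produced by [embedOmParticles()] or
#'   [generatePhantom()]).
#' @return List with elements `volume` ([VoxelVolume-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
#' @examples
#' p <- generatePhantom(phantomSpec(shape = 64, nOmParticles = 2,
#'                                  omSizeRangeUm = c(120, 200), seed = 3))
#' p$truth
generateGrainPack <- function(spec, exclude = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (any(spec@shape < 64L))
    stop("grain packs need at least 64 voxels per axis")
  set.seed(spec@seed)
  omIds <- if (is.null(exclude)) array(0L, spec@shape) else exclude
  pack <- .pack_grains(spec, omIds)
  truth <- .make_truth(pack$labels, omIds, spec)
  volume <- .render_truth(pack$labels, spec@grayLevels, spec@pitchUm)
  list(volume = volume, truth = truth)
}

#' Embed organic-matter particles into an existing phantom
#'
#' Places `nOmParticles` axis-aligned ellipsoids with per-axis diameters
#' drawn from `omSizeRangeUm`, without mutual overlap, replacing
#' whatever phase they cover. OM is rendered at a gray level strictly
#' between the pore and mineral means. Fails (naming the achieved
#' count) if the requested number cannot be placed.
#'
#' @param volume The [VoxelVolume-class] of the pack (re-rendered).
#' @param truth The matching [GroundTruth-class].
#' @param spec The [PhantomSpec-class] (fields `nOmParticles`,
#'   `omSizeRangeUm`, `grayLevels`, `seed` are used).
#' @return List with updated `volume` and `truth`.
#' @export
embedOmParticles <- function(volume, truth, spec) {
  stopifnot(is(truth, "GroundTruth"), is(spec, "PhantomSpec"))
  if (spec@nOmParticles == 0L) return(list(volume = volume, truth = truth))
  set.seed(spec@seed + 1L)
  omIds <- .place_om(truth@omIds, spec, spec@nOmParticles)
  labels <- truth@labels
  labels[omIds > 0L] <- .PHASE[["om"]]
  truth2 <- .make_truth(labels, omIds, spec, truth@info)
  volume2 <- .render_truth(labels, spec@grayLevels, spec@pitchUm)
  list(volume = volume2, truth = truth2)
}

#' Generate a complete soil-core phantom (OM-aware packing)
#'
#' Full phantom pipeline: OM particles are placed first, then mineral
#' grains are packed with the OM volume as an exclusion region, then
#' the sub-resolution matrix fill brings the solid fraction to target.
#' Packing around (rather than through) the OM particles reproduces the
#' structural boundary layer that makes local porosity around OM depend
#' on the grain mixture: coarse mixtures leave wider voids next to the
#' particles, fines-rich mixtures coat them.
#'
#' @param spec A [PhantomSpec-class].
#' @return List with `volume` ([VoxelVolume-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (any(spec@shape < 64L))
    stop("phantoms need at least 64 voxels per axis")
  set.seed(spec@seed)
  omIds <- .place_om(array(0L, spec@shape), spec, spec@nOmParticles)
  pack <- .pack_grains(spec, omIds)
  truth <- .make_truth(pack$labels, omIds, spec)
  volume <- .render_truth(pack$labels, spec@grayLevels, spec@pitchUm)
  list(volume = volume, truth = truth)
}

#' Two-sphere neck phantom with analytic ground truth
#'
#' Binary-phase fixture for the pore-network pipeline: two spherical
#' pores joined by a cylindrical channel of known diameter, surrounded
#' by mineral. The truth records the analytic neck diameter and sphere
#' radius, so watershed separation and neck measurement can be checked
#' against construction.
#'
#' @param sphereRadiusUm Radius of each spherical pore, micrometers.
#' @param neckDiameterUm Cylinder (neck) diameter, micrometers; must be
#'   below `2 * sphereRadiusUm` and at least two voxel pitches.
#' @param neckLengthUm Channel length between the sphere surfaces;
#'   0 gives two tangent spheres (a contact neck).
#' @param pitchUm Voxel pitch, micrometers.
#' @param grayLevels Gray rendering (defaults as in [phantomSpec()]).
#' @return List with `volume` and `truth`; `truth@info` holds
#'   `neck_diameter_um`, `sphere_radius_um`, `neck_length_um`.
#' @export
#' @examples
#' np <- makeNeckPhantom(150, 40, 100, pitchUm = 10)
#' np$truth@info$neck_diameter_um
makeNeckPhantom <- function(sphereRadiusUm, neckDiameterUm, neckLengthUm,
                            pitchUm,
                            grayLevels = list(pore = 40, om = 110,
                                              mineral = 200, noiseSd = 0)) {
  if (neckDiameterUm >= 2 * sphereRadiusUm)
    stop("neck diameter must be smaller than the sphere diameter")
  if (neckDiameterUm < 2 * pitchUm)
    stop("neck not representable at this pitch (below 2 voxels)")
  R <- sphereRadiusUm / pitchUm
  rn <- neckDiameterUm / 2 / pitchUm
  L <- neckLengthUm / pitchUm
  pad <- 3L
  nlat <- 2L * ceiling(R) + 2L * pad + 1L
  c1z <- pad + ceiling(R)
  c2z <- c1z + round(2 * R + L)
  nz <- c2z + ceiling(R) + pad + 1L
  if (min(nlat, nz) < 3L) stop("phantom dimensions below 3 voxels")
  d <- c(nlat, nlat, as.integer(nz))
  clat <- (nlat - 1) / 2
  yy <- (seq_len(d[1]) - 1) - clat
  xx <- (seq_len(d[2]) - 1) - clat
  zz <- seq_len(d[3]) - 1
  lat2 <- outer(yy^2, xx^2, "+")
  pore <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    z <- zz[k]
    sl <- lat2 + (z - c1z)^2 <= R^2 | lat2 + (z - c2z)^2 <= R^2
    if (z >= c1z && z <= c2z) sl <- sl | lat2 <= rn^2
    pore[, , k] <- sl
  }
  labels <- array(.PHASE[["mineral"]], d)
  labels[pore] <- .PHASE[["pore"]]
  truth <- new("GroundTruth", labels = labels, omIds = array(0L, d),
               omParticles = .om_particle_table(array(0L, d), pitchUm),
               pitchUm = pitchUm, truePorosity = mean(pore),
               info = list(neck_diameter_um = neckDiameterUm,
                           sphere_radius_um = sphereRadiusUm,
                           neck_length_um = neckLengthUm,
                           centers_z = c(c1z, c2z)))
  volume <- .render_truth(labels, grayLevels, pitchUm)
  list(volume = volume, truth = truth)
}
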