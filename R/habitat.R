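#' Build the local-porosity shell around one OM particle
#'
#' The shell is the Euclidean dilation of the particle by `radiusUm`
#' (center-to-center distances), minus the particle itself, minus
#' voxels of other OM particles, minus voxels outside the ROI. Shells
#' of neighboring particles may overlap: each particle is evaluated
#' independently. A shell truncated by the grid or the ROI is flagged
#' as clipped.
#'
#' @param om An [OmParticleSet-class] (or a [GroundTruth-class] whose
#'   `omIds` are used).
#' @param particleId Id of the particle.
#' @param radiusUm Shell radius in micrometers (default 350, the
#'   distance at which the between-particle variance of local porosity
#'   stabilizes; see [shellRadiusSweep()]).
#' @param roi Optional [RoiMask-class] or logical array.
#' @return A [HabitatShell-class].
#' @export
buildShell <- function(om, particleId, radiusUm = 350, roi = NULL) {
  omIds <- if (is(om, "GroundTruth")) om@omIds else labelArray(om)
  pitch <- pitchUm(om)
  if (radiusUm < pitch) stop("shell radius must be at least one pitch")
  d <- .as_dim3(omIds)
  rvox <- radiusUm / pitch
  sel <- which(omIds == particleId, arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("no such particle: ", particleId)
  pad <- ceiling(rvox) + 1L
  lo <- pmax(apply(sel, 2, min) - pad, 1L)
  hi <- pmin(apply(sel, 2, max) + pad, d)
  clippedGrid <- any(apply(sel, 2, min) - pad < 1L) ||
    any(apply(sel, 2, max) + pad > d)
  sub <- omIds[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dist <- .edt_vox(sub != particleId, borderSolid = FALSE)
  cand <- dist > 0 & dist <= rvox
  cand[sub != 0L] <- FALSE # other OM particles are not shell volume
  m <- .roi_array(roi, d)
  msub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  clippedRoi <- any(cand & !msub)
  cand <- cand & msub
  idx <- which(cand, arr.ind = TRUE)
  lin <- (idx[, 1] + lo[1] - 1L) +
    as.integer(d[1]) * ((idx[, 2] + lo[2] - 2L) +
                          as.integer(d[2]) * (idx[, 3] + lo[3] - 2L))
  new("HabitatShell", particleId = as.integer(particleId),
      voxels = as.integer(lin), dim = d, radiusUm = radiusUm,
      pitchUm = pitch, clipped = clippedGrid || clippedRoi)
}

#' Local porosity inside a shell
#'
#' Pore voxels as a percentage of the shell voxels. The denominator is
#' the full shell (mineral + pore), consistent with bulk CT-visible
#' porosity; OM voxels are excluded from the shell by construction.
#'
#' @param shell A [HabitatShell-class].
#' @param phase A [PhaseMap-class], [GroundTruth-class] or logical pore
#'   mask.
#' @return Local porosity in percent.
#' @export
localPorosity <- function(shell, phase) {
  stopifnot(is(shell, "HabitatShell"))
  if (length(shell@voxels) == 0L) stop("empty shell: porosity undefined")
  pore <- if (is(phase, "PhaseMap") || is(phase, "GroundTruth"))
    labelArray(phase) == .PHASE[["pore"]] else phase
  100 * sum(pore[shell@voxels]) / length(shell@voxels)
}

#' Connectivity of shell pore space to large bulk pores
#'
#' "Local pores" are the watershed regions intersecting the shell. A
#' local pore counts as connected if a path in the region-adjacency
#' graph links it to a region with equivalent sphere diameter above
#' `esdCutoffUm` that extends outside the shell (or if it is itself
#' such a region). The returned fraction is the share of shell pore
#' volume belonging to connected local pores (`share = "count"` gives
#' the count share of local pores instead).
#'
#' @param shell A [HabitatShell-class].
#' @param net A [PoreNetwork-class] over the full ROI, with necks.
#' @param esdCutoffUm Large-pore cutoff, micrometers (default 300:
#'   pores of this equivalent diameter stay air-filled at the study's
#'   moisture levels).
#' @param share `"volume"` (default) or `"count"`.
#' @param path `"any"` (default: any-length path through the adjacency
#'   graph) or `"direct"` (the local pore must itself touch a large
#'   region or be one).
#' @return Fraction in `[0, 1]`, or `NA` if the shell holds no pore
#'   voxels (flagged via attribute `"undefined"`).
#' @export
connectivityFraction <- function(shell, net, esdCutoffUm = 300,
                                 share = c("volume", "count"),
                                 path = c("any", "direct")) {
  share <- match.arg(share)
  path <- match.arg(path)
  stopifnot(is(shell, "HabitatShell"), is(net, "PoreNetwork"))
  labs <- net@labels[shell@voxels]
  labs <- labs[labs > 0L]
  if (length(labs) == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  insideCounts <- table(labs)
  localIds <- as.integer(names(insideCounts))
  reg <- net@regions
  total <- reg$voxels[match(localIds, reg$id)]
  # large regions with at least one voxel outside the shell
  inAll <- integer(nrow(reg))
  inAll[match(localIds, reg$id)] <- as.integer(insideCounts)
  largeExt <- reg$id[reg$esd_um > esdCutoffUm & (reg$voxels - inAll) >= 1L]
  if (length(largeExt) == 0L) {
    connected <- rep(FALSE, length(localIds))
  } else if (path == "direct") {
    adj <- net@necks
    touches <- vapply(localIds, function(i) {
      i %in% largeExt ||
        any(adj$id_b[adj$id_a == i] %in% largeExt) ||
        any(adj$id_a[adj$id_b == i] %in% largeExt)
    }, logical(1))
    connected <- touches
  } else {
    g <- igraph::graph_from_data_frame(
      net@necks[, c("id_a", "id_b"), drop = FALSE], directed = FALSE,
      vertices = data.frame(name = reg$id))
    comp <- igraph::components(g)$membership
    largeComp <- unique(comp[as.character(largeExt)])
    connected <- localIds %in% largeExt |
      comp[as.character(localIds)] %in% largeComp
  }
  if (share == "volume")
    sum(insideCounts[connected]) / sum(insideCounts)
  else mean(connected)
}

#' Habitat shells and metrics for every OM particle in a core
#'
#' Builds the 350 um (by default) shell of each particle and evaluates
#' local porosity and, when a pore network is supplied, connectivity to
#' large bulk pores.
#'
#' @param om An [OmParticleSet-class] or [GroundTruth-class].
#' @param phase A [PhaseMap-class], [GroundTruth-class] or pore mask.
#' @param net Optional [PoreNetwork-class] (enables connectivity).
#' @param roi Optional ROI.
#' @param radiusUm Shell radius (micrometers).
#' @param esdCutoffUm Large-pore cutoff (micrometers).
#' @return data.frame: id, shell_voxels, local_porosity_pct,
#'   connectivity_fraction, connectivity_count_share, clipped.
#' @export
habitatShells <- function(om, phase, net = NULL, roi = NULL,
                          radiusUm = 350, esdCutoffUm = 300) {
  ids <- particleTable(om)$id
  rows <- lapply(ids, function(i) {
    sh <- buildShell(om, i, radiusUm, roi)
    lp <- if (length(sh@voxels)) localPorosity(sh, phase) else NA_real_
    cf <- ccs <- NA_real_
    if (!is.null(net) && length(sh@voxels)) {
      cf <- as.numeric(connectivityFraction(sh, net, esdCutoffUm))
      ccs <- as.numeric(connectivityFraction(sh, net, esdCutoffUm,
                                             share = "count"))
    }
    data.frame(id = i, shell_voxels = length(sh@voxels),
               local_porosity_pct = lp, connectivity_fraction = cf,
               connectivity_count_share = ccs, clipped = sh@clipped)
  })
  do.call(rbind, rows)
}

#' Per-core habitat summary
#'
#' @param shells data.frame from [habitatShells()].
#' @return One-row data.frame: particle count, mean/s.d./variance of
#'   local porosity (sample convention), mean connectivity.
#' @export
habitatSummary <- function(shells) {
  stopifnot(nrow(shells) >= 1L)
  lp <- shells$local_porosity_pct[!is.na(shells$local_porosity_pct)]
  data.frame(n_particles = nrow(shells),
             mean_local_porosity = mean(lp),
             sd_local_porosity = .sample_sd(lp),
             var_local_porosity = .sample_sd(lp)^2,
             mean_connectivity = mean(shells$connectivity_fraction,
                                      na.rm = TRUE))
}

#' Shell-radius selection diagnostic
#'
#' Local porosity mean and between-particle variance as a function of
#' the shell radius: the default 350 um radius is the smallest distance
#' at which this variance settles.
#'
#' @param om An [OmParticleSet-class] or [GroundTruth-class].
#' @param phase A [PhaseMap-class], [GroundTruth-class] or pore mask.
#' @param roi Optional ROI.
#' @param radiiUm Radii to evaluate (micrometers).
#' @return data.frame: radius_um, mean_local_porosity,
#'   var_local_porosity.
#' @export
shellRadiusSweep <- function(om, phase, roi = NULL,
                             radiiUm = seq(50, 500, by = 50)) {
  res <- lapply(radiiUm, function(r) {
    sh <- habitatShells(om, phase, net = NULL, roi = roi, radiusUm = r)
    lp <- sh$local_porosity_pct[!is.na(sh$local_porosity_pct)]
    data.frame(radius_um = r, mean_local_porosity = mean(lp),
               var_local_porosity = .sample_sd(lp)^2)
  })
  do.call(rbind, res)
}
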