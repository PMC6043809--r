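#' PhantomSpec: parameters of a synthetic soil-core phantom
#'
#' Describes a synthetic core: grid shape, voxel pitch, mineral grain
#' size fractions, target porosity, embedded organic-matter particles
#' and gray-level rendering. Grain fractions are expressed as volume
#' fractions of the *total* (non-OM) volume, so fractions plus target
#' porosity must not exceed 1. Fractions whose lower diameter bound is
#' below two voxel pitches are treated as a sub-resolution mineral
#' "matrix" (silt and clay aggregates below the CT resolution) and are
#' rendered as a coating on resolved surfaces rather than as grains.
#'
#' @slot shape Integer(3): voxels per axis (y, x, z).
#' @slot pitchUm Voxel pitch in micrometers.
#' @slot grainSizeFractions data.frame with columns `d_min_um`,
#'   `d_max_um`, `fraction`.
#' @slot targetPorosity Pore fraction of the non-OM volume, in `[0, 1]`.
#' @slot nOmParticles Number of OM particles to embed.
#' @slot omSizeRangeUm Diameter range (min, max) of OM particles, um.
#' @slot grayLevels List: `pore`, `om`, `mineral` mean gray values
#'   (8-bit) and `noiseSd` additive Gaussian noise s.d.
#' @slot seed RNG seed; identical spec + seed gives identical phantoms.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", pitchUm = "numeric",
                 grainSizeFractions = "data.frame",
                 targetPorosity = "numeric", nOmParticles = "integer",
                 omSizeRangeUm = "numeric", grayLevels = "list",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers")
  if (object@pitchUm <= 0) msg <- c(msg, "pitchUm must be positive")
  gf <- object@grainSizeFractions
  if (!all(c("d_min_um", "d_max_um", "fraction") %in% names(gf)))
    msg <- c(msg, "grainSizeFractions needs d_min_um, d_max_um, fraction")
  else {
    if (any(gf$fraction < 0) || any(gf$d_max_um <= 0) ||
        any(gf$d_min_um < 0) || any(gf$d_min_um >= gf$d_max_um))
      msg <- c(msg, "invalid grain size fraction rows")
    if (sum(gf$fraction) + object@targetPorosity > 1 + 1e-9)
      msg <- c(msg, "grain volume fractions + target porosity exceed 1")
  }
  if (object@targetPorosity < 0 || object@targetPorosity > 1)
    msg <- c(msg, "targetPorosity must be in [0, 1]")
  if (object@nOmParticles < 0) msg <- c(msg, "nOmParticles must be >= 0")
  if (length(object@omSizeRangeUm) != 2L ||
      object@omSizeRangeUm[1] <= 0 ||
      object@omSizeRangeUm[1] > object@omSizeRangeUm[2])
    msg <- c(msg, "omSizeRangeUm must be an increasing positive pair")
  gl <- object@grayLevels
  if (!all(c("pore", "om", "mineral", "noiseSd") %in% names(gl)))
    msg <- c(msg, "grayLevels needs pore, om, mineral, noiseSd")
  else if (!(gl$pore < gl$om && gl$om < gl$mineral))
    msg <- c(msg, "gray levels must satisfy pore < om < mineral")
  if (length(msg)) msg else TRUE
})

#' Grain-size fractions from a coarse:fine:silt+clay mixing ratio
#'
#' Converts a mass/volume mixing ratio of the three mineral fractions
#' (coarse sand 500-1000 um, fine sand 100-500 um, silt+clay < 53 um)
#' into volume fractions of the total core volume for a given target
#' porosity. The study's two structures use ratios 10:40:50 ("dense",
#' fines-rich) and 20:60:20 ("loose", fines-poor).
#'
#' @param ratio Numeric(3), relative shares of coarse sand, fine sand,
#'   silt+clay in the solid phase (need not sum to 1).
#' @param targetPorosity Pore fraction of the total volume.
#' @param sizesUm 3x2 matrix of diameter ranges (rows: coarse, fine,
#'   silt+clay).
#' @return data.frame usable as `grainSizeFractions` of a [phantomSpec()].
#' @export
#' @examples
#' grainFractions(c(10, 40, 50), targetPorosity = 0.45)
grainFractions <- function(ratio, targetPorosity,
                           sizesUm = rbind(coarse_sand = c(500, 1000),
                                           fine_sand = c(100, 500),
                                           silt_clay = c(0.1, 53))) {
  stopifnot(length(ratio) == 3L, all(ratio >= 0), sum(ratio) > 0)
  fr <- ratio / sum(ratio) * (1 - targetPorosity)
  data.frame(d_min_um = sizesUm[, 1], d_max_um = sizesUm[, 2],
             fraction = fr, row.names = rownames(sizesUm))
}

#' Construct a PhantomSpec
#'
#' Defaults describe a desk-scale analogue of the incubated cores: a
#' 256^3 grid at 10 um pitch, the fines-rich ("dense", 10:40:50) grain
#' mixture, porosity 0.45, and OM particles sieved to 500-1000 um.
#' `structure = "loose"` switches to the 20:60:20 fines-poor mixture.
#'
#' @param shape Voxels per axis, length 3 (or a single value, cubed).
#' @param pitchUm Voxel pitch, micrometers.
#' @param structure `"dense"` or `"loose"` preset for the grain mixture
#'   (ignored when `grainSizeFractions` is supplied).
#' @param grainSizeFractions Optional data.frame overriding the preset.
#' @param targetPorosity Pore fraction of the non-OM volume.
#' @param nOmParticles Number of OM particles.
#' @param omSizeRangeUm OM particle diameter range, micrometers.
#' @param grayLevels Gray rendering: pore/om/mineral means + noiseSd.
#' @param seed RNG seed.
#' @return A validated [PhantomSpec-class].
#' @export
#' @examples
#' spec <- phantomSpec(shape = 64, nOmParticles = 0, seed = 1)
phantomSpec <- function(shape = c(256L, 256L, 256L), pitchUm = 10,
                        structure = c("dense", "loose"),
                        grainSizeFractions = NULL,
                        targetPorosity = 0.45, nOmParticles = 50L,
                        omSizeRangeUm = c(500, 1000),
                        grayLevels = list(pore = 40, om = 110,
                                          mineral = 200, noiseSd = 0),
                        seed = 1L) {
  structure <- match.arg(structure)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (is.null(grainSizeFractions)) {
    ratio <- if (structure == "dense") c(10, 40, 50) else c(20, 60, 20)
    grainSizeFractions <- grainFractions(ratio, targetPorosity)
  }
  new("PhantomSpec", shape = as.integer(shape),
      pitchUm = as.numeric(pitchUm),
      grainSizeFractions = grainSizeFractions,
      targetPorosity = as.numeric(targetPorosity),
      nOmParticles = as.integer(nOmParticles),
      omSizeRangeUm = as.numeric(omSizeRangeUm),
      grayLevels = grayLevels, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %g um, porosity %.2f, %d OM [%g-%g um], seed %d\n",
              paste(object@shape, collapse = "x"), object@pitchUm,
              object@targetPorosity, object@nOmParticles,
              object@omSizeRangeUm[1], object@omSizeRangeUm[2],
              object@seed))
})
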